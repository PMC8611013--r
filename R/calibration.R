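# Comparator threshold calibration against K-edge filters.
#
# A sweep of one open comparator threshold against a filtered beam shows a
# kink in counts-vs-threshold where the filter's K-edge abruptly changes
# its transmission. Locating that kink for two filters with known edge
# energies (gadolinium 50.2 keV, tungsten 69.5 keV) fixes the linear map
# from device threshold units (DAC) to keV.

#' Simulate an open-threshold count sweep behind a K-edge filter
#'
#' Counts all photons whose recorded energy exceeds the threshold
#' `gain * t + offset` keV, where the recorded energy is the true energy
#' blurred by the detector's Gaussian energy response.
#'
#' @param filter_material Filter material (must have a K-edge).
#' @param thickness_mm Filter thickness.
#' @param spectrum A `tube_spectrum`; re-evaluated on a fine grid
#'   internally.
#' @param det A `detector_config`: `gain` (keV/DAC), `offset` (keV) define
#'   the simulated pixel's true threshold map, `energy_sigma_keV` the
#'   blur.
#' @param thresholds_dac DAC threshold sweep values.
#' @param de Energy sampling step in keV for the transmitted spectrum.
#' @return A `threshold_sweep`: list with `t_dac`, `counts`, `filter`.
#' @export
simulate_threshold_sweep <- function(filter_material, thickness_mm = 0.25,
                                     spectrum = generate_tube_spectrum(),
                                     det = detector_config(),
                                     thresholds_dac = seq(30, 100, by = 0.25),
                                     de = 0.1) {
  tab <- material_table(filter_material)
  E <- energy_grid(20, spectrum$kvp, de)
  sp <- generate_tube_spectrum(spectrum$kvp, spectrum$filtration,
                               spectrum$mas, energies = E)
  flu <- sp$fluence
  mu <- tab$density_g_cm3 * mass_attenuation(tab, E)
  NE <- flu * exp(-mu * thickness_mm / 10)
  thr_keV <- det$gain * thresholds_dac + det$offset
  sig <- det$energy_sigma_keV
  counts <- vapply(thr_keV, function(th) {
    if (sig > 1e-9) sum(NE * stats::pnorm((E - th) / sig))
    else sum(NE[E >= th])
  }, numeric(1))
  structure(list(t_dac = thresholds_dac, counts = counts,
                 filter = tab$name,
                 sigma_keV = sig,
                 kedge_keV = kedge_energy(tab)),
            class = "threshold_sweep")
}

# Locate the K-edge kink in DAC units. The transmission step makes the
# second difference of counts(t) a Gaussian-shaped peak (the detector's
# energy response) riding on the smooth spectral background; fitting
# Gaussian + linear background in a window around the maximum removes the
# slope-induced bias of a bare peak pick.
.locate_edge_dac <- function(sweep) {
  ct <- sweep$counts
  t <- sweep$t_dac
  n <- length(ct)
  dt <- t[2] - t[1]
  d2 <- ct[-c(1, 2)] - 2 * ct[-c(1, n)] + ct[-c(n - 1, n)]
  td <- t[2:(n - 1)]
  i <- which.max(d2)
  if (i <= 2L || i >= length(d2) - 1L)
    stop("threshold sweep for filter '", sweep$filter,
         "' does not cover its K-edge", call. = FALSE)
  # Parabolic sub-sample refinement of the second-difference peak, then a
  # first-order correction for the smooth spectral background: the peak of
  # a Gaussian (the energy response, width sigma) riding on a local slope
  # b1 is displaced by b1 * sigma^2 / amplitude, which we estimate from
  # the window shoulders and subtract.
  a <- d2[i - 1L]; b <- d2[i]; cc <- d2[i + 1L]
  shift <- if (abs(a - 2 * b + cc) > 0) 0.5 * (a - cc) / (a - 2 * b + cc) else 0
  c_raw <- td[i] + shift * dt
  sigma <- if (!is.null(sweep$sigma_keV)) sweep$sigma_keV else 4
  if (sigma > 0.5) {
    lo <- which(td >= td[i] - 3.5 * sigma & td <= td[i] - 2.5 * sigma)
    hi <- which(td >= td[i] + 2.5 * sigma & td <= td[i] + 3.5 * sigma)
    if (length(lo) >= 2 && length(hi) >= 2) {
      b1 <- (mean(d2[hi]) - mean(d2[lo])) / (mean(td[hi]) - mean(td[lo]))
      b0 <- (mean(d2[hi]) + mean(d2[lo])) / 2
      amp <- d2[i] - b0
      if (amp > 0) c_raw <- c_raw - b1 * sigma^2 / amp
    }
  }
  c_raw
}

#' Run the standard two-filter threshold calibration
#'
#' Sweeps one open threshold behind the gadolinium and tungsten
#' calibration foils and solves for the comparator gain and offset. The
#' tungsten foil is thicker than the gadolinium foil so that both
#' K-edge transmission steps have comparable amplitude against the
#' spectral background.
#'
#' @param det A `detector_config` (its `gain`/`offset` are the simulated
#'   truth to recover).
#' @param spectrum A `tube_spectrum`.
#' @param gd_mm,w_mm Foil thicknesses.
#' @param thresholds_dac DAC sweep.
#' @return See [calibrate_thresholds()].
#' @export
run_threshold_calibration <- function(det = detector_config(),
                                      spectrum = generate_tube_spectrum(),
                                      gd_mm = 0.25, w_mm = 0.30,
                                      thresholds_dac = seq(30, 100,
                                                           by = 0.25)) {
  calibrate_thresholds(list(
    simulate_threshold_sweep("gadolinium", gd_mm, spectrum, det,
                             thresholds_dac),
    simulate_threshold_sweep("tungsten", w_mm, spectrum, det,
                             thresholds_dac)))
}

#' Calibrate comparator gain and offset from two K-edge filter sweeps
#'
#' Locates the transmission kink of each filter in the sweep derivative and
#' solves the two-point linear system mapping DAC units to keV using the
#' filters' known K-edge energies.
#'
#' @param sweeps List of two (or more) `threshold_sweep` objects with
#'   distinct filter K-edges.
#' @return List with `gain` (keV/DAC), `offset` (keV), and a data frame
#'   `edges` of per-filter located DAC positions and reference energies.
#' @export
calibrate_thresholds <- function(sweeps) {
  if (length(sweeps) < 2)
    stop("need sweeps for at least two K-edge filters", call. = FALSE)
  ek <- vapply(sweeps, function(s) {
    if (is.null(s$kedge_keV))
      stop("filter '", s$filter, "' has no K-edge in the imaging window",
           call. = FALSE)
    s$kedge_keV
  }, numeric(1))
  td <- vapply(sweeps, .locate_edge_dac, numeric(1))
  fit <- stats::lm.fit(cbind(1, td), ek)
  gain <- unname(fit$coefficients[2])
  offset <- unname(fit$coefficients[1])
  list(gain = gain, offset = offset,
       edges = data.frame(filter = vapply(sweeps, `[[`, "", "filter"),
                          dac = td, keV = ek,
                          located_keV = gain * td + offset))
}
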