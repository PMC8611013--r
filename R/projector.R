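# Fan-beam acquisition model: material path projection, polychromatic
# Beer--Lambert bin counts, Poisson sampling with counter saturation,
# detector binning, and the EID comparison mode.

.view_angles <- function(geometry) {
  (seq_len(geometry$n_views) - 1) * 2 * pi / geometry$n_views
}

.fan_angles <- function(n_cols, dgamma) {
  (seq_len(n_cols) - (n_cols + 1) / 2) * dgamma
}

# per-stage seed derivation from a master seed (kept below 2^31)
.stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 131 + stage * 7919) %% 2147483629)
}

#' Project material path lengths
#'
#' Exact (finely sampled) line integrals of each material's volume-fraction
#' map along every fan-beam ray; one pass per material; linear in phantom
#' content.
#'
#' @param phantom A `digital_phantom`.
#' @param geometry A `scanner_geometry`.
#' @param step_mm Ray sampling step (default half the phantom pixel).
#' @return Array `n_views x n_cols x n_materials` of path lengths in cm,
#'   with material names on the third dimension.
#' @export
project_material_paths <- function(phantom, geometry,
                                   step_mm = phantom$pixel_mm / 2) {
  fan_half <- geometry$dgamma * geometry$n_cols / 2
  coverage <- geometry$sid_mm * sin(min(fan_half, pi / 2))
  if (phantom$fov_mm / 2 > coverage + 1e-9)
    warning("phantom extends beyond the scanned field of view; ",
            "projections are truncated")
  mats <- names(phantom$materials)
  paths <- project_paths_cpp(unname(phantom$materials), phantom$n,
                             phantom$pixel_mm, geometry$sid_mm,
                             .view_angles(geometry),
                             .fan_angles(geometry$n_cols, geometry$dgamma),
                             step_mm)
  paths <- paths / 10  # mm -> cm
  dimnames(paths) <- list(NULL, NULL, mats)
  paths
}

# Bin weight of each spectrum energy: probability that a photon of true
# energy E is recorded inside [lo, hi) after Gaussian energy blur (applied
# to E before thresholding). The top threshold of the last bin is closed so
# that contiguous bins tile the full range exactly.
.bin_weights <- function(energies, bins, sigma) {
  W <- matrix(0, length(energies), bins$n_bins)
  for (b in seq_len(bins$n_bins)) {
    lo <- bins$lo[b]; hi <- bins$hi[b]
    if (sigma > 1e-9) {
      W[, b] <- stats::pnorm((hi - energies) / sigma) -
        stats::pnorm((lo - energies) / sigma)
    } else {
      top <- if (b == bins$n_bins) energies <= hi else energies < hi
      W[, b] <- as.numeric(energies >= lo & top)
    }
  }
  W
}

#' Expected photon counts per energy bin
#'
#' For each energy sample `E`: `N(E) = fluence(E) * exp(-sum_m mu_m(E) *
#' path_m)`; bin counts integrate `N(E)` against the Gaussian
#' energy-response weights of each bin.
#'
#' @param paths Array from [project_material_paths()] (cm).
#' @param spectrum A `tube_spectrum`.
#' @param bins An `energy_bins`.
#' @param det A `detector_config` (supplies the energy response width).
#' @param exposure_scale Multiplier on the spectrum fluence (e.g. the
#'   per-view, per-row share of the total exposure).
#' @return Array `n_views x n_cols x n_bins` of expected (real-valued)
#'   counts.
#' @export
expected_bin_counts <- function(paths, spectrum, bins, det = detector_config(),
                                exposure_scale = 1) {
  E <- spectrum$energies
  if (bins$thresholds[1] < min(E) || max(bins$thresholds) > max(E) + 1e-9)
    stop("energy bins exceed the spectrum support [",
         min(E), ", ", max(E), "] keV", call. = FALSE)
  d <- dim(paths)
  mats <- dimnames(paths)[[3]]
  P <- matrix(paths, d[1] * d[2], d[3])
  mu <- sapply(mats, function(m) {
    tab <- material_table(m)
    tab$density_g_cm3 * mass_attenuation(tab, E)
  })  # nE x n_mat
  W <- .bin_weights(E, bins, det$energy_sigma_keV)
  flu <- spectrum$fluence * exposure_scale
  counts <- matrix(0, d[1] * d[2], bins$n_bins)
  for (e in seq_along(E)) {
    active <- W[e, ] != 0
    if (!any(active) || flu[e] == 0) next
    NE <- flu[e] * exp(-drop(P %*% mu[e, ]))
    for (b in which(active)) counts[, b] <- counts[, b] + W[e, b] * NE
  }
  array(counts, c(d[1], d[2], bins$n_bins))
}

#' Poisson-sample photon counts with counter saturation
#'
#' Independent Poisson draw per (view, column, bin), clipped at the per-bin
#' counter saturation `2^bits - 1` (scaled by `sat_scale` when the sample
#' represents a sum over `sat_scale` physical counters).
#'
#' @param expected Nonnegative expected-count array (`... x n_bins`).
#' @param det A `detector_config` (bit depths).
#' @param seed Integer seed; the draw is reproducible.
#' @param sat_scale Number of physical counters summed per sample.
#' @return Integer-valued array of the same shape.
#' @export
sample_counts <- function(expected, det = detector_config(), seed = 1L,
                          sat_scale = 1L) {
  if (any(expected < 0)) stop("expected counts must be nonnegative")
  d <- dim(expected)
  n_bins <- d[length(d)]
  sat <- counter_saturation(det)
  if (length(sat) < n_bins) sat <- rep(sat, length.out = n_bins)
  per_bin <- prod(d[-length(d)])
  out <- expected
  set.seed(seed)
  for (b in seq_len(n_bins)) {
    idx <- (b - 1) * per_bin + seq_len(per_bin)
    out[idx] <- pmin(stats::rpois(per_bin, expected[idx]),
                     as.numeric(sat[b]) * sat_scale)
  }
  out
}

#' Sum detector pixels into binned pixels
#'
#' Standard mode sums 5-row x 6-column blocks (80 x 2304 native ->
#' 16 x 384); HR mode is the identity. Total counts are conserved exactly.
#'
#' @param counts Array `rows x cols` or `rows x cols x bins` of native
#'   counts.
#' @param mode `"standard"` or `"hr"`, or a length-2 integer vector of
#'   (row, column) binning factors.
#' @return Binned array.
#' @export
apply_binning <- function(counts, mode = "standard") {
  factors <- if (is.character(mode)) {
    if (match.arg(mode, c("standard", "hr")) == "standard") c(5L, 6L)
    else c(1L, 1L)
  } else as.integer(mode)
  d <- dim(counts)
  if (is.null(d)) stop("counts must be a matrix or array", call. = FALSE)
  if (all(factors == 1L)) return(counts)
  if (length(d) == 2) d <- c(d, 1L)
  if (d[1] %% factors[1] != 0 || d[2] %% factors[2] != 0)
    stop("binning factors ", paste(factors, collapse = "x"),
         " do not divide the native dimensions ", d[1], "x", d[2],
         call. = FALSE)
  arr <- array(counts, d)
  r2 <- d[1] %/% factors[1]; c2 <- d[2] %/% factors[2]
  out <- array(0, c(r2, c2, d[3]))
  for (b in seq_len(d[3])) {
    m <- arr[, , b]
    # sum row blocks, then column blocks
    m <- rowsum(m, rep(seq_len(r2), each = factors[1]))
    m <- t(rowsum(t(m), rep(seq_len(c2), each = factors[2])))
    out[, , b] <- m
  }
  if (length(dim(counts)) == 2) out[, , 1] else out
}

# Sum groups of `factor` adjacent columns of a views x cols x bins array.
.bin_sino_columns <- function(arr, factor) {
  if (factor == 1L) return(arr)
  d <- dim(arr)
  if (d[2] %% factor != 0)
    stop("column binning factor does not divide detector columns",
         call. = FALSE)
  c2 <- d[2] %/% factor
  out <- array(0, c(d[1], c2, d[3]))
  grp <- rep(seq_len(c2), each = factor)
  for (b in seq_len(d[3]))
    out[, , b] <- t(rowsum(t(arr[, , b, drop = TRUE]), grp))
  out
}

#' Simulate a complete photon-counting acquisition
#'
#' Projects the phantom, computes expected per-bin counts for every native
#' detector column and view (the per-view exposure is `mas / n_views`, and
#' the z rows summed into one slice multiply the fluence by the row binning
#' factor), Poisson-samples them, and sums detector columns according to
#' the binning mode. The noiseless expected counts serve as the air-scan
#' reference after an identical binning.
#'
#' @param phantom A `digital_phantom`.
#' @param geometry A `scanner_geometry`.
#' @param spectrum A `tube_spectrum` (its `mas` is the whole-scan exposure).
#' @param bins An `energy_bins`.
#' @param det A `detector_config`.
#' @param seed Master seed for the Poisson draw.
#' @param noise If `FALSE`, return noiseless expected counts.
#' @param paths Optional precomputed [project_material_paths()] result.
#' @param expected Optional precomputed native expected-count array (from
#'   a previous run with identical acquisition settings); skips the
#'   polychromatic forward model when replicate noise realisations of one
#'   phantom are needed.
#' @return A `binned_sinogram`: `counts` and `air` arrays
#'   (`n_views x binned_cols x n_bins`) plus acquisition metadata.
#' @export
simulate_scan <- function(phantom, geometry, spectrum,
                          bins = energy_bins(), det = detector_config(),
                          seed = 1L, noise = TRUE, paths = NULL,
                          expected = NULL) {
  if (is.null(expected)) {
    if (is.null(paths)) paths <- project_material_paths(phantom, geometry)
    scale <- det$row_factor / geometry$n_views
    expected <- expected_bin_counts(paths, spectrum, bins, det, scale)
  } else scale <- det$row_factor / geometry$n_views
  native <- if (noise)
    sample_counts(expected, det, .stage_seed(seed, 1L), det$row_factor)
  else expected
  air_bin <- colSums(.bin_weights(spectrum$energies, bins,
                                  det$energy_sigma_keV) *
                       spectrum$fluence) * scale
  d <- dim(expected)
  air_native <- array(rep(air_bin, each = d[1] * d[2]), d)
  structure(list(counts = .bin_sino_columns(native, det$col_factor),
                 air = .bin_sino_columns(air_native, det$col_factor),
                 geometry = geometry, bins = bins, det = det,
                 mas = spectrum$mas, seed = seed, noise = noise,
                 phantom_name = phantom$name, expected = expected),
            class = "binned_sinogram")
}

#' @export
print.binned_sinogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<binned_sinogram> %s: %d views x %d columns x %d bins (%s mode, %g mAs, seed %s)\n",
              x$phantom_name, d[1], d[2], d[3], x$det$binning, x$mas,
              format(x$seed)))
  invisible(x)
}

#' Energy-integrating detector (EID) comparison mode
#'
#' The EID signal is the energy-weighted photon sum over the full spectrum,
#' `sum_E E * N(E)`, with Gaussian quantum + electronic noise
#' (`Var = sum_E E^2 N(E) + sigma_e^2`).
#'
#' @param paths Material path array (cm).
#' @param spectrum A `tube_spectrum`.
#' @param det A `detector_config` (`eid_noise_sd` is the electronic term).
#' @param exposure_scale Multiplier on the fluence, as in
#'   [expected_bin_counts()].
#' @param seed Seed for the noise draw, or `NULL` for a noiseless signal.
#' @return List with `signal` and `air` matrices (`n_views x n_cols`).
#' @export
simulate_eid <- function(paths, spectrum, det = detector_config(),
                         exposure_scale = 1, seed = NULL) {
  E <- spectrum$energies
  d <- dim(paths)
  mats <- dimnames(paths)[[3]]
  P <- matrix(paths, d[1] * d[2], d[3])
  mu <- sapply(mats, function(m) {
    tab <- material_table(m)
    tab$density_g_cm3 * mass_attenuation(tab, E)
  })
  flu <- spectrum$fluence * exposure_scale
  sig <- var <- numeric(d[1] * d[2])
  for (e in seq_along(E)) {
    if (flu[e] == 0) next
    NE <- flu[e] * exp(-drop(P %*% mu[e, ]))
    sig <- sig + E[e] * NE
    var <- var + E[e]^2 * NE
  }
  if (!is.null(seed)) {
    set.seed(seed)
    sig <- sig + stats::rnorm(length(sig),
                              sd = sqrt(var + det$eid_noise_sd^2))
  }
  air <- sum(E * flu)
  list(signal = matrix(sig, d[1], d[2]),
       air = matrix(air, d[1], d[2]))
}

#' Simulate an EID acquisition of a phantom
#'
#' Same exposure bookkeeping as [simulate_scan()]; native column signals
#' are summed into binned columns after the noise draw.
#'
#' @inheritParams simulate_scan
#' @return An `eid_sinogram` list with `signal`, `air`, and metadata.
#' @export
simulate_scan_eid <- function(phantom, geometry, spectrum,
                              det = detector_config(), seed = 1L,
                              noise = TRUE, paths = NULL) {
  if (is.null(paths)) paths <- project_material_paths(phantom, geometry)
  scale <- det$row_factor / geometry$n_views
  eid <- simulate_eid(paths, spectrum, det, scale,
                      seed = if (noise) .stage_seed(seed, 2L) else NULL)
  f <- det$col_factor
  grp <- rep(seq_len(ncol(eid$signal) %/% f), each = f)
  structure(list(signal = t(rowsum(t(eid$signal), grp)),
                 air = t(rowsum(t(eid$air), grp)),
                 geometry = geometry, det = det, mas = spectrum$mas,
                 seed = seed, phantom_name = phantom$name),
            class = "eid_sinogram")
}
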