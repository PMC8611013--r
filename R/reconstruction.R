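# Log-normalization and equiangular fan-beam filtered back-projection.

#' Log-normalize a binned sinogram to line integrals
#'
#' `p = -ln(max(counts, eps) / air)`; `"total"` first sums counts (and air
#' reference) over the three bins, matching the system's total-energy
#' image.
#'
#' @param sino A `binned_sinogram`.
#' @param channel Bin index (1-based) or `"total"`.
#' @param eps Zero-count guard in counts (default 0.5).
#' @return Matrix `n_views x n_cols` of line integrals (dimensionless,
#'   mu in cm^-1 times path in cm).
#' @export
log_normalize <- function(sino, channel = "total", eps = 0.5) {
  if (identical(channel, "total")) {
    counts <- rowSums(sino$counts, dims = 2)
    air <- rowSums(sino$air, dims = 2)
  } else {
    counts <- sino$counts[, , channel]
    air <- sino$air[, , channel]
  }
  if (any(air <= 0)) stop("air reference counts must be positive",
                          call. = FALSE)
  -log(pmax(counts, eps) / air)
}

# Equiangular ramp filter kernel (spatial domain), indices -(N-1)..(N-1):
# 1/(8 dgamma^2) at 0, 0 at even offsets, -1/(2 pi^2 sin^2(n dgamma)) at
# odd offsets.
.ramp_kernel_eq <- function(n_cols, dgamma) {
  n <- -(n_cols - 1):(n_cols - 1)
  k <- numeric(length(n))
  k[n == 0] <- 1 / (8 * dgamma^2)
  odd <- n %% 2 != 0
  k[odd] <- -1 / (2 * pi^2 * sin(n[odd] * dgamma)^2)
  k
}

# FFT-based linear convolution of each sinogram row with the ramp kernel,
# optionally Hann-apodized in the frequency domain.
.filter_projections <- function(p_weighted, dgamma, filter = "ram-lak") {
  n_views <- nrow(p_weighted); n_cols <- ncol(p_weighted)
  kern <- .ramp_kernel_eq(n_cols, dgamma)
  L <- stats::nextn(n_cols + length(kern) - 1, 2)
  K <- stats::fft(c(kern, rep(0, L - length(kern))))
  if (filter == "hann") {
    f <- c(seq(0, L / 2), seq(-L / 2 + 1, -1)) / L
    K <- K * 0.5 * (1 + cos(2 * pi * f))
  }
  P <- rbind(t(p_weighted), matrix(0, L - n_cols, n_views))
  Q <- Re(stats::mvfft(stats::mvfft(P) * K, inverse = TRUE)) / L
  # rows n_cols..(2*n_cols-1) of the linear convolution align with columns
  t(Q[n_cols:(2 * n_cols - 1), , drop = FALSE]) * dgamma
}

#' Equiangular fan-beam filtered back-projection
#'
#' Standard weighting (`p * SID * cos(gamma)`), ramp filtering along the
#' detector, and distance-weighted backprojection onto a pixel-center
#' grid. The operator is linear in `p`.
#'
#' @param p Line-integral sinogram (`n_views x n_cols`), e.g. from
#'   [log_normalize()] (mu in cm^-1 integrated over cm).
#' @param geometry A `scanner_geometry`.
#' @param col_factor Detector column binning factor that produced `p`
#'   (widens the effective angular pitch).
#' @param filter `"ram-lak"` or `"hann"`.
#' @param n_out Output grid size (pixels).
#' @param fov_mm Output field of view (default the geometry FoV).
#' @param center_mm Length-2 (x, y) center of the output grid.
#' @return `n_out x n_out` matrix of effective attenuation in cm^-1.
#' @export
fbp_fan <- function(p, geometry, col_factor = 1L,
                    filter = c("ram-lak", "hann"),
                    n_out = 313L, fov_mm = geometry$fov_mm,
                    center_mm = c(0, 0)) {
  filter <- match.arg(filter)
  if (nrow(p) < 2) stop("need at least 2 views", call. = FALSE)
  dgamma <- geometry$dgamma * col_factor
  n_cols <- ncol(p)
  gam <- .fan_angles(n_cols, dgamma)
  pw <- sweep(p, 2, geometry$sid_mm * cos(gam), `*`)
  q <- .filter_projections(pw, dgamma, filter)
  img <- backproject_cpp(q, geometry$sid_mm, .view_angles(geometry),
                         dgamma, n_cols, as.integer(n_out),
                         fov_mm / n_out, center_mm[1], center_mm[2])
  # p carries mu in cm^-1 integrated over cm while the geometry is in mm,
  # so the 1/L^2-weighted backprojection returns mu/10 per cm.
  img * 10
}

#' Water calibration of effective attenuation per channel
#'
#' Simulates a noiseless scan of a centered water cylinder and records the
#' mean reconstructed attenuation in a central ROI for every energy bin,
#' the total-energy channel and (optionally) the EID mode. These values
#' anchor the HU scale so water reconstructs to 0 HU per channel.
#'
#' @param geometry,spectrum,bins,det Acquisition configuration.
#' @param n_out Reconstruction grid used downstream.
#' @param disc_radius_mm Radius of the calibration cylinder.
#' @param render_n Phantom render grid.
#' @param include_eid Also calibrate the EID channel.
#' @param filter Reconstruction filter.
#' @return A `water_calibration`: named list `mu_water` (cm^-1) per
#'   channel.
#' @export
calibrate_water <- function(geometry, spectrum, bins = energy_bins(),
                            det = detector_config(), n_out = 313L,
                            disc_radius_mm = 100, render_n = 2L * n_out,
                            include_eid = FALSE,
                            filter = "ram-lak") {
  ph <- .empty_phantom("water_cal", render_n, geometry$fov_mm)
  g <- .coord_grids(ph)
  ph <- .paint(ph, .disc_mask(g, c(0, 0), disc_radius_mm), c(water = 1))
  paths <- project_material_paths(ph, geometry)
  sino <- simulate_scan(ph, geometry, spectrum, bins, det,
                        noise = FALSE, paths = paths)
  roi <- roi_spec("cal", "tissue", c(0, 0), disc_radius_mm * 0.3)
  chans <- c(as.list(seq_len(bins$n_bins)), list("total"))
  names(chans) <- c(paste0("bin", seq_len(bins$n_bins)), "total")
  mu_water <- lapply(chans, function(ch) {
    mu <- fbp_fan(log_normalize(sino, ch), geometry, det$col_factor,
                  filter = filter, n_out = n_out)
    .roi_mean(mu, roi, geometry$fov_mm / n_out)
  })
  if (include_eid) {
    eid <- simulate_scan_eid(ph, geometry, spectrum, det,
                             noise = FALSE, paths = paths)
    p <- -log(eid$signal / eid$air)
    mu <- fbp_fan(p, geometry, det$col_factor, filter = filter,
                  n_out = n_out)
    mu_water$eid <- .roi_mean(mu, roi, geometry$fov_mm / n_out)
  }
  structure(list(mu_water = mu_water, n_out = n_out, filter = filter),
            class = "water_calibration")
}

.recon_image <- function(hu, pixel_mm, channel, geometry, filter) {
  structure(list(hu = hu, pixel_mm = pixel_mm, channel = channel,
                 n = nrow(hu), filter = filter,
                 geometry = geometry), class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> channel=%s %dx%d px (%.4g mm/px, %s filter)\n",
              x$channel, x$n, x$n, x$pixel_mm, x$filter))
  invisible(x)
}

#' Reconstruct HU images for every bin and the total-energy channel
#'
#' @param sino A `binned_sinogram`.
#' @param water_cal A `water_calibration` for the same acquisition
#'   configuration (required: it defines the HU scale).
#' @param n_out Grid size (defaults to the calibration grid).
#' @param filter Reconstruction filter.
#' @return Named list of `recon_image` objects: `bin1..binN` and `total`.
#' @export
reconstruct_all <- function(sino, water_cal, n_out = NULL,
                            filter = NULL) {
  if (missing(water_cal) || !inherits(water_cal, "water_calibration"))
    stop("water calibration required: run calibrate_water() for this ",
         "acquisition configuration first", call. = FALSE)
  if (is.null(n_out)) n_out <- water_cal$n_out
  if (is.null(filter)) filter <- water_cal$filter
  geometry <- sino$geometry
  px <- geometry$fov_mm / n_out
  chans <- c(as.list(seq_len(sino$bins$n_bins)), list("total"))
  names(chans) <- c(paste0("bin", seq_len(sino$bins$n_bins)), "total")
  lapply(seq_along(chans), function(i) {
    ch <- chans[[i]]; nm <- names(chans)[i]
    mu <- fbp_fan(log_normalize(sino, ch), geometry, sino$det$col_factor,
                  filter = filter, n_out = n_out)
    .recon_image(hu_from_mu(mu, water_cal$mu_water[[nm]]), px, nm,
                 geometry, filter)
  }) -> imgs
  names(imgs) <- names(chans)
  imgs
}

#' Reconstruct the EID comparison image
#'
#' @param eid An `eid_sinogram`.
#' @param water_cal A `water_calibration` built with `include_eid = TRUE`.
#' @param n_out,filter As in [reconstruct_all()].
#' @return A `recon_image` with channel `"eid"`.
#' @export
reconstruct_eid <- function(eid, water_cal, n_out = NULL, filter = NULL) {
  if (is.null(water_cal$mu_water$eid))
    stop("water calibration lacks the EID channel; rerun calibrate_water(",
         "include_eid = TRUE)", call. = FALSE)
  if (is.null(n_out)) n_out <- water_cal$n_out
  if (is.null(filter)) filter <- water_cal$filter
  p <- -log(pmax(eid$signal, 1e-6) / eid$air)
  mu <- fbp_fan(p, eid$geometry, eid$det$col_factor, filter = filter,
                n_out = n_out)
  .recon_image(hu_from_mu(mu, water_cal$mu_water$eid),
               eid$geometry$fov_mm / n_out, "eid", eid$geometry, filter)
}
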