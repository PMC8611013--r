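# Scanner geometry, energy bins, and detector configuration.

#' Scanner geometry
#'
#' Curved (equiangular) fan-beam geometry. The source-to-detector distance
#' defaults to 337.7 mm, derived from the detector z pitch (0.190 mm), the
#' 5-row standard binning, and the 0.640 mm slice thickness at the
#' isocenter: SDD = SID * (0.190 * 5) / 0.640.
#'
#' @param sid_mm Source-to-isocenter distance (mm).
#' @param sdd_mm Source-to-detector distance (mm); must exceed `sid_mm`.
#' @param n_views Projections per rotation.
#' @param rotation_s Gantry rotation time (metadata only).
#' @param n_cols Native detector columns.
#' @param n_rows Native detector rows.
#' @param col_pitch_mm In-plane detector column pitch at the detector (mm).
#' @param row_pitch_mm z-axis detector row pitch at the detector (mm).
#' @param n_modules Detector modules in the assembly.
#' @param fov_mm Reconstruction field of view (mm).
#' @return A `scanner_geometry` list.
#' @export
scanner_geometry <- function(sid_mm = 227.5, sdd_mm = 337.7,
                             n_views = 1440, rotation_s = 2,
                             n_cols = 2304, n_rows = 80,
                             col_pitch_mm = 0.230, row_pitch_mm = 0.190,
                             n_modules = 48, fov_mm = 250) {
  if (sdd_mm <= sid_mm)
    stop("source-to-detector distance must exceed source-to-isocenter",
         call. = FALSE)
  g <- list(sid_mm = sid_mm, sdd_mm = sdd_mm, n_views = n_views,
            rotation_s = rotation_s, n_cols = n_cols, n_rows = n_rows,
            col_pitch_mm = col_pitch_mm, row_pitch_mm = row_pitch_mm,
            n_modules = n_modules, fov_mm = fov_mm)
  g$dgamma <- col_pitch_mm / sdd_mm              # equiangular column pitch
  fan_half <- g$dgamma * n_cols / 2
  if (sid_mm * sin(min(fan_half, pi / 2)) < fov_mm / 2)
    warning("fan angle does not cover the requested FoV; ",
            "objects near the FoV edge will be truncated")
  class(g) <- "scanner_geometry"
  g
}

#' Detector channel bookkeeping
#'
#' Each ASIC serves one 80 x 48 pixel module, i.e. 3840 parallel readout
#' channels; the assembly of 48 modules has 80 rows x 2304 columns.
#'
#' @param geometry A `scanner_geometry`.
#' @return List with `channels_per_module`, `assembly_columns`,
#'   `assembly_rows`.
#' @export
detector_channels <- function(geometry = scanner_geometry()) {
  cols_per_module <- geometry$n_cols / geometry$n_modules
  list(channels_per_module = geometry$n_rows * cols_per_module,
       assembly_columns = geometry$n_modules * cols_per_module,
       assembly_rows = geometry$n_rows)
}

#' Energy bin thresholds
#'
#' @param thresholds Ascending keV thresholds; `n` thresholds define `n - 1`
#'   contiguous bins. Default `c(30, 50, 65, 140)`: bin 1 30--50, bin 2
#'   50--65, bin 3 65--140 keV.
#' @return An `energy_bins` list with `thresholds`, `n_bins`, `lo`, `hi`.
#' @export
energy_bins <- function(thresholds = c(30, 50, 65, 140)) {
  stopifnot(length(thresholds) >= 2, all(diff(thresholds) > 0))
  if (thresholds[1] < 20)
    stop("lowest threshold must be at least 20 keV", call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 n_bins = length(thresholds) - 1L,
                 lo = thresholds[-length(thresholds)],
                 hi = thresholds[-1]),
            class = "energy_bins")
}

#' Detector configuration
#'
#' @param bit_depths Counter bit depths per bin, low to high energy
#'   (default `c(14, 13, 12)`); each counter saturates at `2^bits - 1`.
#' @param binning `"standard"` (5 rows x 6 columns summed) or `"hr"`
#'   (native 1 x 1 pixels).
#' @param energy_sigma_keV Gaussian energy-response width (keV).
#' @param gain Comparator gain, keV per DAC unit (threshold model).
#' @param offset Comparator offset in keV.
#' @param eid_noise_sd Electronic noise SD for the EID comparison mode, in
#'   energy-weighted count units per measurement.
#' @return A `detector_config` list.
#' @export
detector_config <- function(bit_depths = c(14, 13, 12),
                            binning = c("standard", "hr"),
                            energy_sigma_keV = 4,
                            gain = 1, offset = 0,
                            eid_noise_sd = 0) {
  binning <- match.arg(binning)
  stopifnot(all(bit_depths > 0), energy_sigma_keV >= 0)
  structure(list(bit_depths = as.integer(bit_depths), binning = binning,
                 row_factor = if (binning == "standard") 5L else 1L,
                 col_factor = if (binning == "standard") 6L else 1L,
                 energy_sigma_keV = energy_sigma_keV,
                 gain = gain, offset = offset,
                 eid_noise_sd = eid_noise_sd),
            class = "detector_config")
}

#' Per-bin counter saturation values
#' @param det A `detector_config`.
#' @return Integer vector `2^bits - 1` per bin counter.
#' @export
counter_saturation <- function(det) as.integer(2^det$bit_depths - 1)

#' Effective detector pixel size at the isocenter
#'
#' Native pitch x binning factor x (SID / SDD). With the default geometry
#' this gives a 0.640 mm z pixel (slice thickness) in standard 5 x 6
#' binning and 0.128 mm in HR 1 x 1 mode.
#'
#' @param geometry A `scanner_geometry`.
#' @param mode `"standard"` or `"hr"`.
#' @param axis `"z"` (rows) or `"inplane"` (columns).
#' @return Size in mm.
#' @export
effective_pixel_at_iso <- function(geometry = scanner_geometry(),
                                   mode = c("standard", "hr"),
                                   axis = c("z", "inplane")) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  pitch <- if (axis == "z") geometry$row_pitch_mm else geometry$col_pitch_mm
  factor <- if (mode == "hr") 1 else if (axis == "z") 5 else 6
  pitch * factor * geometry$sid_mm / geometry$sdd_mm
}

#' Slices per scan for a binning mode
#' @param geometry A `scanner_geometry`.
#' @param mode `"standard"` or `"hr"`.
#' @export
n_slices <- function(geometry = scanner_geometry(),
                     mode = c("standard", "hr")) {
  mode <- match.arg(mode)
  geometry$n_rows %/% (if (mode == "standard") 5L else 1L)
}

#' Predefined simulation profiles
#'
#' `"full"` matches the physical system (1440 views, 2304 native columns,
#' 625 x 625 reconstruction). `"reduced"` and `"coarse"` scale the view and
#' column counts down (widening the column pitch so the fan still covers
#' the 250 mm FoV) for fast desk-scale runs; the phantom render grid is
#' always twice the reconstruction grid.
#'
#' @param name `"full"`, `"reduced"` or `"coarse"`.
#' @return List with `geometry`, `recon_n`, `render_n`.
#' @export
scan_profile <- function(name = c("reduced", "full", "coarse")) {
  name <- match.arg(name)
  switch(name,
    full = list(geometry = scanner_geometry(),
                recon_n = 625L, render_n = 1250L),
    reduced = list(geometry = scanner_geometry(n_views = 720, n_cols = 768,
                                               col_pitch_mm = 0.690),
                   recon_n = 313L, render_n = 626L),
    coarse = list(geometry = scanner_geometry(n_views = 360, n_cols = 384,
                                              col_pitch_mm = 1.380),
                  recon_n = 157L, render_n = 314L))
}
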