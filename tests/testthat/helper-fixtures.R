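# Shared fixtures, built lazily and cached for the whole test run.
# Everything is generated in code; no stored data.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_spectrum <- function() fx_get("spectrum", function()
  generate_tube_spectrum(mas = 14))

# coarse profile: fast end-to-end physics checks
fx_coarse <- function() fx_get("coarse", function() {
  prof <- scan_profile("coarse")
  list(prof = prof, bins = energy_bins(), det = detector_config(),
       px = prof$geometry$fov_mm / prof$recon_n)
})

fx_coarse_cal <- function() fx_get("coarse_cal", function() {
  cx <- fx_coarse()
  calibrate_water(cx$prof$geometry, fx_spectrum(), cx$bins, cx$det,
                  n_out = cx$prof$recon_n, include_eid = TRUE)
})

# noiseless water-disc acquisition on the coarse profile
fx_water_disc <- function() fx_get("water_disc", function() {
  cx <- fx_coarse()
  ph <- make_insert_phantom(iodine_concs = numeric(0),
                            calcium_concs = numeric(0),
                            n_water_inserts = 0, body_radius_mm = 80,
                            n = cx$prof$render_n)
  paths <- project_material_paths(ph, cx$prof$geometry)
  sino <- simulate_scan(ph, cx$prof$geometry, fx_spectrum(), cx$bins,
                        cx$det, noise = FALSE, paths = paths)
  list(phantom = ph, paths = paths, sino = sino)
})

# reduced profile: decomposition-scale fixtures
fx_reduced <- function() fx_get("reduced", function() {
  prof <- scan_profile("reduced")
  list(prof = prof, bins = energy_bins(), det = detector_config(),
       px = prof$geometry$fov_mm / prof$recon_n)
})

fx_reduced_cal <- function() fx_get("reduced_cal", function() {
  rx <- fx_reduced()
  calibrate_water(rx$prof$geometry, fx_spectrum(), rx$bins, rx$det,
                  n_out = rx$prof$recon_n)
})

# noiseless insert-phantom reconstruction (reduced profile) and the
# decomposition model trained on it with the printed lr/epochs
fx_insert_noiseless <- function() fx_get("insert_noiseless", function() {
  rx <- fx_reduced()
  ph <- make_insert_phantom(n = rx$prof$render_n)
  sino <- simulate_scan(ph, rx$prof$geometry, fx_spectrum(), rx$bins,
                        rx$det, noise = FALSE)
  imgs <- reconstruct_all(sino, fx_reduced_cal())
  ts <- extract_training_set(imgs[1:3], ph$rois, side_px = 25)
  list(phantom = ph, images = imgs, ts = ts)
})

fx_insert_model <- function() fx_get("insert_model", function() {
  train_decomposition(fx_insert_noiseless()$ts,
                      training_config(hidden_width = 16L, seed = 11L))
})

# brute-force ROI statistics oracle: explicit loop over pixel centers
oracle_roi_stats <- function(mat, roi, pixel_mm) {
  n <- nrow(mat)
  vals <- c()
  for (r in seq_len(n)) for (cc in seq_len(n)) {
    x <- (cc - 1 - (n - 1) / 2) * pixel_mm
    y <- ((n - 1) / 2 - (r - 1)) * pixel_mm
    if ((x - roi$center_mm[1])^2 + (y - roi$center_mm[2])^2 <=
        roi$radius_mm^2)
      vals <- c(vals, mat[r, cc])
  }
  list(n = length(vals), mean = mean(vals), sd = stats::sd(vals))
}
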