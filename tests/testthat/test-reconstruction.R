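# Log-normalization and fan-beam FBP.

test_that("log normalization has the right anchors and guards", {
  wd <- fx_water_disc()
  sino <- wd$sino
  # counts equal to air give p = 0 (outside the object)
  p <- log_normalize(sino, 1)
  expect_equal(p[1, 1], 0, tolerance = 1e-12)
  # zero counts stay finite through the epsilon guard
  s0 <- sino
  s0$counts[, , 1] <- 0
  expect_true(all(is.finite(log_normalize(s0, 1))))
  # total mode sums bins before the log
  ptot <- log_normalize(sino, "total")
  oracle <- -log(rowSums(sino$counts, dims = 2) /
                   rowSums(sino$air, dims = 2))
  expect_equal(ptot, oracle)
})

test_that("line integrals match the spectrum-weighted oracle", {
  cx <- fx_coarse()
  wd <- fx_water_disc()
  sp <- fx_spectrum()
  # central ray: p = integral over the blurred-bin spectrum of
  # fluence * exp(-mu L), computed directly from the energy grid
  gamb <- pcctsim:::.fan_angles(ncol(wd$sino$counts),
                                cx$prof$geometry$dgamma * cx$det$col_factor)
  ic <- which.min(abs(gamb))
  p2 <- log_normalize(wd$sino, 2)[1, ic]
  W <- pcctsim:::.bin_weights(sp$energies, cx$bins,
                              cx$det$energy_sigma_keV)[, 2]
  mu <- mass_attenuation("water", sp$energies)
  L <- 16  # cm, disc diameter
  oracle <- -log(sum(W * sp$fluence * exp(-mu * L)) / sum(W * sp$fluence))
  expect_equal(p2, oracle, tolerance = 0.02)
})

test_that("FBP is linear and zero-preserving", {
  cx <- fx_coarse()
  wd <- fx_water_disc()
  p <- log_normalize(wd$sino, 2)
  z <- fbp_fan(p * 0, cx$prof$geometry, cx$det$col_factor,
               n_out = cx$prof$recon_n)
  expect_true(all(z == 0))
  f1 <- fbp_fan(p, cx$prof$geometry, cx$det$col_factor,
                n_out = cx$prof$recon_n)
  f3 <- fbp_fan(3 * p, cx$prof$geometry, cx$det$col_factor,
                n_out = cx$prof$recon_n)
  expect_equal(f3, 3 * f1, tolerance = 1e-10)
  expect_error(fbp_fan(p[1, , drop = FALSE], cx$prof$geometry), "views")
})

test_that("a noiseless water disc reconstructs to its effective mu", {
  cx <- fx_coarse()
  wd <- fx_water_disc()
  roi <- roi_spec("c", "tissue", c(0, 0), 25)
  for (ch in list(2, 3)) {   # narrow/high bins: negligible hardening
    mu <- fbp_fan(log_normalize(wd$sino, ch), cx$prof$geometry,
                  cx$det$col_factor, n_out = cx$prof$recon_n)
    oracle <- effective_mu("water", fx_spectrum(), cx$bins, cx$det,
                           channel = ch)
    expect_equal(pcctsim:::.roi_mean(mu, roi, cx$px), oracle,
                 tolerance = 0.02)
  }
})

test_that("water calibration closes to zero HU in every channel", {
  cx <- fx_coarse()
  cal <- fx_coarse_cal()
  ph <- make_insert_phantom(iodine_concs = numeric(0),
                            calcium_concs = numeric(0),
                            n_water_inserts = 0, body_radius_mm = 100,
                            n = cx$prof$render_n)
  paths <- project_material_paths(ph, cx$prof$geometry)
  sino <- simulate_scan(ph, cx$prof$geometry, fx_spectrum(), cx$bins,
                        cx$det, noise = FALSE, paths = paths)
  imgs <- reconstruct_all(sino, cal)
  roi <- roi_spec("c", "tissue", c(0, 0), 30)
  for (nm in names(imgs))
    expect_lt(abs(roi_stats(imgs[[nm]], roi)$mean), 10)
  eid <- simulate_scan_eid(ph, cx$prof$geometry, fx_spectrum(), cx$det,
                           noise = FALSE, paths = paths)
  eimg <- reconstruct_eid(eid, cal)
  expect_lt(abs(roi_stats(eimg, roi)$mean), 10)
  # air background reconstructs near -1000 HU
  corner <- roi_spec("air", "tissue", c(0, -115), 6)
  expect_lt(abs(roi_stats(imgs$total, corner)$mean + 1000), 30)
})

test_that("reconstruction requires a water calibration", {
  wd <- fx_water_disc()
  expect_error(reconstruct_all(wd$sino), "calibration")
})

test_that("iodine contrast falls from bin 1 to bin 3", {
  cx <- fx_coarse()
  cal <- fx_coarse_cal()
  ph <- make_insert_phantom(iodine_concs = 10, calcium_concs = numeric(0),
                            n_water_inserts = 0, n = cx$prof$render_n)
  sino <- simulate_scan(ph, cx$prof$geometry, fx_spectrum(), cx$bins,
                        cx$det, noise = FALSE)
  imgs <- reconstruct_all(sino, cal)
  roi <- ph$rois[[1]]
  expect_gt(roi_stats(imgs$bin1, roi)$mean, roi_stats(imgs$bin3, roi)$mean)
})

test_that("image noise falls monotonically with exposure", {
  cx <- fx_coarse()
  cal <- fx_coarse_cal()
  wd <- fx_water_disc()
  roi <- roi_spec("c", "tissue", c(0, 0), 25)
  sds <- vapply(c(3.5, 7, 14, 28), function(mas) {
    sino <- simulate_scan(wd$phantom, cx$prof$geometry,
                          generate_tube_spectrum(mas = mas), cx$bins,
                          cx$det, seed = 77, paths = wd$paths)
    img <- reconstruct_all(sino, cal)$total
    roi_stats(img, roi)$sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})
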