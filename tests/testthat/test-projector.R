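# Forward model: path projection, polychromatic bin counts, Poisson
# sampling, detector binning, EID mode.

test_that("central ray through a centered disc measures its diameter", {
  cx <- fx_coarse()
  wd <- fx_water_disc()
  gam <- pcctsim:::.fan_angles(cx$prof$geometry$n_cols,
                               cx$prof$geometry$dgamma)
  ic <- which.min(abs(gam))
  # 80 mm radius -> 16 cm chord, up to edge pixelization of the render grid
  expect_equal(unname(wd$paths[1, ic, "water"]), 16, tolerance = 0.01)
  # rays outside the disc miss entirely
  expect_equal(unname(wd$paths[1, 1, "water"]), 0)
  expect_equal(unname(wd$paths[1, dim(wd$paths)[2], "water"]), 0)
})

test_that("projection is linear in the phantom content", {
  cx <- fx_coarse()
  ph <- make_insert_phantom(iodine_concs = numeric(0),
                            calcium_concs = numeric(0),
                            n_water_inserts = 0, body_radius_mm = 60,
                            n = cx$prof$render_n)
  half <- ph
  half$materials$water <- 0.5 * ph$materials$water
  p1 <- project_material_paths(ph, cx$prof$geometry)
  p2 <- project_material_paths(half, cx$prof$geometry)
  expect_equal(p2, 0.5 * p1, tolerance = 1e-12)
})

test_that("air scan reproduces the binned incident fluence", {
  cx <- fx_coarse()
  sp <- fx_spectrum()
  paths <- array(0, c(4, 6, 1), dimnames = list(NULL, NULL, "water"))
  counts <- expected_bin_counts(paths, sp, cx$bins, cx$det)
  W <- pcctsim:::.bin_weights(sp$energies, cx$bins,
                              cx$det$energy_sigma_keV)
  oracle <- colSums(W * sp$fluence)
  for (b in 1:3) expect_equal(unique(as.vector(counts[, , b])), oracle[b])
})

test_that("zero energy resolution reduces to sharp threshold sums", {
  sp <- fx_spectrum()
  bins <- energy_bins()
  det0 <- detector_config(energy_sigma_keV = 0)
  paths <- array(0.5, c(2, 2, 1), dimnames = list(NULL, NULL, "water"))
  counts <- expected_bin_counts(paths, sp, bins, det0)
  mu <- mass_attenuation("water", sp$energies)
  NE <- sp$fluence * exp(-mu * 0.5)
  E <- sp$energies
  sharp <- c(sum(NE[E >= 30 & E < 50]), sum(NE[E >= 50 & E < 65]),
             sum(NE[E >= 65 & E <= 140]))
  expect_equal(as.vector(counts[1, 1, ]), sharp)
})

test_that("bin additivity: three bins equal one wide bin to 1e-9", {
  sp <- fx_spectrum()
  det <- detector_config()
  set.seed(7)
  paths <- array(stats::runif(2 * 3 * 2, 0, 5), c(2, 3, 2),
                 dimnames = list(NULL, NULL, c("water", "iodine")))
  three <- expected_bin_counts(paths, sp, energy_bins(), det)
  wide <- expected_bin_counts(paths, sp, energy_bins(c(30, 140)), det)
  expect_equal(rowSums(three, dims = 2), wide[, , 1],
               tolerance = 1e-9)
})

test_that("adding material along a ray never increases any bin count", {
  sp <- fx_spectrum()
  det <- detector_config()
  base <- array(1, c(1, 1, 1), dimnames = list(NULL, NULL, "water"))
  more <- base; more[] <- 2
  expect_true(all(expected_bin_counts(more, sp, energy_bins(), det) <=
                    expected_bin_counts(base, sp, energy_bins(), det)))
})

test_that("bins outside the spectrum support are rejected", {
  sp <- generate_tube_spectrum(kvp = 120)
  paths <- array(0, c(1, 1, 1), dimnames = list(NULL, NULL, "water"))
  expect_error(expected_bin_counts(paths, sp, energy_bins(c(30, 50, 65, 140)),
                                   detector_config()), "support")
})

test_that("Poisson sampling: zero mean, saturation, moment recovery", {
  det <- detector_config()
  expect_equal(counter_saturation(det), c(16383L, 8191L, 4095L))
  z <- array(0, c(5, 5, 3))
  expect_true(all(sample_counts(z, det, seed = 1) == 0))
  # saturation clip: enormous expected counts clip at 2^bits - 1 per bin
  big <- array(1e7, c(2, 2, 3))
  clipped <- sample_counts(big, det, seed = 1)
  for (b in 1:3)
    expect_true(all(clipped[, , b] == counter_saturation(det)[b]))
  # sample mean of 10,000 draws at expected 100 within 3 standard errors
  e <- array(100, c(100, 100, 1))
  draws <- sample_counts(e, detector_config(bit_depths = 20), seed = 42)
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / length(draws)))
  # variance/mean ratio near 1 (Poisson property)
  expect_gt(stats::var(as.vector(draws)) / mean(draws), 0.9)
  expect_lt(stats::var(as.vector(draws)) / mean(draws), 1.1)
  # reproducible under the same seed
  expect_identical(sample_counts(e, det, seed = 9),
                   sample_counts(e, det, seed = 9))
})

test_that("detector binning sums blocks and conserves counts", {
  set.seed(3)
  native <- array(stats::rpois(80 * 96 * 3, 20), c(80, 96, 3))
  std <- apply_binning(native, "standard")
  expect_equal(dim(std), c(16L, 16L, 3L))
  expect_equal(sum(std), sum(native))
  expect_equal(apply_binning(native, "hr"), native)
  expect_equal(std[1, 1, 1], sum(native[1:5, 1:6, 1]))
  expect_error(apply_binning(array(0, c(7, 6, 1)), "standard"), "divide")
  # the physical assembly: 80 x 2304 native -> 16 slices x 384 columns
  g <- scanner_geometry()
  expect_equal(n_slices(g, "standard"), 16L)
  expect_equal(g$n_cols / 6, 384)
})

test_that("effective pixel sizes at the isocenter match the system", {
  g <- scanner_geometry()
  expect_equal(effective_pixel_at_iso(g, "standard", "z"), 0.640,
               tolerance = 1e-4)
  expect_equal(effective_pixel_at_iso(g, "hr", "z"), 0.128,
               tolerance = 1e-4)
  expect_equal(effective_pixel_at_iso(g, "hr", "z"),
               effective_pixel_at_iso(g, "standard", "z") / 5)
  # z-coverage self-consistency: slice thickness x slices = row pitch
  # footprint of all 80 rows scaled to the isocenter
  expect_equal(effective_pixel_at_iso(g, "standard", "z") * 16,
               g$row_pitch_mm * 80 * g$sid_mm / g$sdd_mm)
})

test_that("EID signal matches its closed forms", {
  sp <- fx_spectrum()
  det <- detector_config()
  paths0 <- array(0, c(2, 2, 1), dimnames = list(NULL, NULL, "water"))
  eid <- simulate_eid(paths0, sp, det)
  expect_equal(unique(as.vector(eid$signal)),
               sum(sp$energies * sp$fluence))
  # monoenergetic spectrum: EID signal = E0 x photon count
  spm <- sp
  spm$fluence <- ifelse(spm$energies == 70, 1000, 0)
  eidm <- simulate_eid(paths0, spm, det)
  expect_equal(unique(as.vector(eidm$signal)), 70 * 1000)
})

test_that("scans are reproducible and truncation warns", {
  cx <- fx_coarse()
  ph <- make_insert_phantom(iodine_concs = 5, calcium_concs = numeric(0),
                            n_water_inserts = 0, body_radius_mm = 50,
                            n = cx$prof$render_n)
  s1 <- simulate_scan(ph, cx$prof$geometry, fx_spectrum(), cx$bins, cx$det,
                      seed = 5)
  s2 <- simulate_scan(ph, cx$prof$geometry, fx_spectrum(), cx$bins, cx$det,
                      seed = 5)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0))
  # air reference dominates the object scan in expectation
  s0 <- simulate_scan(ph, cx$prof$geometry, fx_spectrum(), cx$bins, cx$det,
                      noise = FALSE)
  expect_true(all(s0$counts <= s0$air + 1e-9))
  big <- ph; big$fov_mm <- 400; big$pixel_mm <- 400 / big$n
  expect_warning(project_material_paths(big, cx$prof$geometry),
                 "truncat")
})
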