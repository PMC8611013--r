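# Digital phantom construction and ROI layouts.

test_that("insert phantom emits one training ROI per insert", {
  ph <- make_insert_phantom(n = 314)
  rois <- Filter(function(r) r$role == "training-material", ph$rois)
  expect_length(rois, 7)   # 3 iodine + 3 calcium + 1 water
  expect_setequal(unique(vapply(rois, `[[`, "", "material")),
                  c("iodine", "calcium", "water"))
})

test_that("phantom fraction maps are bounded and sum to at most one", {
  for (ph in list(make_insert_phantom(n = 314),
                  make_brain_phantom(n = 314),
                  make_liver_phantom(n = 314),
                  make_bar_phantom(n = 320, fov_mm = 64))) {
    tot <- Reduce(`+`, ph$materials)
    expect_true(all(tot <= 1 + 1e-12), info = ph$name)
    expect_true(all(tot >= 0), info = ph$name)
    for (m in ph$materials) expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("zero inserts give a uniform water cylinder", {
  ph <- make_insert_phantom(iodine_concs = numeric(0),
                            calcium_concs = numeric(0),
                            n_water_inserts = 0, n = 314)
  expect_named(ph$materials, "water")
  inside <- ph$materials$water > 0
  expect_true(all(ph$materials$water[inside] == 1))
  expect_length(ph$rois, 0)
})

test_that("overlapping insert layouts are rejected", {
  expect_error(make_insert_phantom(iodine_concs = rep(5, 10),
                                   calcium_concs = rep(50, 10),
                                   insert_radius_mm = 20,
                                   ring_radius_mm = 40, n = 314),
               "overlap")
})

test_that("phantoms regenerate bitwise identically", {
  a <- make_liver_phantom(n = 314, seed = 3)
  b <- make_liver_phantom(n = 314, seed = 3)
  expect_identical(a$materials, b$materials)
  c1 <- make_brain_phantom(n = 314)
  c2 <- make_brain_phantom(n = 314)
  expect_identical(c1$materials, c2$materials)
})

test_that("every ROI lies strictly inside its labeled region", {
  px_checks <- list(
    list(ph = make_insert_phantom(n = 626), region = NULL),
    list(ph = make_liver_phantom(n = 626), region = NULL))
  # insert ROIs: all pixels of the ROI disc carry the ROI's material
  ph <- make_insert_phantom(n = 626)
  g <- expand.grid(r = seq_len(ph$n), c = seq_len(ph$n))
  for (roi in ph$rois) {
    mask <- pcctsim:::.roi_mask(ph$n, ph$pixel_mm, roi)
    frac <- ph$materials[[roi$material]][mask]
    expect_true(all(frac > 0), info = roi$label)
  }
  # liver: tumor ROI inside the tumor disc, muscle ROI inside muscle
  ph <- make_liver_phantom(n = 626)
  mus <- ph$rois[[which(vapply(ph$rois, `[[`, "", "label") == "muscle")]]
  mask <- pcctsim:::.roi_mask(ph$n, ph$pixel_mm, mus)
  expect_true(all(ph$materials$muscle[mask] == 1))
})

test_that("brain phantom has the expected structure", {
  ph <- make_brain_phantom(n = 314)
  tr <- Filter(function(r) r$role == "training-material", ph$rois)
  expect_length(tr, 2)
  expect_setequal(vapply(tr, `[[`, "", "material"),
                  c("white_matter", "gray_matter"))
  # skull pixels are pure bone
  skull <- ph$materials$cortical_bone > 0
  expect_true(all(ph$materials$cortical_bone[skull] == 1))
  brainy <- ph$materials$white_matter + ph$materials$gray_matter
  expect_true(all(brainy[skull] == 0))
  # no-contrast phantom is identical outside vessels
  ph0 <- make_brain_phantom(vessel_iodine_mg_ml = 0, n = 314)
  expect_null(ph0$materials$iodine)
  vessel <- !is.null(ph$materials$iodine) & ph$materials$iodine > 0
  for (m in c("cortical_bone", "muscle"))
    expect_identical(ph$materials[[m]], ph0$materials[[m]])
  expect_identical(ph$materials$white_matter[!vessel],
                   ph0$materials$white_matter[!vessel])
})

test_that("liver rim attenuation collapses to the core when not enhanced", {
  ph <- make_liver_phantom(iodine_rim_mg_ml = 0, n = 314)
  mu45 <- phantom_mu(ph, 45)
  g <- pcctsim:::.coord_grids(ph)
  rim <- pcctsim:::.disc_mask(g, c(-25, 12), 12) &
    !pcctsim:::.disc_mask(g, c(-25, 12), 9)
  core <- pcctsim:::.disc_mask(g, c(-25, 12), 8)
  expect_equal(unique(mu45[rim]), unique(mu45[core]))
})

test_that("iodinated aorta shows the expected spectral drop", {
  ph <- make_liver_phantom(n = 314)
  g <- pcctsim:::.coord_grids(ph)
  aorta <- pcctsim:::.disc_mask(g, c(0, -28), 3)
  d_aorta <- mean(phantom_mu(ph, 45)[aorta]) - mean(phantom_mu(ph, 75)[aorta])
  d_water <- linear_attenuation(c(water = 1), 45) -
    linear_attenuation(c(water = 1), 75)
  expect_gt(d_aorta, d_water)
  # oracle: direct mixture evaluation at the aorta's composition
  f <- pcctsim:::.solution("iodine", 8)
  expect_equal(mean(phantom_mu(ph, 45)[aorta]),
               linear_attenuation(f, 45), tolerance = 1e-9)
})

test_that("bar phantom honours widths and occupancy", {
  ph <- make_bar_phantom(bar_width_mm = 0.5, n = 640, fov_mm = 64)
  expect_equal(ph$bar_spec$bar_width_mm, 0.5)
  # 0.5 mm bars on a 0.1 mm grid are 5 pixels wide
  bone <- ph$materials$cortical_bone
  row <- bone[nrow(bone) / 2, ]
  runs <- rle(row > 0)
  expect_true(all(runs$lengths[runs$values] == 5))
  # occupancy of the pattern window is one half up to pixel quantization
  g <- pcctsim:::.coord_grids(ph)
  win <- abs(g$y) <= 10 & abs(g$x) <= 8 * 0.5
  expect_equal(mean(bone[win] > 0), 0.5, tolerance = 0.01)
  expect_error(make_bar_phantom(bar_width_mm = 0.05, n = 640, fov_mm = 64),
               "narrower")
})
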