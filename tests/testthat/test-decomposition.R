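# Training-set extraction, network training, per-pixel decomposition,
# model persistence.

# tiny synthetic images: three "bins" with known per-region values
make_synthetic_images <- function(n = 80, px = 1) {
  vals <- list(a = c(100, 60, 20), b = c(-50, -30, -10), c = c(0, 0, 0))
  imgs <- lapply(1:3, function(b) matrix(vals$c[b], n, n))
  # left block material a, right block material b
  for (b in 1:3) {
    imgs[[b]][, 1:30] <- vals$a[b]
    imgs[[b]][, 51:80] <- vals$b[b]
  }
  rois <- list(
    roi_spec("a", "training-material", c(-25, 0), 8, material = "iodine",
             conc = 10),
    roi_spec("b", "training-material", c(25, 0), 8, material = "calcium",
             conc = 100),
    roi_spec("c", "training-material", c(0, 25), 8, material = "water"))
  list(images = imgs, rois = rois, px = px, n = n)
}

test_that("training-set bookkeeping matches the ROI arithmetic", {
  s <- make_synthetic_images()
  ts <- extract_training_set(s$images, s$rois, pixel_mm = s$px,
                             side_px = 15L)
  expect_equal(nrow(ts$X), 15^2 * 3)
  expect_equal(ts$n_units, 15^2 * 3 * 3)
  expect_equal(ncol(ts$X), 3)
  expect_equal(ncol(ts$Y), 3)
  # 25 x 25 ROIs: 625 units per ROI per bin; 9 ROIs x 3 bins = 16,875
  s2 <- make_synthetic_images(n = 200)
  rois9 <- lapply(1:9, function(i)
    roi_spec(paste0("r", i), "training-material",
             c(-60 + 15 * i, 0), 10,
             material = c("iodine", "calcium", "water")[1 + i %% 3]))
  ts9 <- extract_training_set(s2$images, rois9, pixel_mm = 1,
                              side_px = 25L)
  expect_equal(ts9$n_units, 16875)
  expect_equal(nrow(ts9$X), 5625)
  expect_equal(extract_training_set(s$images, s$rois[3], pixel_mm = s$px,
                                    side_px = 25L)$n_units / 3, 625)
  expect_error(extract_training_set(s$images, list(
    roi_spec("out", "training-material", c(39, 0), 5,
             material = "water")), pixel_mm = s$px, side_px = 15L),
    "outside")
})

test_that("solute targets scale with concentration, tissues are one-hot", {
  s <- make_synthetic_images()
  rois <- c(s$rois, list(
    roi_spec("a2", "training-material", c(-25, 20), 5, material = "iodine",
             conc = 5)))
  ts <- extract_training_set(s$images, rois, pixel_mm = s$px, side_px = 9L)
  i <- match("iodine", ts$materials)
  ya <- ts$Y[ts$X[, 1] == 100, i]
  expect_setequal(unique(ya), c(0.5, 1))   # conc 5 and 10, cmax 10
  w <- match("water", ts$materials)
  expect_true(all(ts$Y[ts$X[, 1] == 0, w] == 1))
  # explicit channel list: unlisted materials train the background
  ts0 <- extract_training_set(s$images, s$rois, pixel_mm = s$px,
                              side_px = 9L,
                              materials = c("iodine", "calcium"))
  expect_equal(ncol(ts0$Y), 2)
  expect_true(all(ts0$Y[ts0$X[, 1] == 0, ] == 0))
})

test_that("training decreases the loss and is reproducible", {
  s <- make_synthetic_images()
  ts <- extract_training_set(s$images, s$rois, pixel_mm = s$px,
                             side_px = 9L)
  cfg <- training_config(epochs = 300, hidden_width = 8L, seed = 4L)
  m1 <- train_decomposition(ts, cfg)
  expect_length(m1$loss_history, 300)
  expect_lt(m1$loss_history[300], m1$loss_history[1])
  m2 <- train_decomposition(ts, cfg)
  expect_identical(m1$W, m2$W)
  # zero learning rate leaves the weights at their initialization
  m0 <- train_decomposition(ts, training_config(learning_rate = 0,
                                                epochs = 20,
                                                hidden_width = 8L,
                                                seed = 4L))
  expect_equal(length(unique(round(m0$loss_history, 12))), 1)
  init <- pcctsim:::.init_mlp(3, 8L, 3, 4L)
  expect_identical(m0$W, init$W)
  # single-class training sets are degenerate
  ts1 <- extract_training_set(s$images, s$rois[3], pixel_mm = s$px,
                              side_px = 9L)
  expect_error(train_decomposition(ts1, cfg), "degenerate")
})

test_that("a linearly realizable map trains to near-zero error", {
  set.seed(5)
  X <- matrix(stats::rnorm(900), ncol = 3)
  ts <- structure(list(X = X, Y = X, materials = c("a", "b", "c"),
                       n_units = nrow(X) * 3), class = "training_set")
  m <- train_decomposition(ts, training_config(hidden_width = 32L,
                                               seed = 2L))
  expect_lt(utils::tail(m$loss_history, 1), 1e-3)
})

test_that("per-pixel decomposition has the right shape and zero map", {
  # zero-bias model on all-zero input yields all-zero maps
  net <- pcctsim:::.init_mlp(3, 8L, 4L, seed = 1L)
  model <- structure(list(W = net$W, b = net$b, widths = net$widths,
                          materials = c("iodine", "calcium",
                                        "white_matter", "gray_matter"),
                          norm = list(mean = rep(0, 3), sd = rep(1, 3)),
                          config = NULL, loss_history = numeric()),
                     class = "mlp_model")
  imgs <- lapply(1:3, function(i) matrix(0, 625, 625))
  maps <- decompose(imgs, model)
  expect_equal(dim(maps), c(625L, 625L, 4L))
  expect_true(all(maps == 0))
  expect_equal(dimnames(maps)[[3]][1], "iodine")
  expect_error(decompose(imgs[1:2], model), "bins")
  expect_error(material_map(maps, "bone"), "channel")
})

test_that("noiseless train/apply closure labels ROI pixels correctly", {
  fx <- fx_insert_noiseless()
  m <- fx_insert_model()
  # loss converges far below its starting value on the noiseless set
  expect_lt(utils::tail(m$loss_history, 1), 0.1 * m$loss_history[1])
  Xs <- sweep(sweep(fx$ts$X, 2, m$norm$mean), 2, m$norm$sd, "/")
  pred <- pcctsim:::.mlp_forward(m, Xs)
  acc <- mean(apply(pred, 1, which.max) == apply(fx$ts$Y, 1, which.max))
  expect_gte(acc, 0.99)
})

test_that("iodine scores rise with concentration on noiseless inserts", {
  fx <- fx_insert_noiseless()
  m <- fx_insert_model()
  maps <- decompose(fx$images[1:3], m)
  io <- material_map(maps, "iodine")
  rx <- fx_reduced()
  scores <- vapply(fx$phantom$rois[1:3], function(r)
    roi_stats(io, r, rx$px)$mean, numeric(1))
  expect_true(all(diff(scores) > 0))   # 2, 5, 10 mg/mL
})

test_that("models survive a save/load round-trip bitwise", {
  s <- make_synthetic_images()
  ts <- extract_training_set(s$images, s$rois, pixel_mm = s$px,
                             side_px = 9L)
  m <- train_decomposition(ts, training_config(epochs = 50,
                                               hidden_width = 8L,
                                               seed = 6L))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  X <- matrix(stats::rnorm(30), ncol = 3)
  expect_identical(pcctsim:::.mlp_forward(m, X),
                   pcctsim:::.mlp_forward(back, X))
  expect_equal(back$loss_history, m$loss_history)
  # corrupted files raise a format error, not a crash
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_model(bad), "format")
  writeLines('{"format": "something-else"}', bad)
  expect_error(load_model(bad), "format")
})
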