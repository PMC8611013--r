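# Per-pixel neural-network material decomposition.
#
# An eight-hidden-layer ReLU network maps each pixel's per-bin HU values
# to per-material scores. Training samples come from 25 x 25 pixel ROIs
# drawn on reconstructed images of materials with known identity. Tissue
# targets are one-hot; solute targets (iodine, calcium) are scaled to the
# normalised concentration c / c_max, so the learned channels behave as
# concentration maps and grow monotonically with solute content.

#' Extract a per-pixel training set from ROIs
#'
#' One sample per ROI pixel; the feature vector holds that pixel's value
#' in each energy bin. The scalar data unit count is
#' `side^2 x n_rois x n_bins` (25 x 25 x 9 ROIs x 3 bins = 16,875 with the
#' defaults).
#'
#' @param images List of per-bin images (`recon_image` or plain matrices),
#'   one per energy bin, identical grids.
#' @param rois List of `roi_spec` with `material` set; axis-aligned
#'   `side_px` squares centered on each ROI center are extracted.
#' @param pixel_mm Image pixel size (taken from the first `recon_image` if
#'   available).
#' @param side_px Square ROI side in pixels (default 25).
#' @param materials Output channel names. Defaults to the distinct ROI
#'   materials; when given explicitly, ROIs whose material is not listed
#'   (e.g. plain water) train the background with an all-zero target.
#' @return A `training_set`: `X` (samples x bins), `Y` (samples x
#'   materials), `materials`, `provenance`, `n_units`.
#' @export
extract_training_set <- function(images, rois, pixel_mm = NULL,
                                 side_px = 25L, materials = NULL) {
  mats <- lapply(images, function(im) if (inherits(im, "recon_image"))
    im$hu else im)
  if (is.null(pixel_mm)) {
    if (inherits(images[[1]], "recon_image")) pixel_mm <- images[[1]]$pixel_mm
    else stop("pixel_mm required for plain-matrix images", call. = FALSE)
  }
  n <- nrow(mats[[1]])
  for (m in mats) stopifnot(identical(dim(m), c(n, n)))
  half <- side_px %/% 2L

  roi_mats <- vapply(rois, function(r) r$material, "")
  if (anyNA(roi_mats)) stop("every training ROI needs a material label",
                            call. = FALSE)
  if (is.null(materials)) materials <- unique(roi_mats)
  # per-material maximum concentration, for concentration-scaled targets
  cmax <- vapply(materials, function(m) {
    cc <- vapply(Filter(function(r) r$material == m, rois),
                 function(r) r$conc, numeric(1))
    max(c(cc, 0), na.rm = TRUE)
  }, numeric(1))

  X_list <- Y_list <- prov <- list()
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    col <- round(r$center_mm[1] / pixel_mm + (n + 1) / 2)
    row <- round((n + 1) / 2 - r$center_mm[2] / pixel_mm)
    rr <- (row - half):(row - half + side_px - 1L)
    cc <- (col - half):(col - half + side_px - 1L)
    if (min(rr) < 1 || min(cc) < 1 || max(rr) > n || max(cc) > n)
      stop("ROI '", r$label, "' extends outside the image", call. = FALSE)
    feat <- sapply(mats, function(m) as.vector(m[rr, cc]))
    y <- matrix(0, nrow(feat), length(materials))
    j <- match(r$material, materials)
    conc <- r$conc
    if (!is.na(j))
      y[, j] <- if (is.na(conc) || cmax[j] == 0) 1 else conc / cmax[j]
    X_list[[i]] <- feat
    Y_list[[i]] <- y
    prov[[i]] <- data.frame(roi = r$label, material = r$material,
                            n_px = nrow(feat))
  }
  X <- do.call(rbind, X_list)
  structure(list(X = X, Y = do.call(rbind, Y_list),
                 materials = materials,
                 provenance = do.call(rbind, prov),
                 n_units = side_px^2 * length(rois) * length(mats),
                 side_px = side_px),
            class = "training_set")
}

#' Export a training set to CSV (one row per sample)
#' @param ts A `training_set`.
#' @param path Output file.
#' @export
write_training_csv <- function(ts, path) {
  df <- cbind(as.data.frame(ts$X), as.data.frame(ts$Y))
  names(df) <- c(paste0("bin", seq_len(ncol(ts$X))), ts$materials)
  .atomic_write(path, function(tmp) utils::write.csv(df, tmp,
                                                     row.names = FALSE))
  invisible(path)
}

#' Training configuration
#'
#' @param learning_rate Gradient-descent learning rate (default 0.00005).
#' @param epochs Training epochs (default 4500).
#' @param hidden_width Width of each of the 8 hidden layers.
#' @param optimizer `"adam"` or `"gd"` (plain full-batch gradient
#'   descent).
#' @param seed Weight-initialisation seed.
#' @export
training_config <- function(learning_rate = 0.00005, epochs = 4500,
                            hidden_width = 64L,
                            optimizer = c("adam", "gd"), seed = 1L) {
  stopifnot(learning_rate >= 0, epochs >= 1)
  list(learning_rate = learning_rate, epochs = as.integer(epochs),
       hidden_width = as.integer(hidden_width),
       optimizer = match.arg(optimizer), seed = as.integer(seed))
}

.relu <- function(x) (x + abs(x)) / 2

# Glorot (Xavier) scaled-uniform initialisation, zero biases. The small
# initial weights bias the deep ReLU stack toward near-linear solutions,
# which extrapolate stably to tissue mixtures outside the training hull.
.init_mlp <- function(n_in, hidden_width, n_out, seed, n_hidden = 8L) {
  set.seed(seed)
  widths <- c(n_in, rep(hidden_width, n_hidden), n_out)
  W <- b <- vector("list", length(widths) - 1)
  for (l in seq_along(W)) {
    a <- sqrt(6 / (widths[l] + widths[l + 1]))
    W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1], -a, a),
                     widths[l], widths[l + 1])
    b[[l]] <- numeric(widths[l + 1])
  }
  list(W = W, b = b, widths = widths)
}

.mlp_forward <- function(model, Xs) {
  A <- Xs
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    A <- sweep(A %*% model$W[[l]], 2, model$b[[l]], `+`)
    if (l < nl) A <- .relu(A)
  }
  A
}

#' Train the material-decomposition network
#'
#' Full-batch minimisation of the mean squared error between the network
#' output and the material target vectors, for exactly the configured
#' number of epochs. Hidden layers use ReLU; the output layer is linear.
#' Reproducible given the configuration seed.
#'
#' @param ts A `training_set` (at least two distinct material labels).
#' @param cfg A [training_config()].
#' @return An `mlp_model` with weights, feature-normalisation constants,
#'   material names, and the per-epoch `loss_history`.
#' @export
train_decomposition <- function(ts, cfg = training_config()) {
  if (length(ts$materials) < 2)
    stop("degenerate training set: need at least two distinct materials",
         call. = FALSE)
  mu <- colMeans(ts$X)
  sd <- apply(ts$X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  Xs <- sweep(sweep(ts$X, 2, mu), 2, sd, `/`)
  Y <- ts$Y
  n <- nrow(Xs)
  net <- .init_mlp(ncol(Xs), cfg$hidden_width, ncol(Y), cfg$seed)
  nl <- length(net$W)
  loss_history <- numeric(cfg$epochs)
  adam <- cfg$optimizer == "adam"
  if (adam) {
    mW <- vW <- lapply(net$W, function(w) w * 0)
    mb <- vb <- lapply(net$b, function(x) x * 0)
    b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  }
  lr <- cfg$learning_rate
  for (ep in seq_len(cfg$epochs)) {
    # forward with cached activations
    A <- vector("list", nl + 1); Z <- vector("list", nl)
    A[[1]] <- Xs
    for (l in seq_len(nl)) {
      Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
      A[[l + 1]] <- if (l < nl) .relu(Z[[l]]) else Z[[l]]
    }
    err <- A[[nl + 1]] - Y
    loss_history[ep] <- mean(err^2)
    delta <- 2 * err / length(err)
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(A[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(net$W[[l]])) * (Z[[l - 1]] > 0)
      if (adam) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
        net$W[[l]] <- net$W[[l]] -
          lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + epsa)
        net$b[[l]] <- net$b[[l]] -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + epsa)
      } else {
        net$W[[l]] <- net$W[[l]] - lr * gW
        net$b[[l]] <- net$b[[l]] - lr * gb
      }
    }
  }
  structure(list(W = net$W, b = net$b, widths = net$widths,
                 materials = ts$materials,
                 norm = list(mean = mu, sd = sd),
                 config = cfg, loss_history = loss_history),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s  (%d hidden layers, width %d)\n",
              paste(x$widths, collapse = "-"), length(x$W) - 1,
              x$widths[2]))
  cat("  materials:", paste(x$materials, collapse = ", "), "\n")
  if (length(x$loss_history))
    cat(sprintf("  final loss %.3g (initial %.3g)\n",
                utils::tail(x$loss_history, 1), x$loss_history[1]))
  invisible(x)
}

#' Apply the decomposition network pixelwise
#'
#' Reshapes the per-bin images to one sample per pixel, runs the forward
#' pass, and reshapes the outputs to one map per material. The iodine map
#' is the `"iodine"` channel of the result.
#'
#' @param images List of per-bin images (`recon_image` or matrices), in
#'   the bin order the model was trained on.
#' @param model An `mlp_model`.
#' @return A `material_maps` object: array `n x n x n_materials` with
#'   material names on the third dimension.
#' @export
decompose <- function(images, model) {
  mats <- lapply(images, function(im) if (inherits(im, "recon_image"))
    im$hu else im)
  if (length(mats) != model$widths[1])
    stop("model expects ", model$widths[1], " energy bins, got ",
         length(mats), call. = FALSE)
  n <- nrow(mats[[1]])
  for (m in mats)
    if (!identical(dim(m), c(n, n)))
      stop("per-bin images must share one grid", call. = FALSE)
  X <- sapply(mats, as.vector)
  Xs <- sweep(sweep(X, 2, model$norm$mean), 2, model$norm$sd, `/`)
  out <- .mlp_forward(model, Xs)
  maps <- array(out, c(n, n, ncol(out)),
                dimnames = list(NULL, NULL, model$materials))
  structure(maps, class = c("material_maps", "array"))
}

#' Extract one material's score map
#' @param maps A `material_maps`.
#' @param material Material name (e.g. `"iodine"`).
#' @return Matrix of per-pixel scores.
#' @export
material_map <- function(maps, material) {
  if (!material %in% dimnames(maps)[[3]])
    stop("no '", material, "' channel in maps", call. = FALSE)
  maps[, , material]
}

#' Save a decomposition model (JSON, lossless round-trip)
#' @param model An `mlp_model`.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  # weights and normalisation constants serialize as %.17g strings:
  # 17 significant digits round-trip IEEE-754 doubles exactly, so the
  # reloaded forward pass is bitwise identical
  num <- function(x) sprintf("%.17g", x)
  obj <- list(format = "pcctsim-mlp", version = 1L,
              widths = model$widths, materials = model$materials,
              norm = list(mean = num(model$norm$mean),
                          sd = num(model$norm$sd)),
              W = lapply(model$W, function(w)
                list(dim = dim(w), data = num(as.vector(w)))),
              b = lapply(model$b, num), config = model$config,
              loss_history = model$loss_history)
  .atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Load a decomposition model saved by [save_model()]
#' @param path Model file.
#' @return An `mlp_model` whose forward pass is identical to the saved
#'   model's.
#' @export
load_model <- function(path) {
  obj <- tryCatch(suppressWarnings(jsonlite::read_json(path)),
                  error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "pcctsim-mlp"))
    stop("model format error: ", path, " is not a pcctsim MLP file",
         call. = FALSE)
  if (!identical(as.integer(obj$version), 1L))
    stop("model format error: unsupported version ", obj$version,
         call. = FALSE)
  nums <- function(x) as.numeric(unlist(x))
  W <- lapply(obj$W, function(w) {
    d <- as.integer(unlist(w$dim))
    matrix(nums(w$data), d[1], d[2])
  })
  structure(list(W = W, b = lapply(obj$b, nums),
                 widths = as.integer(unlist(obj$widths)),
                 materials = as.character(unlist(obj$materials)),
                 norm = list(mean = nums(obj$norm$mean),
                             sd = nums(obj$norm$sd)),
                 config = obj$config,
                 loss_history = nums(obj$loss_history)),
            class = "mlp_model")
}
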