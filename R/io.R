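# File round-trips: NIfTI images with JSON sidecars, sinogram
# persistence, PNG previews. All writes are atomic
# (write-temp-then-rename) so interrupted runs never leave truncated
# files.

.atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp-",
                                                           basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Write a reconstructed image as NIfTI with a JSON sidecar
#'
#' @param image A `recon_image` (or a plain matrix with `pixel_mm`
#'   given).
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param pixel_mm Pixel size for plain matrices.
#' @export
write_recon_nifti <- function(image, path, pixel_mm = NULL) {
  mat <- .image_matrix(image)
  px <- .image_pixel(image, pixel_mm)
  .atomic_write(path, function(tmp)
    RNifti::writeNifti(RNifti::asNifti(mat, pixdim = c(px, px)), tmp))
  meta <- list(pixel_mm = px,
               channel = if (inherits(image, "recon_image"))
                 image$channel else "image",
               filter = if (inherits(image, "recon_image"))
                 image$filter else NULL,
               units = "HU")
  .atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read an image written by [write_recon_nifti()]
#' @param path NIfTI path.
#' @return A `recon_image` (geometry slot empty).
#' @export
read_recon_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(pixel_mm = RNifti::pixdim(img)[1], channel = "image",
            filter = NA)
  .recon_image(matrix(as.numeric(img), dim(img)[1], dim(img)[2]),
               meta$pixel_mm, meta$channel, NULL, meta$filter)
}

#' Persist a binned sinogram
#'
#' The count and air-reference arrays are stored as a NIfTI volume pair
#' and the acquisition metadata (geometry, bins, detector mode, seed) as
#' a JSON sidecar.
#'
#' @param sino A `binned_sinogram`.
#' @param path Output stem; writes `<path>.counts.nii.gz`,
#'   `<path>.air.nii.gz`, `<path>.json`.
#' @export
write_sinogram <- function(sino, path) {
  .atomic_write(paste0(path, ".counts.nii.gz"), function(tmp)
    RNifti::writeNifti(RNifti::asNifti(sino$counts), tmp))
  .atomic_write(paste0(path, ".air.nii.gz"), function(tmp)
    RNifti::writeNifti(RNifti::asNifti(sino$air), tmp))
  meta <- list(geometry = unclass(sino$geometry),
               bins = sino$bins$thresholds,
               det = unclass(sino$det),
               mas = sino$mas, seed = sino$seed,
               phantom = sino$phantom_name)
  .atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#' @param path The stem passed to [write_sinogram()].
#' @return A `binned_sinogram`.
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  counts <- RNifti::readNifti(paste0(path, ".counts.nii.gz"))
  air <- RNifti::readNifti(paste0(path, ".air.nii.gz"))
  g <- meta$geometry
  geometry <- scanner_geometry(g$sid_mm, g$sdd_mm, g$n_views, g$rotation_s,
                               g$n_cols, g$n_rows, g$col_pitch_mm,
                               g$row_pitch_mm, g$n_modules, g$fov_mm)
  det <- detector_config(meta$det$bit_depths, meta$det$binning,
                         meta$det$energy_sigma_keV, meta$det$gain,
                         meta$det$offset, meta$det$eid_noise_sd)
  structure(list(counts = array(as.numeric(counts), dim(counts)),
                 air = array(as.numeric(air), dim(air)),
                 geometry = geometry, bins = energy_bins(meta$bins),
                 det = det, mas = meta$mas, seed = meta$seed,
                 noise = NA, phantom_name = meta$phantom),
            class = "binned_sinogram")
}

#' Write an 8-bit PNG preview with window/level
#'
#' @param image Image to render.
#' @param path Output `.png`.
#' @param window,level Display window width and level in image units
#'   (default W/L = 450/100 HU).
#' @param pixel_mm Pixel size for plain matrices (unused, accepted for
#'   symmetry).
#' @export
write_png_preview <- function(image, path, window = 450, level = 100,
                              pixel_mm = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for previews", call. = FALSE)
  mat <- .image_matrix(image)
  lo <- level - window / 2
  g <- pmin(pmax((mat - lo) / window, 0), 1)
  .atomic_write(path, function(tmp) png::writePNG(g, tmp))
  invisible(path)
}
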