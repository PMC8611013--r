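# ROI statistics, CNR, iodine-map CNR gain, HU comparison, and
# bar-pattern modulation.

.image_matrix <- function(image) {
  if (inherits(image, "recon_image")) image$hu else image
}

.image_pixel <- function(image, pixel_mm) {
  if (!is.null(pixel_mm)) return(pixel_mm)
  if (inherits(image, "recon_image")) return(image$pixel_mm)
  stop("pixel_mm required for plain-matrix images", call. = FALSE)
}

# logical mask of pixels whose centers fall inside the circular ROI
.roi_mask <- function(n, pixel_mm, roi) {
  cx <- .pixel_coords(n, pixel_mm)
  x <- matrix(cx, n, n, byrow = TRUE)
  y <- matrix(rev(cx), n, n)
  (x - roi$center_mm[1])^2 + (y - roi$center_mm[2])^2 <= roi$radius_mm^2
}

.roi_mean <- function(mat, roi, pixel_mm) {
  mean(mat[.roi_mask(nrow(mat), pixel_mm, roi)])
}

#' ROI mean and standard deviation
#'
#' Statistics over the pixels whose centers fall inside the circular ROI.
#'
#' @param image A `recon_image`, material map, or plain matrix.
#' @param roi A `roi_spec`.
#' @param pixel_mm Pixel size (required for plain matrices).
#' @return List with `label`, `n`, `mean`, `sd`.
#' @export
roi_stats <- function(image, roi, pixel_mm = NULL) {
  mat <- .image_matrix(image)
  px <- .image_pixel(image, pixel_mm)
  mask <- .roi_mask(nrow(mat), px, roi)
  if (!any(mask))
    stop("ROI '", roi$label, "' contains no pixel centers", call. = FALSE)
  v <- mat[mask]
  list(label = roi$label, n = length(v), mean = mean(v),
       sd = stats::sd(v))
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mean(tissue ROI) - mean(muscle ROI)) / SD(noise ROI)`; the sign
#' of the contrast is preserved.
#'
#' @param image Image to measure.
#' @param tissue,muscle,noise `roi_spec`s for the tissue, the reference
#'   muscle, and a uniform noise region.
#' @param pixel_mm Pixel size for plain matrices.
#' @export
cnr <- function(image, tissue, muscle, noise, pixel_mm = NULL) {
  st <- roi_stats(image, tissue, pixel_mm)
  sm <- roi_stats(image, muscle, pixel_mm)
  sn <- roi_stats(image, noise, pixel_mm)
  if (sn$sd <= 0)
    stop("noise ROI has zero standard deviation; choose a noise ROI in a ",
         "region with nonzero image noise", call. = FALSE)
  (st$mean - sm$mean) / sn$sd
}

#' Per-tissue CNR gain of the iodine map over the total-energy image
#'
#' Computes the CNR of each tissue ROI in both images (with the same
#' muscle and noise ROIs, measured in each image's own units) and reports
#' the elementwise ratio `CNR_iodine / CNR_total`.
#'
#' @param total_image Total-energy HU image.
#' @param iodine_map Iodine score map on the same grid.
#' @param rois Named list of `roi_spec`s; entries with role `"tissue"` are
#'   scored, and entries named/role-tagged `muscle` and `noise` provide
#'   the references.
#' @param pixel_mm Pixel size for plain matrices.
#' @return Data frame with `tissue`, `cnr_total`, `cnr_iodine`, `ratio`.
#' @export
cnr_gain <- function(total_image, iodine_map, rois, pixel_mm = NULL) {
  if (is.null(pixel_mm)) pixel_mm <- .image_pixel(total_image, NULL)
  roles <- vapply(rois, `[[`, "", "role")
  muscle <- rois[[which(roles == "muscle")[1]]]
  noise <- rois[[which(roles == "noise")[1]]]
  tissues <- rois[roles == "tissue"]
  rows <- lapply(tissues, function(r) {
    ct <- cnr(total_image, r, muscle, noise, pixel_mm)
    ci <- cnr(iodine_map, r, muscle, noise, pixel_mm)
    if (abs(ct) < .Machine$double.eps)
      stop("total-energy CNR is zero for ROI '", r$label,
           "'; the gain ratio is undefined", call. = FALSE)
    data.frame(tissue = r$label, cnr_total = ct, cnr_iodine = ci,
               ratio = ci / ct)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Mean-HU comparison between PCD and EID images
#'
#' @param pcd_image PCD image (typically the total-energy channel).
#' @param eid_image EID image on the same grid.
#' @param rois Named list of `roi_spec`s (e.g. air, muscle, brain, skull).
#' @param air_offset Apply the display convention of adding 1000 HU to the
#'   air ROI means (default TRUE).
#' @param pixel_mm Pixel size for plain matrices.
#' @return Data frame with per-ROI means for both systems and their
#'   difference.
#' @export
hu_comparison <- function(pcd_image, eid_image, rois, air_offset = TRUE,
                          pixel_mm = NULL) {
  rows <- lapply(rois, function(r) {
    mp <- roi_stats(pcd_image, r, pixel_mm)$mean
    me <- roi_stats(eid_image, r, pixel_mm)$mean
    if (air_offset && identical(r$label, "air")) {
      mp <- mp + 1000; me <- me + 1000
    }
    data.frame(roi = r$label, hu_pcd = mp, hu_eid = me,
               diff = mp - me)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Bar-pattern modulation
#'
#' `(mean over bar-center pixels - mean over gap-center pixels) /
#' (ideal bar - ideal gap)`: 1 for a perfectly resolved pattern, 0 when
#' the bars are unresolved.
#'
#' @param image Reconstructed (or ground-truth) image covering the bar
#'   pattern.
#' @param bar_spec The `$bar_spec` of [make_bar_phantom()].
#' @param ideal_bar,ideal_gap Image values of a fully resolved bar and
#'   gap (e.g. the large-area HU of the bar material and of air).
#' @param pixel_mm Pixel size for plain matrices.
#' @return Modulation (clipped below at 0).
#' @export
bar_modulation <- function(image, bar_spec, ideal_bar, ideal_gap,
                           pixel_mm = NULL) {
  mat <- .image_matrix(image)
  px <- .image_pixel(image, pixel_mm)
  n <- nrow(mat)
  cx <- .pixel_coords(n, px)
  ys <- rev(cx)
  rsel <- which(abs(ys) <= 0.35 * bar_spec$bar_height_mm)
  sample_centers <- function(centers) {
    v <- unlist(lapply(centers, function(x0) {
      csel <- which.min(abs(cx - x0))
      if (abs(cx[csel] - x0) > bar_spec$bar_width_mm / 2 + px)
        stop("bar pattern lies outside the image", call. = FALSE)
      mat[rsel, csel]
    }))
    mean(v)
  }
  m <- (sample_centers(bar_spec$bar_centers_mm) -
          sample_centers(bar_spec$gap_centers_mm)) /
    (ideal_bar - ideal_gap)
  max(m, 0)
}
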