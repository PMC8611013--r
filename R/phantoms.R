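# Digital 2-D phantoms: per-material volume-fraction maps plus ROI layouts.
#
# Coordinate convention: physical origin at the isocenter, x increases to
# the right, y increases upward (image row 1 is anterior/top); pixel centers
# sit at half-integer offsets from the grid center.

#' Circular region-of-interest specification
#'
#' @param label ROI label.
#' @param role One of `"tissue"`, `"muscle"`, `"noise"`,
#'   `"training-material"`.
#' @param center_mm Length-2 vector, ROI center (x, y) in mm at isocenter.
#' @param radius_mm Circle radius in mm.
#' @param material Material the ROI samples (for training labels).
#' @param conc Solute concentration in mg/mL, if applicable.
#' @export
roi_spec <- function(label, role, center_mm, radius_mm,
                     material = NA_character_, conc = NA_real_) {
  stopifnot(length(center_mm) == 2, radius_mm > 0)
  structure(list(label = label, role = role,
                 center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, material = material, conc = conc),
            class = "roi_spec")
}

.pixel_coords <- function(n, pixel_mm) {
  (seq_len(n) - 1 - (n - 1) / 2) * pixel_mm
}

.empty_phantom <- function(name, n, fov_mm, seed = NA_integer_) {
  structure(list(name = name, n = as.integer(n),
                 pixel_mm = fov_mm / n, fov_mm = fov_mm,
                 materials = list(), rois = list(), seed = seed),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %s  %dx%d px (%.4g mm/px, FoV %g mm)\n",
              x$name, x$n, x$n, x$pixel_mm, x$fov_mm))
  cat("  materials:", paste(names(x$materials), collapse = ", "), "\n")
  cat("  ROIs:", length(x$rois), "\n")
  invisible(x)
}

.coord_grids <- function(ph) {
  cx <- .pixel_coords(ph$n, ph$pixel_mm)
  list(x = matrix(cx, ph$n, ph$n, byrow = TRUE),
       y = matrix(rev(cx), ph$n, ph$n))
}

.get_map <- function(ph, material) {
  m <- ph$materials[[material]]
  if (is.null(m)) matrix(0, ph$n, ph$n) else m
}

# Overwrite every material at masked pixels with the given fractions
# (named vector). Keeps per-pixel fraction sums <= 1 by construction.
.paint <- function(ph, mask, fractions) {
  if (sum(fractions) > 1 + 1e-9) stop("fractions exceed 1", call. = FALSE)
  for (m in names(ph$materials)) {
    map <- ph$materials[[m]]
    map[mask] <- 0
    ph$materials[[m]] <- map
  }
  for (m in names(fractions)) {
    map <- .get_map(ph, m)
    map[mask] <- fractions[[m]]
    ph$materials[[m]] <- map
  }
  ph
}

.disc_mask <- function(grids, center, radius) {
  (grids$x - center[1])^2 + (grids$y - center[2])^2 <= radius^2
}

.ellipse_mask <- function(grids, center, a, b) {
  ((grids$x - center[1]) / a)^2 + ((grids$y - center[2]) / b)^2 <= 1
}

# Volume fraction of solute for a concentration in mg/mL of solution.
.solute_fraction <- function(material, conc_mg_ml) {
  conc_mg_ml / 1000 / material_table(material)$density_g_cm3
}

# water-based solution fractions (solute displaces water)
.solution <- function(solute, conc_mg_ml, solvent = "water") {
  f <- .solute_fraction(solute, conc_mg_ml)
  out <- c(1 - f, f)
  names(out) <- c(solvent, solute)
  out
}

#' Linear attenuation map of a phantom at one energy
#'
#' @param phantom A `digital_phantom`.
#' @param E Energy in keV (scalar).
#' @return Matrix of mu in cm^-1.
#' @export
phantom_mu <- function(phantom, E) {
  stopifnot(length(E) == 1)
  mu <- matrix(0, phantom$n, phantom$n)
  for (m in names(phantom$materials)) {
    tab <- material_table(m)
    mu <- mu + phantom$materials[[m]] *
      (tab$density_g_cm3 * mass_attenuation(tab, E))
  }
  mu
}

#' Multi-energy insert phantom
#'
#' Water cylinder with cylindrical solution inserts on a ring: iodine and
#' calcium at the given concentrations plus water-filled inserts. One
#' training ROI is centered in each insert.
#'
#' @param iodine_concs Iodine concentrations, mg/mL.
#' @param calcium_concs Calcium concentrations, mg/mL.
#' @param n_water_inserts Number of plain water inserts (default 1).
#' @param body_radius_mm Radius of the water cylinder.
#' @param insert_radius_mm Radius of each insert.
#' @param ring_radius_mm Radius of the insert ring.
#' @param n Grid size in pixels.
#' @param fov_mm Field of view.
#' @param seed Stored for provenance (the layout is deterministic).
#' @return A `digital_phantom` with `training-material` ROIs.
#' @export
make_insert_phantom <- function(iodine_concs = c(2, 5, 10),
                                calcium_concs = c(50, 100, 300),
                                n_water_inserts = 1,
                                body_radius_mm = 100,
                                insert_radius_mm = 16,
                                ring_radius_mm = 62,
                                n = 626, fov_mm = 250, seed = 1L) {
  ph <- .empty_phantom("insert", n, fov_mm, seed)
  g <- .coord_grids(ph)
  ph <- .paint(ph, .disc_mask(g, c(0, 0), body_radius_mm), c(water = 1))

  k <- length(iodine_concs) + length(calcium_concs) + n_water_inserts
  if (k > 0) {
    if (2 * pi * ring_radius_mm / k < 2 * insert_radius_mm)
      stop("insert layout error: ", k, " inserts of radius ",
           insert_radius_mm, " mm overlap on a ring of radius ",
           ring_radius_mm, " mm", call. = FALSE)
    ang <- (seq_len(k) - 1) * 2 * pi / k + pi / 2
    centers <- cbind(ring_radius_mm * cos(ang), ring_radius_mm * sin(ang))
    specs <- c(lapply(iodine_concs, function(c) list(mat = "iodine", conc = c)),
               lapply(calcium_concs, function(c) list(mat = "calcium", conc = c)),
               replicate(n_water_inserts, list(mat = "water", conc = 0),
                         simplify = FALSE))
    for (i in seq_len(k)) {
      s <- specs[[i]]
      frac <- if (s$mat == "water") c(water = 1) else .solution(s$mat, s$conc)
      ph <- .paint(ph, .disc_mask(g, centers[i, ], insert_radius_mm), frac)
      ph$rois[[i]] <- roi_spec(
        label = sprintf("%s_%g", s$mat, s$conc), role = "training-material",
        center_mm = centers[i, ], radius_mm = 0.6 * insert_radius_mm,
        material = s$mat, conc = s$conc)
    }
  }
  ph
}

#' Brain phantom
#'
#' Elliptical skull shell (cortical bone), gray-matter ribbon, white-matter
#' core, optional iodinated vessel discs, a posterior neck-muscle pad and an
#' air reference region. Two `training-material` ROIs sample white and gray
#' matter.
#'
#' @param vessel_iodine_mg_ml Iodine concentration of the vessels (0 gives a
#'   pre-contrast phantom).
#' @param skull_a_mm,skull_b_mm Outer skull semi-axes.
#' @param skull_thickness_mm Skull shell thickness.
#' @param white_a_mm,white_b_mm White-matter core semi-axes.
#' @param n,fov_mm Grid size and field of view.
#' @param seed Stored for provenance.
#' @export
make_brain_phantom <- function(vessel_iodine_mg_ml = 4,
                               skull_a_mm = 75, skull_b_mm = 60,
                               skull_thickness_mm = 6,
                               white_a_mm = 42, white_b_mm = 32,
                               n = 626, fov_mm = 250, seed = 1L) {
  ph <- .empty_phantom("brain", n, fov_mm, seed)
  g <- .coord_grids(ph)
  ph <- .paint(ph, .ellipse_mask(g, c(0, 0), skull_a_mm, skull_b_mm),
               c(cortical_bone = 1))
  ia <- skull_a_mm - skull_thickness_mm
  ib <- skull_b_mm - skull_thickness_mm
  ph <- .paint(ph, .ellipse_mask(g, c(0, 0), ia, ib), c(gray_matter = 1))
  ph <- .paint(ph, .ellipse_mask(g, c(0, 0), white_a_mm, white_b_mm),
               c(white_matter = 1))
  ph <- .paint(ph, .disc_mask(g, c(0, -75), 12), c(muscle = 1))
  if (vessel_iodine_mg_ml > 0) {
    vf <- .solute_fraction("iodine", vessel_iodine_mg_ml)
    for (vc in list(c(0, 20), c(-30, -10)))
      ph <- .paint(ph, .disc_mask(g, vc, 2.5),
                   c(water = 1 - vf, iodine = vf))
  }
  ph$rois <- list(
    roi_spec("white", "training-material", c(0, 0), 11,
             material = "white_matter"),
    roi_spec("gray", "training-material", c(55, 0), 11,
             material = "gray_matter"),
    roi_spec("air", "tissue", c(0, -100), 10),
    roi_spec("muscle", "muscle", c(0, -75), 8),
    roi_spec("brain", "tissue", c(20, 18), 8),
    roi_spec("skull", "tissue", c(0, 57), 2))
  ph
}

#' Liver phantom with rim-enhanced tumor
#'
#' Soft-tissue body ellipse containing a contrast-enhanced liver, a tumor
#' with an iodine-enhanced rim and hypo-enhancing core, an iodinated aorta,
#' and back muscles. Emits ROIs with roles tumor/liver/aorta/muscle/noise.
#'
#' @param tumor_radius_mm Tumor radius.
#' @param rim_width_mm Width of the enhancing rim (`< tumor_radius_mm`).
#' @param iodine_rim_mg_ml Iodine concentration in the rim.
#' @param iodine_aorta_mg_ml Iodine concentration in the aorta.
#' @param iodine_liver_mg_ml Background parenchymal enhancement (small in
#'   the hepatic arterial phase, when parenchyma is mostly portally
#'   supplied).
#' @param n,fov_mm Grid size and field of view.
#' @param seed Stored for provenance.
#' @export
make_liver_phantom <- function(tumor_radius_mm = 12, rim_width_mm = 3,
                               iodine_rim_mg_ml = 3, iodine_aorta_mg_ml = 8,
                               iodine_liver_mg_ml = 0.3,
                               n = 626, fov_mm = 250, seed = 1L) {
  if (rim_width_mm >= tumor_radius_mm)
    stop("rim width must be smaller than the tumor radius", call. = FALSE)
  ph <- .empty_phantom("liver", n, fov_mm, seed)
  g <- .coord_grids(ph)
  ph <- .paint(ph, .ellipse_mask(g, c(0, 0), 75, 55), c(soft_tissue = 1))

  liver_c <- c(-22, 6)
  fl <- .solute_fraction("iodine", iodine_liver_mg_ml)
  ph <- .paint(ph, .disc_mask(g, liver_c, 34),
               c(liver = 1 - fl, iodine = fl))

  tumor_c <- c(-25, 12)
  fr <- .solute_fraction("iodine", iodine_rim_mg_ml)
  ph <- .paint(ph, .disc_mask(g, tumor_c, tumor_radius_mm),
               c(soft_tissue = 1 - fr, iodine = fr))
  ph <- .paint(ph, .disc_mask(g, tumor_c, tumor_radius_mm - rim_width_mm),
               c(soft_tissue = 1))

  fa <- .solute_fraction("iodine", iodine_aorta_mg_ml)
  ph <- .paint(ph, .disc_mask(g, c(0, -28), 5), c(water = 1 - fa, iodine = fa))
  for (mc in list(c(-27, -36), c(27, -36)))
    ph <- .paint(ph, .disc_mask(g, mc, 15), c(muscle = 1))

  ph$rois <- list(
    roi_spec("tumor", "tissue", tumor_c, tumor_radius_mm - 0.5),
    roi_spec("liver", "tissue", c(-38, -6), 8),
    roi_spec("aorta", "tissue", c(0, -28), 3.5),
    roi_spec("muscle", "muscle", c(27, -36), 12, material = "muscle"),
    roi_spec("noise", "noise", c(-12, -8), 8))
  ph
}

#' Resolution bar phantom
#'
#' Alternating bone/air bars of equal width inside a soft-tissue disc,
#' emulating sub-millimeter trabecular structure (default 0.5 mm bars).
#' Bar period is `2 * bar_width_mm`.
#'
#' @param bar_width_mm Width of each bar and gap (default 0.5).
#' @param n_bars Number of solid bars.
#' @param contrast_material Bar material (default cortical bone).
#' @param disc_radius_mm Radius of the surrounding soft-tissue disc.
#' @param bar_height_mm Bar length along y.
#' @param n,fov_mm Grid size and (small) field of view.
#' @return A `digital_phantom` with a `$bar_spec` element holding the bar
#'   and gap center x-coordinates and pattern bounds.
#' @export
make_bar_phantom <- function(bar_width_mm = 0.5, n_bars = 8,
                             contrast_material = "cortical_bone",
                             disc_radius_mm = 24, bar_height_mm = 20,
                             n = 640, fov_mm = 64) {
  ph <- .empty_phantom("bars", n, fov_mm)
  if (bar_width_mm < ph$pixel_mm)
    stop("bar width ", bar_width_mm, " mm is narrower than one phantom pixel (",
         signif(ph$pixel_mm, 3), " mm)", call. = FALSE)
  g <- .coord_grids(ph)
  ph <- .paint(ph, .disc_mask(g, c(0, 0), disc_radius_mm), c(soft_tissue = 1))

  width_total <- n_bars * 2 * bar_width_mm
  x0 <- -width_total / 2
  ymask <- abs(g$y) <= bar_height_mm / 2
  # clear the whole pattern window to air, then paint the solid bars
  win <- ymask & g$x >= x0 & g$x < x0 + width_total
  ph <- .paint(ph, win, c(water = 0))
  bar_centers <- gap_centers <- numeric(n_bars)
  for (k in seq_len(n_bars)) {
    xs <- x0 + (2 * (k - 1)) * bar_width_mm
    mask <- ymask & g$x >= xs & g$x < xs + bar_width_mm
    frac <- c(1); names(frac) <- contrast_material
    ph <- .paint(ph, mask, frac)
    bar_centers[k] <- xs + bar_width_mm / 2
    gap_centers[k] <- xs + 1.5 * bar_width_mm
  }
  ph$bar_spec <- list(bar_width_mm = bar_width_mm,
                      bar_centers_mm = bar_centers,
                      gap_centers_mm = gap_centers,
                      bar_height_mm = bar_height_mm,
                      contrast_material = contrast_material)
  ph
}
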