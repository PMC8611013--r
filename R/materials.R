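# Material attenuation tables.
#
# Each table stores mass attenuation mu/rho (cm^2/g) on a sparse energy grid,
# split into segments at K-edge energies so that interpolation never bridges
# a discontinuity. Values follow standard published photon cross-section
# shapes (photoelectric power-law decay plus a Compton floor); the gadolinium
# and tungsten K-edge energies (50.2 and 69.5 keV) are the landmarks the
# threshold calibration relies on.

.seg <- function(E, mur) {
  stopifnot(length(E) == length(mur), all(diff(E) > 0))
  list(E = as.numeric(E), mur = as.numeric(mur))
}

.make_table <- function(name, density, segments, kedges = numeric(0)) {
  structure(
    list(name = name, density_g_cm3 = density,
         segments = segments, kedges_keV = as.numeric(kedges)),
    class = "attenuation_table")
}

#' @export
print.attenuation_table <- function(x, ...) {
  rng <- range(unlist(lapply(x$segments, `[[`, "E")))
  cat(sprintf("<attenuation_table> %s  rho=%.4g g/cm3  E=[%g, %g] keV",
              x$name, x$density_g_cm3, rng[1], rng[2]))
  if (length(x$kedges_keV))
    cat(sprintf("  K-edges: %s keV", paste(x$kedges_keV, collapse = ", ")))
  cat("\n")
  invisible(x)
}

.build_material_db <- function() {
  E1 <- c(15, 20, 30, 40, 50, 60, 80, 100, 120, 140, 160)

  water_mur <- c(1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
                 0.1837, 0.1707, 0.1614, 0.1543, 0.1483)
  ca_mur <- c(9.66, 4.08, 1.355, 0.651, 0.424, 0.319,
              0.2251, 0.1862, 0.1672, 0.1551, 0.1466)

  db <- list()

  db$water <- .make_table("water", 1.000, list(.seg(E1, water_mur)))
  db$air <- .make_table("air", 0.001205, list(.seg(E1, c(
    1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875,
    0.1662, 0.1541, 0.1456, 0.1391, 0.1337))))
  db$aluminium <- .make_table("aluminium", 2.699, list(.seg(E1, c(
    7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778,
    0.2018, 0.1704, 0.1536, 0.1426, 0.1343))))
  db$calcium <- .make_table("calcium", 1.550, list(.seg(E1, ca_mur)))
  db$cortical_bone <- .make_table("cortical_bone", 1.920, list(.seg(E1, c(
    6.323, 2.851, 0.9646, 0.5168, 0.3504, 0.2741,
    0.2083, 0.1800, 0.1651, 0.1549, 0.1470))))
  db$soft_tissue <- .make_table("soft_tissue", 1.060, list(.seg(E1, c(
    1.693, 0.8205, 0.3783, 0.2699, 0.2281, 0.2068,
    0.1844, 0.1713, 0.1620, 0.1549, 0.1490))))
  db$muscle <- .make_table("muscle", 1.050, list(.seg(E1, c(
    1.699, 0.8240, 0.3793, 0.2708, 0.2288, 0.2074,
    0.1849, 0.1717, 0.1623, 0.1552, 0.1492))))
  db$liver <- .make_table("liver", 1.060, list(.seg(E1, c(
    1.710, 0.8290, 0.3810, 0.2716, 0.2292, 0.2077,
    0.1851, 0.1718, 0.1624, 0.1553, 0.1493))))

  # Iodine, K-edge 33.17 keV.
  db$iodine <- .make_table("iodine", 4.933, list(
    .seg(c(15, 20, 25, 30, 33.17),
         c(49.1, 21.6, 11.4, 6.79, 5.10)),
    .seg(c(33.17, 40, 50, 60, 80, 100, 120, 140, 160),
         c(30.3, 18.1, 9.79, 5.94, 2.69, 1.61, 1.04, 0.75, 0.58))),
    kedges = 33.17)

  # Gadolinium, K-edge 50.2 keV.
  db$gadolinium <- .make_table("gadolinium", 7.900, list(
    .seg(c(15, 20, 30, 40, 50.2),
         c(48.0, 22.0, 7.40, 3.40, 1.84)),
    .seg(c(50.2, 60, 80, 100, 120, 140, 160),
         c(8.74, 5.50, 2.60, 1.55, 1.02, 0.73, 0.55))),
    kedges = 50.2)

  # Tungsten, K-edge 69.5 keV (L-edges lie below the table range).
  db$tungsten <- .make_table("tungsten", 19.30, list(
    .seg(c(15, 20, 30, 40, 50, 60, 69.5),
         c(60.0, 28.0, 9.50, 4.40, 2.45, 1.55, 1.10)),
    .seg(c(69.5, 80, 100, 120, 140, 160),
         c(4.24, 2.99, 1.81, 1.21, 0.88, 0.68))),
    kedges = 69.5)

  # White/gray matter: water-based tissues at realistic densities (CT
  # numbers near +25 and +40 HU) plus, for gray matter, a small
  # calcium-shaped tilt in effective atomic number so the three bins carry
  # separable signal. Phantom parameters, not claims: the offsets keep the
  # two tissues clear of the water and calcium training clusters.
  db$white_matter <- .make_table("white_matter", 1.025,
                                 list(.seg(E1, water_mur)))
  db$gray_matter <- .make_table("gray_matter", 1.040,
                                list(.seg(E1, 0.99 * water_mur + 0.01 * ca_mur)))

  # Vacuum pseudo-material: zero density, so linear attenuation is always 0.
  db$vacuum <- .make_table("vacuum", 0.0, list(.seg(E1, water_mur)))

  db
}

.material_db <- .build_material_db()

#' Built-in material names
#' @return Character vector of material names known to [material_table()].
#' @export
material_names <- function() names(.material_db)

#' Look up a built-in attenuation table
#'
#' @param name Material name (see [material_names()]), or an
#'   `attenuation_table` which is returned unchanged.
#' @return An `attenuation_table` object.
#' @export
material_table <- function(name) {
  if (inherits(name, "attenuation_table")) return(name)
  tab <- .material_db[[name]]
  if (is.null(tab))
    stop("unknown material '", name, "'; known: ",
         paste(material_names(), collapse = ", "), call. = FALSE)
  tab
}

.table_range <- function(mat) {
  segs <- mat$segments
  c(segs[[1]]$E[1], segs[[length(segs)]]$E[length(segs[[length(segs)]]$E)])
}

#' Mass attenuation coefficient
#'
#' Log-log interpolation of mu/rho within the table segment containing each
#' query energy. Interpolation never bridges a K-edge; a query exactly on an
#' edge takes the right (above-edge) limit.
#'
#' @param material Material name or `attenuation_table`.
#' @param E Energies in keV (vectorised).
#' @return mu/rho in cm^2/g, same length as `E`.
#' @export
mass_attenuation <- function(material, E) {
  mat <- material_table(material)
  rng <- .table_range(mat)
  if (any(E < rng[1] | E > rng[2]))
    stop(sprintf("energy out of range for material '%s': table covers [%g, %g] keV",
                 mat$name, rng[1], rng[2]), call. = FALSE)
  out <- numeric(length(E))
  edges <- mat$kedges_keV
  # segment index: on-edge queries fall in the right-hand segment
  seg_idx <- if (length(edges)) 1L + rowSums(outer(E, edges, `>=`)) else
    rep(1L, length(E))
  for (s in unique(seg_idx)) {
    seg <- mat$segments[[s]]
    sel <- seg_idx == s
    out[sel] <- exp(approx(log(seg$E), log(seg$mur), xout = log(E[sel]),
                           rule = 2)$y)
  }
  out
}

#' Linear attenuation of a material mixture
#'
#' Partial-volume mixing: mu = sum_m fraction_m * rho_m * (mu/rho)_m(E).
#' Fractions must be nonnegative and sum to at most 1 (remainder is vacuum).
#'
#' @param fractions Named numeric vector of volume fractions.
#' @param E Energies in keV (vectorised).
#' @return Linear attenuation mu in cm^-1, one value per energy.
#' @export
linear_attenuation <- function(fractions, E) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (any(fractions < 0)) stop("volume fractions must be nonnegative")
  if (sum(fractions) > 1 + 1e-9) stop("volume fractions must sum to at most 1")
  mu <- numeric(length(E))
  for (m in names(fractions)) {
    f <- fractions[[m]]
    if (f == 0) next
    tab <- material_table(m)
    mu <- mu + f * tab$density_g_cm3 * mass_attenuation(tab, E)
  }
  mu
}

#' Lowest K-edge of a material within the imaging window
#'
#' @param material Material name or `attenuation_table`.
#' @param window keV interval searched (default the system's 30--140 range).
#' @return K-edge energy in keV, or `NULL` if the table has no discontinuity
#'   in the window.
#' @export
kedge_energy <- function(material, window = c(30, 140)) {
  mat <- material_table(material)
  k <- mat$kedges_keV[mat$kedges_keV >= window[1] & mat$kedges_keV <= window[2]]
  if (!length(k)) NULL else min(k)
}

# --- JSON round-trip -------------------------------------------------------

#' Write an attenuation table as JSON
#' @param material Material name or `attenuation_table`.
#' @param path Output file.
#' @export
write_material_json <- function(material, path) {
  mat <- material_table(material)
  obj <- list(
    name = mat$name, density_g_cm3 = mat$density_g_cm3,
    segments = lapply(mat$segments, function(s)
      list(E_keV = s$E, mu_rho_cm2_g = s$mur)),
    kedges_keV = mat$kedges_keV)
  .atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read an attenuation table from JSON
#' @param path File written by [write_material_json()] (or hand-authored in
#'   the same dialect).
#' @return An `attenuation_table`.
#' @export
read_material_json <- function(path) {
  obj <- tryCatch(
    suppressWarnings(jsonlite::read_json(path, simplifyVector = TRUE)),
    error = function(e) stop("cannot read material table from '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(obj$name) || is.null(obj$density_g_cm3) || is.null(obj$segments))
    stop("not a material table JSON file: ", path, call. = FALSE)
  segs <- obj$segments
  if (is.data.frame(segs))
    segs <- lapply(seq_len(nrow(segs)), function(i)
      .seg(segs$E_keV[[i]], segs$mu_rho_cm2_g[[i]]))
  else
    segs <- lapply(segs, function(s) .seg(s$E_keV, s$mu_rho_cm2_g))
  .make_table(obj$name, obj$density_g_cm3, segs,
              if (length(obj$kedges_keV)) obj$kedges_keV else numeric(0))
}
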