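# Tube spectrum model and Hounsfield conversion.

#' Uniform energy grid
#'
#' @param lo,hi Interval bounds in keV (`lo >= 1`).
#' @param de Spacing in keV (default 1).
#' @return Numeric vector of strictly increasing energies.
#' @export
energy_grid <- function(lo = 20, hi = 140, de = 1) {
  stopifnot(lo >= 1, hi > lo, de > 0)
  seq(lo, hi, by = de)
}

#' Generate a filtered bremsstrahlung tube spectrum
#'
#' Kramers-type analytic shape, fluence proportional to `E * (kVp - E)`
#' before filtration, hardened by Beer--Lambert transmission through the
#' stated filter stack. The unfiltered spectrum is normalised so its total
#' fluence equals `photons_per_mas * mAs` per ray; filtration then removes
#' photons physically, and the total scales linearly with mAs.
#'
#' @param kvp Tube potential in keV, in \[40, 150\].
#' @param filtration List of `list(material=, thickness_mm=)` entries
#'   (default 2.5 mm aluminium-equivalent inherent filtration).
#' @param mas Exposure in mAs for the whole spectrum.
#' @param energies Energy samples in keV (default 1 keV grid from 20 to kVp).
#' @param photons_per_mas Unfiltered photons per ray per mAs (exposure scale;
#'   default 1.4e5, which leaves roughly 9e4 photons/ray/mAs behind the
#'   default filtration at 140 kVp).
#' @return A `tube_spectrum`: list with `energies` (keV), `fluence`
#'   (photons per sample per ray), `kvp`, `mas`, `filtration`.
#' @export
generate_tube_spectrum <- function(kvp = 140,
                                   filtration = list(
                                     list(material = "aluminium",
                                          thickness_mm = 2.5)),
                                   mas = 14,
                                   energies = energy_grid(20, kvp),
                                   photons_per_mas = 1.4e5) {
  stopifnot(kvp >= 40, kvp <= 150, mas > 0)
  raw <- pmax(energies * (kvp - energies), 0)
  raw[energies > kvp] <- 0
  raw <- raw / sum(raw) * photons_per_mas * mas
  trans <- rep(1, length(energies))
  for (f in filtration) {
    if (f$thickness_mm < 0)
      stop("filter thickness must be nonnegative", call. = FALSE)
    tab <- material_table(f$material)
    mu <- tab$density_g_cm3 * mass_attenuation(tab, energies)  # cm^-1
    trans <- trans * exp(-mu * f$thickness_mm / 10)
  }
  structure(list(energies = energies, fluence = raw * trans,
                 kvp = kvp, mas = mas, filtration = filtration),
            class = "tube_spectrum")
}

#' Rescale a spectrum to a different exposure
#' @param spectrum A `tube_spectrum`.
#' @param mas New exposure in mAs.
#' @export
with_exposure <- function(spectrum, mas) {
  spectrum$fluence <- spectrum$fluence * (mas / spectrum$mas)
  spectrum$mas <- mas
  spectrum
}

#' Export a spectrum as two-column CSV (keV, fluence)
#' @param spectrum A `tube_spectrum`.
#' @param path Output file.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  .atomic_write(path, function(tmp)
    utils::write.csv(data.frame(keV = spectrum$energies,
                                fluence = spectrum$fluence),
                     tmp, row.names = FALSE))
  invisible(path)
}

#' Convert linear attenuation to Hounsfield units
#'
#' HU = 1000 * (mu - mu_water) / mu_water, elementwise.
#'
#' @param mu Linear attenuation image or vector (cm^-1).
#' @param mu_water_eff Effective linear attenuation of water for the same
#'   spectrum/channel (cm^-1, positive).
#' @export
hu_from_mu <- function(mu, mu_water_eff) {
  if (!is.numeric(mu_water_eff) || length(mu_water_eff) != 1 ||
      mu_water_eff <= 0)
    stop("mu_water_eff must be a single positive number", call. = FALSE)
  1000 * (mu - mu_water_eff) / mu_water_eff
}

#' Inverse of [hu_from_mu()]
#' @param hu HU image or vector.
#' @param mu_water_eff Water attenuation used in the forward conversion.
#' @export
mu_from_hu <- function(hu, mu_water_eff) {
  if (mu_water_eff <= 0)
    stop("mu_water_eff must be positive", call. = FALSE)
  mu_water_eff * (1 + hu / 1000)
}
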