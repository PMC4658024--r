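#' Material attenuation table
#'
#' The package models linear attenuation with a two-basis decomposition:
#' a photoelectric term scaling as \eqn{(E/E_0)^{-3}} and a Compton term
#' following the Klein-Nishina total cross-section shape, both normalized to
#' 1 at the reference energy \eqn{E_0 = 70} keV. Each material is therefore
#' fully described by two coefficients `a_pe` and `a_c` (cm^-1 at 70 keV),
#' whose sum is the material's attenuation at 70 keV. The water entry anchors
#' the Hounsfield calibration (mu_water(70 keV) = 0.1928 cm^-1, the standard
#' narrow-beam value); metal coefficients are tiered
#' (titanium < steel < amalgam) to drive density-dependent behaviour of the
#' iterative MAR loop. `aluminum` and `tin` exist for tube filtration only.
#'
#' @param file Optional path to a JSON file holding a custom table with the
#'   same columns (name, density, a_pe, a_c); `NULL` uses the built-in table.
#' @return A tibble with columns `name`, `density` (g/cm^3), `a_pe`, `a_c`
#'   (cm^-1 at 70 keV) and `is_metal`.
#' @export
material_table <- function(file = NULL) {
  if (!is.null(file)) {
    raw <- jsonlite::fromJSON(file)
    tab <- tibble::as_tibble(raw)
    stopifnot(all(c("name", "density", "a_pe", "a_c") %in% names(tab)))
    if (!"is_metal" %in% names(tab)) {
      tab$is_metal <- tab$name %in% c("titanium", "steel", "amalgam")
    }
    validate_materials(tab)
    return(tab)
  }
  tab <- tibble::tribble(
    ~name,          ~density, ~a_pe,  ~a_c,   ~is_metal,
    "air",          0.0012,   1e-5,   5e-5,   FALSE,
    "water",        1.00,     0.0080, 0.1848, FALSE,
    "soft_tissue",  1.05,     0.0090, 0.1880, FALSE,
    "bone",         1.90,     0.1200, 0.4000, FALSE,
    "iodine_blood", 1.06,     0.0590, 0.1900, FALSE,
    "titanium",     4.50,     4.0000, 1.3000, TRUE,
    "steel",        7.90,     6.5000, 2.0000, TRUE,
    "amalgam",      10.0,     4.0000, 18.000, TRUE,
    "aluminum",     2.70,     0.2000, 0.4200, FALSE,
    "tin",          7.31,     7.5000, 1.0000, FALSE
  )
  tab
}

validate_materials <- function(tab) {
  stopifnot(
    all(tab$density[tab$name != "air"] > 0),
    all(tab$a_pe >= 0), all(tab$a_c >= 0)
  )
  invisible(tab)
}

#' Write a material table to JSON
#'
#' @param tab A material table as returned by [material_table()].
#' @param file Output path.
#' @export
write_materials <- function(tab, file) {
  jsonlite::write_json(tab, file, digits = NA)
  invisible(file)
}

# reference energy for both basis functions (keV)
E_REF <- 70

# Klein-Nishina total cross-section (per electron, arbitrary scale) as a
# function of photon energy in keV; alpha = E / (m_e c^2).
kn_sigma <- function(energy) {
  a <- energy / 511
  (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
    log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
}

#' Energy basis functions of the two-material attenuation model
#'
#' Returns the photoelectric basis \eqn{(E/70)^{-3}} and the Klein-Nishina
#' Compton basis, each normalized to 1 at 70 keV. Shared by the simulator
#' and the dual-energy decomposition, which makes noiseless decomposition
#' exact by construction.
#'
#' @param energy Photon energy (keV), vectorized.
#' @return A list with numeric components `pe` and `compton`.
#' @export
basis_functions <- function(energy) {
  list(
    pe = (energy / E_REF)^(-3),
    compton = kn_sigma(energy) / kn_sigma(E_REF)
  )
}

#' Linear attenuation coefficient of a material
#'
#' \eqn{\mu(E) = a_{pe} (E/70)^{-3} + a_c f_{KN}(E)}, with both basis
#' functions normalized to 1 at 70 keV so that \eqn{\mu(70) = a_{pe} + a_c}.
#' Strictly decreasing in energy over the diagnostic range for every
#' material with a positive coefficient.
#'
#' @param material Material name (character) or a one-row slice of
#'   [material_table()].
#' @param energy Photon energy in keV; must lie in (10, 200]. Vectorized.
#' @param materials Material table to look the name up in.
#' @return Linear attenuation coefficient(s) in cm^-1.
#' @export
attenuation <- function(material, energy, materials = material_table()) {
  if (any(energy <= 10 | energy > 200)) {
    stop("energy must lie in (10, 200] keV", call. = FALSE)
  }
  if (is.character(material)) {
    row <- materials[materials$name == material, ]
    if (nrow(row) != 1) stop("unknown material: ", material, call. = FALSE)
  } else {
    row <- material
  }
  b <- basis_functions(energy)
  row$a_pe * b$pe + row$a_c * b$compton
}

#' Attenuation of water (the Hounsfield anchor)
#'
#' @param energy Photon energy in keV.
#' @return mu_water(E) in cm^-1.
#' @export
mu_water <- function(energy) {
  attenuation("water", energy)
}
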