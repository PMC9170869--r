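# Physical constants and the bundled element table.

# package-local cache (range tables, parsed data files)
.cy_cache <- new.env(parent = emptyenv())

#' Physical constants for the stopping-power model
#'
#' CODATA values of the constants entering the Bethe stopping-power formula:
#' the Coulomb constant \eqn{k_0}, the elementary charge \eqn{e}, the electron
#' rest mass energy \eqn{m_ec^2}, the proton rest mass energy (used for the
#' relativistic \eqn{\beta^2} of the projectile), the projectile charge number
#' \eqn{z} (1 for protons) and the speed of light.
#'
#' The object is a read-only snapshot; all stopping-power code takes the
#' constants from here so that a single definition exists in the package.
#'
#' @return a list of class `"physical_constants"`.
#' @examples
#' physical_constants()$electron_rest_mass_energy_MeV
#' @export
physical_constants <- function() {
  structure(list(
    coulomb_constant_N_m2_C2   = 8.9875517923e9,
    elementary_charge_C        = 1.602176634e-19,
    electron_rest_mass_energy_MeV = 0.510998950,
    proton_rest_mass_energy_MeV   = 938.2720813,
    projectile_charge_number   = 1L,
    speed_of_light_m_s         = 2.99792458e8,
    avogadro_per_mol           = 6.02214076e23,
    joule_per_MeV              = 1.602176634e-13
  ), class = "physical_constants")
}

#' Bundled element table
#'
#' Atomic number, molar mass and ICRU-style mean excitation energy \eqn{I}
#' for the elements needed by the bundled target and degrader materials.
#' Mean excitation energies follow the ICRU elemental recommendations;
#' compound values are obtained by Bragg additivity (see [material()]).
#'
#' @return data.frame with columns `symbol`, `Z`, `molar_mass_g_mol`,
#'   `mean_excitation_eV`.
#' @export
element_table <- function() {
  if (is.null(.cy_cache$elements)) {
    path <- system.file("extdata", "elements.csv", package = "cycloyield",
                        mustWork = TRUE)
    .cy_cache$elements <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .cy_cache$elements
}

# internal: look up one element, error on unknown symbol
lookup_element <- function(symbol) {
  tab <- element_table()
  i <- match(symbol, tab$symbol)
  if (any(is.na(i))) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(i)], collapse = ", "))
  }
  tab[i, , drop = FALSE]
}
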