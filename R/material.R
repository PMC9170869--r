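# Materials: the stopping media (targets and degrader foils).

#' Define a material from element mass fractions
#'
#' A material is the medium of the stopping-power model: element mass
#' fractions, bulk density, and two derived quantities used by the Bethe
#' formula: the electron density (per gram and per cm^3)
#' \deqn{n_g = \sum_i w_i N_A Z_i / M_i}
#' and the mean excitation energy obtained by Bragg additivity on
#' \eqn{\ln I} weighted by each element's electron fraction:
#' \deqn{\ln I = \sum_i f_i \ln I_i, \quad f_i = w_i Z_i/M_i \big/ \sum_j w_j Z_j/M_j.}
#'
#' Mass fractions must sum to 1 within `1e-6`; there is no silent
#' renormalization.
#'
#' @param name material name.
#' @param composition named numeric vector of element mass fractions,
#'   e.g. `c(Te = 0.7995, O = 0.2005)`. Elements must be present in
#'   [element_table()].
#' @param density bulk density in g/cm^3.
#' @return object of class `"material"` with fields `name`, `composition`,
#'   `density_g_cm3`, `electrons_per_g`, `electrons_per_cm3`,
#'   `mean_excitation_eV`.
#' @examples
#' al <- material("Al", c(Al = 1), density = 2.70)
#' al$electrons_per_g  # N_A * 13 / 26.982
#' @export
material <- function(name, composition, density) {
  if (!is.numeric(composition) || is.null(names(composition)) ||
      any(!nzchar(names(composition)))) {
    stop("'composition' must be a named numeric vector of mass fractions")
  }
  if (any(composition <= 0) || any(composition > 1)) {
    stop("mass fractions must lie in (0, 1]")
  }
  s <- sum(composition)
  if (abs(s - 1) > 1e-6) {
    stop("material '", name, "': mass fractions sum to ", format(s, digits = 10),
         ", expected 1 (+-1e-6); no silent renormalization is performed")
  }
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("'density' must be a positive number (g/cm^3)")
  }
  el <- lookup_element(names(composition))
  NA_ <- physical_constants()$avogadro_per_mol
  zm <- el$Z / el$molar_mass_g_mol              # electrons per amu, mol e / g
  ne_g <- sum(composition * NA_ * zm)
  efrac <- composition * zm / sum(composition * zm)   # electron fractions
  lnI <- sum(efrac * log(el$mean_excitation_eV))
  structure(list(
    name = name,
    composition = composition,
    elements = el,
    density_g_cm3 = density,
    electrons_per_g = ne_g,
    electrons_per_cm3 = ne_g * density,
    mol_electrons_per_g = sum(composition * zm),  # the <Z/A> of the compound
    mean_excitation_eV = exp(lnI)
  ), class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material %s  rho = %g g/cm3  I = %.1f eV  n_e = %.4g e/g>\n",
              x$name, x$density_g_cm3, x$mean_excitation_eV, x$electrons_per_g))
  comp <- paste(sprintf("%s %.4g", names(x$composition), x$composition),
                collapse = ", ")
  cat("  mass fractions: ", comp, "\n", sep = "")
  invisible(x)
}

#' Bundled materials
#'
#' Convenience constructors for the media of the worked production case:
#'
#' * `material_teo2()`: tellurium dioxide glass, stoichiometric mass
#'   fractions (Te 127.60/159.598, O 31.998/159.598), default density
#'   5.65 g/cm^3 (solidified TeO2 glass).
#' * `material_havar()`: Havar degrader alloy, density 8.3 g/cm^3. The alloy
#'   composition (Co 42.5, Cr 20.0, Fe 17.9, Ni 13.0, W 2.8, Mo 2.2,
#'   Mn 1.6 wt%) is the standard commercial specification, bundled here as
#'   an assumption since foil data sheets usually quote only the density.
#' * `material_aluminum()`, `material_molybdenum()`: elemental degrader
#'   foils, densities 2.7 and 10.2 g/cm^3.
#'
#' @param density override the default density (g/cm^3).
#' @return a [material()].
#' @name bundled_materials
NULL

#' @rdname bundled_materials
#' @export
material_teo2 <- function(density = 5.65) {
  m_te <- 127.60; m_o2 <- 2 * 15.999
  material("TeO2", c(Te = m_te / (m_te + m_o2), O = m_o2 / (m_te + m_o2)),
           density = density)
}

#' @rdname bundled_materials
#' @export
material_havar <- function(density = 8.3) {
  material("Havar",
           c(Co = 0.425, Cr = 0.200, Fe = 0.179, Ni = 0.130,
             W = 0.028, Mo = 0.022, Mn = 0.016),
           density = density)
}

#' @rdname bundled_materials
#' @export
material_aluminum <- function(density = 2.7) {
  material("Aluminum", c(Al = 1), density = density)
}

#' @rdname bundled_materials
#' @export
material_molybdenum <- function(density = 10.2) {
  material("Molybdenum", c(Mo = 1), density = density)
}

#' Read a material definition from file
#'
#' Two formats are accepted:
#' * JSON with fields `name`, `density_g_cm3` and `composition`
#'   (an object mapping element symbols to mass fractions);
#' * CSV with columns `element,mass_fraction` and either a
#'   `density_g_cm3` column (constant) or the `density` argument.
#'
#' @param file path to a `.json` or `.csv` file.
#' @param density density in g/cm^3, required for CSV files without a
#'   `density_g_cm3` column.
#' @param name material name; defaults to the file base name.
#' @return a [material()].
#' @export
read_material <- function(file, density = NULL, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(file))
  ext <- tolower(tools::file_ext(file))
  if (ext == "json") {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    comp <- unlist(x$composition)
    material(if (!is.null(x$name)) x$name else name, comp, x$density_g_cm3)
  } else if (ext == "csv") {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("element", "mass_fraction") %in% names(df))) {
      stop("material CSV must have columns element,mass_fraction")
    }
    if (is.null(density)) {
      if (!"density_g_cm3" %in% names(df)) {
        stop("no density: supply 'density' or a density_g_cm3 column")
      }
      density <- df$density_g_cm3[1]
    }
    comp <- stats::setNames(df$mass_fraction, df$element)
    material(name, comp, density)
  } else {
    stop("unsupported material file extension: ", ext)
  }
}

#' Write a material definition to JSON
#'
#' @param mat a [material()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_material <- function(mat, file) {
  jsonlite::write_json(
    list(name = mat$name, density_g_cm3 = mat$density_g_cm3,
         composition = as.list(mat$composition)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
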