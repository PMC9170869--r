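# Bethe stopping power, CSDA ranges, slab energy degradation, straggling.

#' Stopping-power model settings
#'
#' Collects the numerical settings of the stopping/range engine: the physical
#' constants, the low-energy cutoff below which the Bethe integrand is
#' truncated (the formula loses validity below a few hundred keV; the
#' sub-cutoff residual range is set to zero), the tabulation step of the
#' energy-range table used for range inversion, and the upper end of the
#' validity window.
#'
#' @param low_energy_cutoff MeV, must be >= 0.1. Default 0.25 MeV: the
#'   truncated residual range is below ~2 um in TeO2, negligible against the
#'   model accuracy.
#' @param energy_grid_step MeV, tabulation step of the energy-range table
#'   (default 0.01 MeV).
#' @param energy_max MeV, upper end of the declared validity window
#'   (default 30 MeV).
#' @param constants a [physical_constants()] object.
#' @return object of class `"stopping_model"`.
#' @export
stopping_model <- function(low_energy_cutoff = 0.25, energy_grid_step = 0.01,
                           energy_max = 30, constants = physical_constants()) {
  if (low_energy_cutoff < 0.1) {
    stop("low_energy_cutoff must be >= 0.1 MeV (validity floor of the Bethe formula)")
  }
  if (energy_grid_step <= 0) stop("energy_grid_step must be > 0")
  if (energy_max <= low_energy_cutoff) stop("energy_max must exceed the cutoff")
  structure(list(low_energy_cutoff = low_energy_cutoff,
                 energy_grid_step = energy_grid_step,
                 energy_max = energy_max,
                 constants = constants),
            class = "stopping_model")
}

#' Mass stopping power of protons (Bethe formula)
#'
#' Evaluates the Bethe stopping power
#' \deqn{-\frac{dE}{dx} = \frac{4\pi n k_0^2 z^2 e^4}{m_e c^2 \beta^2}
#'   \left[\ln\frac{2 m_e c^2 \beta^2}{I(1-\beta^2)} - \beta^2\right]}
#' divided by the density, i.e. in MeV cm^2/g, so the result depends on the
#' material only through its composition (electron density per gram and mean
#' excitation energy), not its density. \eqn{\beta^2} is computed
#' relativistically from the proton kinetic energy. No shell or
#' density-effect corrections are applied; for 1-30 MeV protons these are
#' small against the few-percent accuracy the model claims.
#'
#' @param mat a [material()].
#' @param energy proton kinetic energy in MeV (vectorized). Must lie within
#'   `[low_energy_cutoff, energy_max]`; values outside raise an error rather
#'   than extrapolating.
#' @param model a [stopping_model()].
#' @return mass stopping power in MeV cm^2/g.
#' @examples
#' mass_stopping_power(material_aluminum(), 10)
#' @export
mass_stopping_power <- function(mat, energy, model = stopping_model()) {
  stopifnot(inherits(mat, "material"))
  if (any(!is.finite(energy)) ||
      any(energy < model$low_energy_cutoff - 1e-12) ||
      any(energy > model$energy_max + 1e-12)) {
    stop("energy outside the validity window [",
         model$low_energy_cutoff, ", ", model$energy_max,
         "] MeV; no extrapolation is performed")
  }
  k <- model$constants
  gamma <- 1 + energy / k$proton_rest_mass_energy_MeV
  beta2 <- 1 - 1 / gamma^2
  # leading coefficient evaluated in SI from k0, e, me c^2, then converted:
  # 4 pi k0^2 z^2 e^4 / (me c^2) in J m^2; times n [m^-3] / beta^2 gives J/m
  me_J <- k$electron_rest_mass_energy_MeV * k$joule_per_MeV
  coef_J_m2 <- 4 * pi * k$coulomb_constant_N_m2_C2^2 *
    k$projectile_charge_number^2 * k$elementary_charge_C^4 / me_J
  n_m3 <- mat$electrons_per_g * 1e6            # electrons per m^3 per (g/cm^3)
  I_MeV <- mat$mean_excitation_eV * 1e-6
  L <- log(2 * k$electron_rest_mass_energy_MeV * beta2 /
             (I_MeV * (1 - beta2))) - beta2
  S_J_m <- coef_J_m2 * n_m3 / beta2 * L        # J/m per unit density
  S_J_m / k$joule_per_MeV / 100                # MeV cm^2/g
}

# internal: energy <-> mass-range table for one material, cached.
# Mass range (g/cm^2) from the cutoff up, by cumulative trapezoid of the
# inverse mass stopping power; monotone Hyman splines in both directions.
range_table <- function(mat, model) {
  key <- paste(mat$name, mat$density_g_cm3,
               paste(names(mat$composition), mat$composition, collapse = "|"),
               model$low_energy_cutoff, model$energy_grid_step, model$energy_max,
               sep = "@")
  hit <- .cy_cache$ranges[[key]]
  if (!is.null(hit)) return(hit)
  E <- seq(model$low_energy_cutoff, model$energy_max, by = model$energy_grid_step)
  if (E[length(E)] < model$energy_max) E <- c(E, model$energy_max)
  f <- 1 / mass_stopping_power(mat, E, model)
  h <- diff(E)
  R <- c(0, cumsum(h * (f[-1] + f[-length(f)]) / 2))   # g/cm^2
  tab <- list(
    E = E, R = R,
    fwd = stats::splinefun(E, R, method = "hyman"),    # E -> mass range
    inv = stats::splinefun(R, E, method = "hyman")     # mass range -> E
  )
  if (is.null(.cy_cache$ranges)) .cy_cache$ranges <- list()
  .cy_cache$ranges[[key]] <- tab
  tab
}

#' CSDA range of protons in a material
#'
#' Continuous-slowing-down-approximation path length
#' \deqn{R(E_0) = \int_0^{E_0} \left(\frac{dE}{dx}\right)^{-1} dE,}
#' evaluated by quadrature of the inverse Bethe stopping power. The integrand
#' is truncated at the model's low-energy cutoff and the sub-cutoff residual
#' is set to zero (it contributes below ~2 um in TeO2 at the default cutoff).
#'
#' @param mat a [material()].
#' @param energy_in proton energy in MeV (vectorized).
#' @param model a [stopping_model()].
#' @return projected CSDA range in micrometres. Strictly increasing in
#'   `energy_in`.
#' @examples
#' csda_range(material_teo2(), 14.8)   # ~ 8e2 um
#' @export
csda_range <- function(mat, energy_in, model = stopping_model()) {
  stopifnot(inherits(mat, "material"))
  if (any(energy_in < model$low_energy_cutoff - 1e-12) ||
      any(energy_in > model$energy_max + 1e-12)) {
    stop("energy_in outside the validity window [",
         model$low_energy_cutoff, ", ", model$energy_max, "] MeV")
  }
  tab <- range_table(mat, model)
  tab$fwd(energy_in) / mat$density_g_cm3 * 1e4
}

#' Proton energy after traversing a slab
#'
#' Degrades the beam through a slab of material by range inversion:
#' \eqn{E_{out} = R^{-1}(R(E_{in}) - \rho\,t)}. Returns `NA_real_` with
#' attribute `stopped = TRUE` when the residual range is non-positive or the
#' exit energy falls below the model cutoff: a fully absorbed beam is a
#' legitimate outcome of thickness sweeps, not an error.
#'
#' @param mat slab [material()].
#' @param thickness_mm slab thickness in mm, >= 0.
#' @param energy_in entrance energy in MeV.
#' @param model a [stopping_model()].
#' @return exit energy in MeV, or `NA_real_` (attribute `stopped`) if the
#'   beam is absorbed. Composing two slabs equals one combined slab within
#'   1e-3 MeV.
#' @examples
#' energy_after_slab(material_havar(), 0.2, 18)   # ~ 14.7 MeV
#' @export
energy_after_slab <- function(mat, thickness_mm, energy_in,
                              model = stopping_model()) {
  stopifnot(inherits(mat, "material"))
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1L ||
      !is.finite(thickness_mm) || thickness_mm < 0) {
    stop("'thickness_mm' must be a single non-negative number")
  }
  if (thickness_mm == 0) return(energy_in)
  tab <- range_table(mat, model)
  r_res <- tab$fwd(energy_in) - mat$density_g_cm3 * thickness_mm / 10
  if (r_res <= 0) {
    return(structure(NA_real_, stopped = TRUE))
  }
  e_out <- tab$inv(r_res)
  if (e_out < model$low_energy_cutoff) {
    return(structure(NA_real_, stopped = TRUE))
  }
  e_out
}

#' Test whether a degradation outcome is "beam stopped"
#'
#' @param x return value of [energy_after_slab()].
#' @return logical.
#' @export
is_stopped <- function(x) {
  isTRUE(attr(x, "stopped")) || (length(x) == 1L && is.na(x))
}

#' Energy window of the beam inside a target
#'
#' The entrance and exit energies of the beam across a target slab; these are
#' the integration limits of the thick-target yield integral. When the target
#' absorbs the beam the window closes at the model cutoff and
#' `fully_stopped` is set.
#'
#' @param target target [material()].
#' @param thickness_mm target thickness in mm.
#' @param energy_in entrance energy in MeV.
#' @param model a [stopping_model()].
#' @return list of class `"energy_window"`: `energy_in_MeV`,
#'   `energy_out_MeV`, `fully_stopped`.
#' @export
energy_window_in_target <- function(target, thickness_mm, energy_in,
                                    model = stopping_model()) {
  e_out <- energy_after_slab(target, thickness_mm, energy_in, model)
  if (is_stopped(e_out)) {
    out <- list(energy_in_MeV = energy_in,
                energy_out_MeV = model$low_energy_cutoff,
                fully_stopped = TRUE)
  } else {
    out <- list(energy_in_MeV = energy_in, energy_out_MeV = e_out,
                fully_stopped = FALSE)
  }
  structure(out, class = "energy_window")
}

# internal: Bohr range-straggling standard deviation, in g/cm^2.
# d(Omega^2)/d(rho x) = 4 pi k0^2 z^2 e^4 n_g = 0.1569 <Z/A> MeV^2 cm^2/g;
# propagated to a range variance through the inverse stopping power cubed.
bohr_range_sigma <- function(mat, energy_in, model) {
  k <- model$constants
  me_J <- k$electron_rest_mass_energy_MeV * k$joule_per_MeV
  # 4 pi k0^2 e^4 n_g in J^2 m^2 per (g/cm^2-ish); do it via the closed
  # coefficient: kappa = 4 pi r_e^2 (me c^2)^2 N_A <Z/A> = 0.1569 <Z/A>
  re_m <- k$coulomb_constant_N_m2_C2 * k$elementary_charge_C^2 / me_J
  kappa <- 4 * pi * re_m^2 * (k$electron_rest_mass_energy_MeV)^2 *
    mat$electrons_per_g * 1e4                     # MeV^2 cm^2/g
  E <- seq(model$low_energy_cutoff, energy_in, length.out = 2000L)
  f <- kappa / mass_stopping_power(mat, E, model)^3
  h <- E[2] - E[1]
  sqrt(sum(h * (f[-1] + f[-length(f)]) / 2))
}

#' Simulate a straggled proton range distribution
#'
#' Draws stopping depths as Gaussian deviates about the CSDA range with the
#' Bohr-straggling standard deviation. This is an explicit approximation to
#' full condensed-history transport: it reproduces the location and rough
#' width of the stopping-depth peak, and is used for qualitative comparison
#' only (the CSDA range itself is the quantitative output).
#'
#' @param mat a [material()].
#' @param energy_in proton energy in MeV.
#' @param n_protons number of simulated protons, >= 100.
#' @param seed mandatory RNG seed (no hidden global state is used).
#' @param model a [stopping_model()].
#' @param bin_width_um histogram bin width in micrometres.
#' @return object of class `"range_distribution"`: `depths_um` (bin
#'   centres), `weights` (counts), `mode_um` (kernel-density mode),
#'   `mean_um`, `sd_um`, `csda_um`, `seed`.
#' @export
simulate_range_distribution <- function(mat, energy_in, n_protons, seed,
                                        model = stopping_model(),
                                        bin_width_um = 2) {
  if (!is.numeric(n_protons) || n_protons < 100) {
    stop("'n_protons' must be >= 100")
  }
  r0 <- csda_range(mat, energy_in, model)
  sig <- bohr_range_sigma(mat, energy_in, model) / mat$density_g_cm3 * 1e4
  x <- with_local_seed(seed, stats::rnorm(n_protons, mean = r0, sd = sig))
  breaks <- seq(floor(min(x)) - bin_width_um, ceiling(max(x)) + bin_width_um,
                by = bin_width_um)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  d <- stats::density(x, n = 2048)
  structure(list(
    depths_um = h$mids, weights = h$counts,
    mode_um = d$x[which.max(d$y)],
    mean_um = mean(x), sd_um = stats::sd(x),
    csda_um = r0, straggling_sd_um = sig, seed = seed
  ), class = "range_distribution")
}

#' @export
print.range_distribution <- function(x, ...) {
  cat(sprintf(paste0("<range distribution  mode %.1f um  mean %.1f um  ",
                     "sd %.1f um  (CSDA %.1f um, n = %d, seed %s)>\n"),
              x$mode_um, x$mean_um, x$sd_um, x$csda_um,
              sum(x$weights), format(x$seed)))
  invisible(x)
}
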