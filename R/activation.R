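# Thick-target activation: excitation function x stopping power over the
# in-target energy window, with the saturation factor.

#' Beam specification
#'
#' @param energy proton energy in MeV at the first surface the beam meets
#'   (degrader entrance or target entrance). Must lie in the 1-30 MeV
#'   validity window of the stopping model.
#' @param current beam current in microampere.
#' @param time_h irradiation time in hours.
#' @return object of class `"beam_spec"`.
#' @examples
#' beam_spec(18, 10, 1.5)
#' @export
beam_spec <- function(energy, current, time_h) {
  if (!is.numeric(energy) || energy <= 0 || energy < 1 || energy > 30) {
    stop("'energy' must lie in the 1-30 MeV validity window")
  }
  if (!is.numeric(current) || current <= 0) stop("'current' must be > 0 uA")
  if (!is.numeric(time_h) || time_h <= 0) stop("'time_h' must be > 0 h")
  structure(list(energy_MeV = energy, current_uA = current, time_h = time_h),
            class = "beam_spec")
}

#' Target specification for activation
#'
#' Describes the irradiated slab and the parent isotope of the production
#' channel: which element carries the parent, its mass fraction in the
#' material, the isotopic abundance of the parent, and its molar mass. For
#' TeO2 the defaults pull the Te mass fraction from the material composition
#' and the molar mass from the bundled element table, so only the abundance
#' must be chosen (4.74% for natural Te, ~99.5% for enriched targets).
#'
#' @param mat target [material()].
#' @param thickness_mm target thickness in mm, > 0.
#' @param parent_isotope label of the parent isotope, e.g. `"Te-124"`.
#' @param parent_abundance isotopic abundance of the parent as a fraction in
#'   (0, 1].
#' @param parent_element element symbol carrying the parent; defaults to the
#'   element part of `parent_isotope`.
#' @param parent_mass_fraction mass fraction of that element in the material;
#'   defaults to the value in `mat$composition`.
#' @param parent_molar_mass g/mol; defaults to the bundled element table
#'   value for `parent_element`.
#' @return object of class `"target_spec"`.
#' @examples
#' target_spec(material_teo2(), 0.5, parent_abundance = 0.0474)
#' @export
target_spec <- function(mat, thickness_mm, parent_isotope = "Te-124",
                        parent_abundance, parent_element = NULL,
                        parent_mass_fraction = NULL, parent_molar_mass = NULL) {
  stopifnot(inherits(mat, "material"))
  if (!is.numeric(thickness_mm) || thickness_mm <= 0) {
    stop("'thickness_mm' must be > 0")
  }
  if (!is.numeric(parent_abundance) || parent_abundance <= 0 ||
      parent_abundance > 1) {
    stop("'parent_abundance' must be a fraction in (0, 1]")
  }
  if (is.null(parent_element)) {
    parent_element <- sub("-.*$", "", parent_isotope)
  }
  if (is.null(parent_mass_fraction)) {
    if (!parent_element %in% names(mat$composition)) {
      stop("parent element '", parent_element, "' is not in the composition of ",
           mat$name)
    }
    parent_mass_fraction <- unname(mat$composition[parent_element])
  }
  if (is.null(parent_molar_mass)) {
    parent_molar_mass <- lookup_element(parent_element)$molar_mass_g_mol
  }
  structure(list(material = mat, thickness_mm = thickness_mm,
                 parent_isotope = parent_isotope,
                 parent_element = parent_element,
                 parent_abundance = parent_abundance,
                 parent_mass_fraction = parent_mass_fraction,
                 parent_molar_mass_g_mol = parent_molar_mass),
            class = "target_spec")
}

#' Thick-target end-of-bombardment activity
#'
#' Standard activation equation for a slab target: the number of parent
#' atoms per gram is \eqn{N_A w f_a / M}, the per-proton reaction
#' probability is the excitation function integrated against the inverse
#' mass stopping power over the in-target energy window,
#' \deqn{P = \frac{N_A w f_a}{M}\int_{E_{out}}^{E_{in}}
#'   \frac{\sigma(E)}{(dE/d(\rho x))}\,dE,}
#' and the end-of-bombardment activity is the production rate scaled by the
#' saturation factor:
#' \deqn{A_{EOB} = \frac{I}{e}\,P\,(1 - e^{-\lambda t_{irr}}).}
#' Secondary reactions and beam attenuation are neglected; each channel is
#' computed independently from its own cross-section table.
#'
#' The energy window comes from [energy_window_in_target()]; the portion of
#' the window outside the tabulated cross-section grid contributes zero and
#' is flagged (`clipped`). An empty window yields a zero-activity result
#' with `empty_window = TRUE` and a warning.
#'
#' @param xs [cross_section_table()] of the channel.
#' @param target a [target_spec()].
#' @param beam a [beam_spec()]; `beam$energy_MeV` is the energy at the
#'   target entrance (degrade beforehand with [energy_after_slab()] or use
#'   [sweep_production()] / [run_plan()]).
#' @param model a [stopping_model()].
#' @param n_grid quadrature points across the energy window (trapezoid on a
#'   uniform grid refined with the cross-section grid nodes).
#' @return object of class `"yield_result"`: `eob_activity_MBq`,
#'   `saturation_activity_MBq`, `yield_MBq_per_uAh`, `energy_window_MeV`,
#'   `fully_stopped`, `clipped`, `empty_window`.
#' @export
thick_target_eob_activity <- function(xs, target, beam,
                                      model = stopping_model(),
                                      n_grid = 2000L) {
  stopifnot(inherits(xs, "xs_table"), inherits(target, "target_spec"),
            inherits(beam, "beam_spec"))
  win <- energy_window_in_target(target$material, target$thickness_mm,
                                 beam$energy_MeV, model)
  e_lo <- win$energy_out_MeV
  e_hi <- win$energy_in_MeV
  clipped <- e_hi > max(xs$energies_MeV) || e_lo < min(xs$energies_MeV)
  lo <- max(e_lo, min(xs$energies_MeV))
  hi <- min(e_hi, max(xs$energies_MeV))
  lambda <- xs$product$decay_constant_per_h
  sat <- 1 - exp(-lambda * beam$time_h)
  n_parent_per_g <- model$constants$avogadro_per_mol *
    target$parent_mass_fraction * target$parent_abundance /
    target$parent_molar_mass_g_mol
  protons_per_s <- beam$current_uA * 1e-6 / model$constants$elementary_charge_C

  if (!(hi > lo)) {
    warning("empty energy window: beam does not overlap the cross-section grid")
    res <- list(eob_activity_MBq = 0, saturation_activity_MBq = 0,
                yield_MBq_per_uAh = 0,
                energy_window_MeV = c(e_hi, e_lo),
                fully_stopped = win$fully_stopped, clipped = clipped,
                empty_window = TRUE)
    return(structure(res, class = "yield_result"))
  }
  grid <- sort(unique(c(seq(lo, hi, length.out = n_grid),
                        xs$energies_MeV[xs$energies_MeV > lo &
                                          xs$energies_MeV < hi])))
  f <- sigma_at(xs, grid) * 1e-27 /
    mass_stopping_power(target$material, grid, model)   # cm^2 * g/(MeV cm^2)
  h <- diff(grid)
  integral <- sum(h * (f[-1] + f[-length(f)]) / 2)      # g ... per-atom-per-g
  p_reaction <- n_parent_per_g * integral               # per proton
  a_sat_MBq <- protons_per_s * p_reaction / 1e6
  a_eob_MBq <- a_sat_MBq * sat
  res <- list(
    eob_activity_MBq = a_eob_MBq,
    saturation_activity_MBq = a_sat_MBq,
    yield_MBq_per_uAh = yield_per_uAh(a_eob_MBq, beam$current_uA, beam$time_h),
    energy_window_MeV = c(e_hi, e_lo),
    fully_stopped = win$fully_stopped,
    clipped = clipped,
    empty_window = FALSE
  )
  structure(res, class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf(paste0("<yield  EOB %.3f MBq  (saturation %.3f MBq)  ",
                     "%.3f MBq/uAh  window %.2f -> %.2f MeV%s%s>\n"),
              x$eob_activity_MBq, x$saturation_activity_MBq,
              x$yield_MBq_per_uAh, x$energy_window_MeV[1],
              x$energy_window_MeV[2],
              if (isTRUE(x$fully_stopped)) "  [beam stopped in target]" else "",
              if (isTRUE(x$clipped)) "  [window clipped to sigma grid]" else ""))
  invisible(x)
}

#' Production yield per integrated beam charge
#'
#' Normalizes an end-of-bombardment activity to MBq per microampere-hour,
#' the conventional unit for comparing production routes.
#'
#' @param eob_activity_MBq activity at EOB in MBq.
#' @param current_uA beam current in uA, > 0.
#' @param time_h irradiation time in hours, > 0.
#' @return yield in MBq/uAh.
#' @examples
#' yield_per_uAh(35.594, 15, 1.5)   # ~1.58
#' @export
yield_per_uAh <- function(eob_activity_MBq, current_uA, time_h) {
  if (!is.numeric(current_uA) || current_uA <= 0 ||
      !is.numeric(time_h) || time_h <= 0) {
    stop("current and irradiation time must be > 0")
  }
  eob_activity_MBq / (current_uA * time_h)
}

#' Sweep production over target and degrader-foil thicknesses
#'
#' Recomputes the thick-target yield for every (foil thickness, target
#' thickness) pair: the beam is degraded through the foil by range
#' inversion, then activated in the target. Rows where the foil already
#' absorbs the beam are flagged (`foil_stopped`) and carry zero yield.
#'
#' @param xs [cross_section_table()].
#' @param target a [target_spec()] used as template; its thickness is
#'   replaced by each value of `target_thicknesses_mm`.
#' @param target_thicknesses_mm numeric vector of target thicknesses (mm).
#' @param foil foil [material()].
#' @param foil_thicknesses_mm numeric vector of foil thicknesses (mm);
#'   0 means no degrader.
#' @param beam a [beam_spec()]; `beam$energy_MeV` is the energy entering
#'   the foil.
#' @param model a [stopping_model()].
#' @return data.frame with one row per (foil, target) pair: `foil_mm`,
#'   `target_mm`, `energy_at_target_MeV`, `energy_exit_MeV`, `foil_stopped`,
#'   `fully_stopped`, `eob_MBq`, `yield_MBq_per_uAh`.
#' @export
sweep_production <- function(xs, target, target_thicknesses_mm, foil,
                             foil_thicknesses_mm, beam,
                             model = stopping_model()) {
  stopifnot(inherits(foil, "material"), inherits(target, "target_spec"))
  if (any(target_thicknesses_mm < 0) || any(foil_thicknesses_mm < 0)) {
    stop("thicknesses must be >= 0")
  }
  grid <- expand.grid(foil_mm = foil_thicknesses_mm,
                      target_mm = target_thicknesses_mm,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  out <- data.frame(grid,
                    energy_at_target_MeV = NA_real_,
                    energy_exit_MeV = NA_real_,
                    foil_stopped = FALSE, fully_stopped = FALSE,
                    eob_MBq = 0, yield_MBq_per_uAh = 0)
  for (i in seq_len(n)) {
    e1 <- energy_after_slab(foil, grid$foil_mm[i], beam$energy_MeV, model)
    if (is_stopped(e1)) {
      out$foil_stopped[i] <- TRUE
      next
    }
    out$energy_at_target_MeV[i] <- e1
    tgt <- target
    tgt$thickness_mm <- grid$target_mm[i]
    b <- beam
    b$energy_MeV <- e1
    y <- suppressWarnings(thick_target_eob_activity(xs, tgt, b, model))
    out$energy_exit_MeV[i] <- y$energy_window_MeV[2]
    out$fully_stopped[i] <- y$fully_stopped
    out$eob_MBq[i] <- y$eob_activity_MBq
    out$yield_MBq_per_uAh[i] <- y$yield_MBq_per_uAh
  }
  out
}
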