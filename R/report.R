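# Pipeline driver: degrade -> energy window -> yield -> decay -> purity.

#' Run a production plan
#'
#' Chains the pipeline stages into one machine-readable report: foil
#' degradation, in-target energy window, thick-target activation yield,
#' decay trajectory of an inventory at requested times, and the purity
#' release-time solution. Every numeric in the report carries its unit in
#' its name, and the resolved configuration (with the seed) is echoed so
#' that a rerun of the echoed configuration reproduces the report exactly.
#'
#' The configuration is a plain named list (directly serializable to and
#' from JSON). Material, cross-section and inventory references may be
#' given as objects, file paths, or `"fixture:<name>"` strings (bare
#' fixture names are also accepted); all references are resolved before any
#' stage runs, so a broken reference fails fast.
#'
#' Recognized fields:
#' \describe{
#'   \item{beam}{list `energy_MeV`, `current_uA`, `time_h` (required).}
#'   \item{foil}{list `material`, `thickness_mm`; optional.}
#'   \item{target}{list `material`, `thickness_mm`, `parent_abundance`, and
#'     optionally `parent_isotope`; required for the yield stage.}
#'   \item{xs}{cross-section reference (`"fixture:toy_xs"`, a CSV path, or
#'     an [cross_section_table()]); required for the yield stage.}
#'   \item{inventory}{inventory reference; optional.}
#'   \item{decay_times_h}{times (h after EOB) at which the inventory is
#'     reported; default 72.}
#'   \item{purity}{list `impurity` (default `"I-123"`), `threshold`
#'     (default 0.0035), `bracket`; optional, needs `inventory`.}
#'   \item{seed}{echoed into the report (stages are deterministic).}
#' }
#'
#' @param config named list as above.
#' @param model a [stopping_model()].
#' @return object of class `"run_report"`: a nested list with elements
#'   `config` (echo), `degrader`, `energy_window`, `yield`, `decay`,
#'   `purity` (stages not requested are `NULL`), plus `package_version`.
#' @examples
#' rep <- run_plan(list(
#'   beam = list(energy_MeV = 18, current_uA = 10, time_h = 1.5),
#'   foil = list(material = "havar", thickness_mm = 0.2),
#'   target = list(material = "teo2", thickness_mm = 0.5,
#'                 parent_abundance = 0.0474),
#'   xs = "fixture:toy_xs"))
#' rep$degrader$energy_out_MeV   # ~14.7
#' @export
run_plan <- function(config, model = stopping_model()) {
  if (!is.list(config) || is.null(config$beam)) {
    stop("'config' must be a list with at least a 'beam' entry")
  }
  beam <- beam_spec(config$beam$energy_MeV, config$beam$current_uA,
                    config$beam$time_h)

  # resolve every reference up front
  foil_mat <- if (!is.null(config$foil)) resolve_material(config$foil$material)
  target_mat <- if (!is.null(config$target)) resolve_material(config$target$material)
  xs <- if (!is.null(config$xs)) resolve_xs(config$xs)
  inv <- if (!is.null(config$inventory)) resolve_inventory(config$inventory)
  if (!is.null(config$purity) && is.null(inv)) {
    stop("purity stage requested but no inventory is configured")
  }

  report <- list(config = config,
                 package_version = as.character(utils::packageVersion("cycloyield")))

  # stage: degrader
  e_target <- beam$energy_MeV
  if (!is.null(foil_mat)) {
    e_out <- energy_after_slab(foil_mat, config$foil$thickness_mm,
                               beam$energy_MeV, model)
    if (is_stopped(e_out)) {
      stop("stage 'degrader': beam of ", beam$energy_MeV,
           " MeV is fully absorbed in ", config$foil$thickness_mm, " mm of ",
           foil_mat$name)
    }
    report$degrader <- list(material = foil_mat$name,
                            thickness_mm = config$foil$thickness_mm,
                            energy_in_MeV = beam$energy_MeV,
                            energy_out_MeV = e_out)
    e_target <- e_out
  }

  # stage: energy window + yield
  if (!is.null(target_mat)) {
    tgt <- target_spec(target_mat, config$target$thickness_mm,
                       parent_isotope = config$target$parent_isotope %||% "Te-124",
                       parent_abundance = config$target$parent_abundance)
    win <- energy_window_in_target(target_mat, tgt$thickness_mm, e_target, model)
    report$energy_window <- list(energy_in_MeV = win$energy_in_MeV,
                                 energy_out_MeV = win$energy_out_MeV,
                                 fully_stopped = win$fully_stopped)
    if (!is.null(xs)) {
      b <- beam; b$energy_MeV <- e_target
      y <- thick_target_eob_activity(xs, tgt, b, model)
      report$yield <- list(channel = xs$channel,
                           eob_activity_MBq = y$eob_activity_MBq,
                           saturation_activity_MBq = y$saturation_activity_MBq,
                           yield_MBq_per_uAh = y$yield_MBq_per_uAh,
                           energy_window_MeV = y$energy_window_MeV,
                           fully_stopped = y$fully_stopped,
                           clipped = y$clipped)
    }
  }

  # stage: decay trajectory
  if (!is.null(inv)) {
    times <- config$decay_times_h %||% 72
    report$decay <- lapply(times, function(t) {
      d <- decay_inventory(inv, t)
      list(time_h = t, total_MBq = total_activity(d),
           activities_MBq = as.list(d$activities_MBq))
    })
    names(report$decay) <- paste0("t_", times, "h")
  }

  # stage: purity
  if (!is.null(config$purity)) {
    p <- purity_time(inv,
                     impurity = config$purity$impurity %||% "I-123",
                     threshold = config$purity$threshold %||% 0.0035,
                     bracket = unlist(config$purity$bracket %||% c(0.5, 1000)))
    report$purity <- list(status = p$status,
                          release_time_h = p$release_time_h,
                          product = p$product,
                          product_activity_MBq = p$product_activity_MBq,
                          impurity = p$impurity,
                          impurity_activity_MBq = p$impurity_activity_MBq,
                          impurity_fraction_pct = 100 * p$impurity_fraction)
  }

  structure(report, class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_material <- function(x) {
  if (inherits(x, "material")) return(x)
  if (is.character(x) && length(x) == 1L) {
    name <- sub("^fixture:", "", x)
    if (name %in% list_fixtures()) {
      m <- load_fixture(name)
      if (!inherits(m, "material")) stop("fixture '", name, "' is not a material")
      return(m)
    }
    if (file.exists(x)) return(read_material(x))
    stop("cannot resolve material reference '", x, "'")
  }
  stop("material reference must be a material, fixture name or file path")
}

resolve_xs <- function(x) {
  if (inherits(x, "xs_table")) return(x)
  if (is.character(x) && length(x) == 1L) {
    name <- sub("^fixture:", "", x)
    if (name %in% list_fixtures()) {
      xs <- load_fixture(name)
      if (!inherits(xs, "xs_table")) stop("fixture '", name, "' is not a cross-section table")
      return(xs)
    }
    if (file.exists(x)) return(read_xs_csv(x))
    stop("cannot resolve cross-section reference '", x, "'")
  }
  stop("xs reference must be an xs_table, fixture name or file path")
}

resolve_inventory <- function(x) {
  if (inherits(x, "activity_inventory")) return(x)
  if (is.character(x) && length(x) == 1L) {
    name <- sub("^fixture:", "", x)
    if (name %in% list_fixtures()) {
      inv <- load_fixture(name)
      if (!inherits(inv, "activity_inventory")) {
        stop("fixture '", name, "' is not an inventory")
      }
      return(inv)
    }
    if (file.exists(x)) return(read_inventory_csv(x))
    stop("cannot resolve inventory reference '", x, "'")
  }
  stop("inventory reference must be an inventory, fixture name or file path")
}

#' Write a run report to JSON
#'
#' Serializes a [run_plan()] report (no timestamps are embedded, so reports
#' from identical configurations are byte-identical).
#'
#' @param report a `"run_report"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<production run report  cycloyield", x$package_version, ">\n")
  if (!is.null(x$degrader)) {
    cat(sprintf("  degrader: %s %.3g mm, %.4g -> %.4g MeV\n",
                x$degrader$material, x$degrader$thickness_mm,
                x$degrader$energy_in_MeV, x$degrader$energy_out_MeV))
  }
  if (!is.null(x$energy_window)) {
    cat(sprintf("  target window: %.4g -> %.4g MeV%s\n",
                x$energy_window$energy_in_MeV, x$energy_window$energy_out_MeV,
                if (x$energy_window$fully_stopped) " (beam stopped)" else ""))
  }
  if (!is.null(x$yield)) {
    cat(sprintf("  yield [%s]: EOB %.4g MBq, %.4g MBq/uAh\n",
                x$yield$channel, x$yield$eob_activity_MBq,
                x$yield$yield_MBq_per_uAh))
  }
  if (!is.null(x$decay)) {
    for (d in x$decay) {
      cat(sprintf("  inventory at %g h: total %.4g MBq\n", d$time_h, d$total_MBq))
    }
  }
  if (!is.null(x$purity)) {
    cat(sprintf("  purity: %s at %.4g%% of total at %.5g h (%s %.4g MBq)\n",
                x$purity$impurity, x$purity$impurity_fraction_pct,
                x$purity$release_time_h, x$purity$product,
                x$purity$product_activity_MBq))
  }
  invisible(x)
}
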