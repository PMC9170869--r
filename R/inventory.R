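# Multi-nuclide activity inventories: decay, fractions, release-time solver.

#' Create an activity inventory
#'
#' A map nuclide -> activity at a common reference time (hours relative to
#' the end of bombardment, 0 = EOB). Each nuclide decays independently;
#' parent-to-daughter ingrowth is out of scope (the bundled reference
#' inventories are exactly entry-wise exponential, as their printed 72 h
#' columns confirm).
#'
#' @param nuclides list of [nuclide()] objects (or a single one).
#' @param activities_MBq non-negative activities, same length.
#' @param reference_time_h reference time in hours after EOB (default 0).
#' @return object of class `"activity_inventory"`.
#' @examples
#' inv <- activity_inventory(list(nuclide("I-124", 4.2, "d"),
#'                                nuclide("I-123", 13.2, "h")),
#'                           c(214.711, 672.623))
#' total_activity(inv)
#' @export
activity_inventory <- function(nuclides, activities_MBq, reference_time_h = 0) {
  if (inherits(nuclides, "nuclide")) nuclides <- list(nuclides)
  if (!is.list(nuclides) ||
      !all(vapply(nuclides, inherits, TRUE, "nuclide"))) {
    stop("'nuclides' must be a list of nuclide objects")
  }
  if (length(nuclides) != length(activities_MBq)) {
    stop("'nuclides' and 'activities_MBq' must have the same length")
  }
  if (any(activities_MBq < 0) || any(!is.finite(activities_MBq))) {
    stop("activities must be finite and >= 0")
  }
  syms <- vapply(nuclides, `[[`, "", "symbol")
  if (anyDuplicated(syms)) {
    stop("duplicate nuclide symbol(s): ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  }
  names(nuclides) <- syms
  structure(list(nuclides = nuclides,
                 activities_MBq = stats::setNames(as.numeric(activities_MBq), syms),
                 negligible = stats::setNames(rep(FALSE, length(syms)), syms),
                 reference_time_h = reference_time_h),
            class = "activity_inventory")
}

#' @export
print.activity_inventory <- function(x, ...) {
  cat(sprintf("<activity inventory  %d nuclides  total %.3f MBq  t = %g h after EOB>\n",
              length(x$nuclides), total_activity(x), x$reference_time_h))
  df <- as.data.frame(x)
  print(df[order(-df$activity_MBq), ], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.activity_inventory <- function(x, ...) {
  data.frame(symbol = names(x$activities_MBq),
             half_life_h = vapply(x$nuclides, `[[`, 0, "half_life_h"),
             activity_MBq = unname(x$activities_MBq),
             negligible = unname(x$negligible),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Decay a single activity
#'
#' \eqn{A(t) = A_0\, 2^{-t/T_{1/2}}}. Negative `dt_h` is rejected: the
#' inventory model does not back-extrapolate.
#'
#' @param activity0_MBq activity at the reference time, MBq.
#' @param nuc a [nuclide()].
#' @param dt_h elapsed time in hours, >= 0.
#' @return decayed activity in MBq.
#' @examples
#' decay_activity(100, nuclide("X", 10, "h"), 10)  # 50
#' @export
decay_activity <- function(activity0_MBq, nuc, dt_h) {
  stopifnot(inherits(nuc, "nuclide"))
  if (!is.numeric(dt_h) || any(dt_h < 0)) {
    stop("'dt_h' must be >= 0 (no back-extrapolation)")
  }
  activity0_MBq * 2^(-dt_h / nuc$half_life_h)
}

#' Decay a whole inventory
#'
#' Entry-wise exponential decay of every nuclide; the reference time is
#' advanced by `dt_h`. Entries that fall below `floor_MBq` are retained but
#' flagged negligible.
#'
#' @param inv an [activity_inventory()].
#' @param dt_h elapsed time in hours, >= 0.
#' @param floor_MBq negligibility floor (default 1e-6 MBq).
#' @return the decayed [activity_inventory()].
#' @export
decay_inventory <- function(inv, dt_h, floor_MBq = 1e-6) {
  stopifnot(inherits(inv, "activity_inventory"))
  if (!is.numeric(dt_h) || length(dt_h) != 1L || dt_h < 0) {
    stop("'dt_h' must be a single value >= 0")
  }
  hl <- vapply(inv$nuclides, `[[`, 0, "half_life_h")
  inv$activities_MBq <- inv$activities_MBq * 2^(-dt_h / hl)
  inv$negligible <- inv$activities_MBq < floor_MBq
  inv$reference_time_h <- inv$reference_time_h + dt_h
  inv
}

#' Total activity of an inventory
#'
#' @param inv an [activity_inventory()].
#' @return sum of all activities in MBq.
#' @export
total_activity <- function(inv) {
  stopifnot(inherits(inv, "activity_inventory"))
  sum(inv$activities_MBq)
}

#' Activity fraction of one nuclide
#'
#' @param inv an [activity_inventory()].
#' @param symbol nuclide symbol; must be present.
#' @return percentage of the total activity (0-100).
#' @export
activity_fraction <- function(inv, symbol) {
  stopifnot(inherits(inv, "activity_inventory"))
  if (!symbol %in% names(inv$activities_MBq)) {
    stop("nuclide '", symbol, "' is not in the inventory")
  }
  100 * unname(inv$activities_MBq[symbol]) / total_activity(inv)
}

#' Solve for the pharmacopoeial release time
#'
#' Finds the first time after the reference time at which the activity
#' fraction of a named impurity drops to a threshold of the *total*
#' remaining activity (all species counted in the denominator). The Ph. Eur.
#' limit for I-123 in an I-124 preparation, impurity/total <= 0.35%, is the
#' default threshold.
#'
#' A coarse scan over the bracket locates the first downward crossing of
#' the threshold; bisection then refines it until the fraction matches the
#' threshold within `tol`. If the impurity fraction is already at or below
#' the threshold at the bracket start, an "already pure" result at the
#' bracket start is returned. If the trajectory never crosses inside the
#' bracket, an explicit no-solution result (not an error) reports the
#' fraction range seen.
#'
#' @param inv an [activity_inventory()] (reference time = EOB for release
#'   planning).
#' @param impurity symbol of the impurity nuclide, e.g. `"I-123"`.
#' @param threshold impurity fraction threshold (default 0.0035 = 0.35%).
#' @param bracket search interval in hours after the reference time
#'   (default `c(0.5, 1000)`).
#' @param product symbol of the product nuclide whose activity is reported
#'   at release; defaults to the largest-activity nuclide at the release
#'   time.
#' @param tol tolerance on |fraction - threshold| (default 1e-6).
#' @param n_scan number of coarse-scan points across the bracket.
#' @return object of class `"purity_result"` with `release_time_h` (hours
#'   after the inventory reference time), `product`, `product_activity_MBq`,
#'   `impurity_activity_MBq`, `impurity_fraction`, `bracket_h`, `status`
#'   (`"solved"`, `"already_pure"` or `"no_crossing"`), and for
#'   `"no_crossing"` the `fraction_range` seen.
#' @examples
#' inv <- load_fixture("inventory_natural_15uA")
#' purity_time(inv, "I-123")   # ~122 h
#' @export
purity_time <- function(inv, impurity, threshold = 0.0035,
                        bracket = c(0.5, 1000), product = NULL,
                        tol = 1e-6, n_scan = 1024L) {
  stopifnot(inherits(inv, "activity_inventory"))
  if (!impurity %in% names(inv$activities_MBq)) {
    stop("impurity '", impurity, "' is not in the inventory")
  }
  if (length(bracket) != 2L || bracket[1] <= 0 || bracket[2] <= bracket[1]) {
    stop("'bracket' must be increasing positive times (h)")
  }
  hl <- vapply(inv$nuclides, `[[`, 0, "half_life_h")
  a0 <- inv$activities_MBq
  frac_at <- function(t) {
    a <- a0 * 2^(-t / hl)
    unname(a[impurity]) / sum(a)
  }
  result <- function(t, status, frange = NULL) {
    a <- a0 * 2^(-t / hl)
    prod_sym <- if (is.null(product)) names(which.max(a)) else product
    structure(list(release_time_h = t,
                   product = prod_sym,
                   product_activity_MBq = unname(a[prod_sym]),
                   impurity = impurity,
                   impurity_activity_MBq = unname(a[impurity]),
                   impurity_fraction = unname(a[impurity]) / sum(a),
                   threshold = threshold,
                   bracket_h = bracket, status = status,
                   fraction_range = frange),
              class = "purity_result")
  }
  ts <- seq(bracket[1], bracket[2], length.out = n_scan)
  fs <- vapply(ts, frac_at, 0)
  if (fs[1] <= threshold) {
    return(result(bracket[1], "already_pure"))
  }
  cross <- which(fs[-length(fs)] > threshold & fs[-1] <= threshold)
  if (length(cross) == 0L) {
    return(result(bracket[2], "no_crossing", frange = range(fs)))
  }
  lo <- ts[cross[1]]; hi <- ts[cross[1] + 1L]
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- frac_at(mid)
    if (abs(fm - threshold) <= tol) {
      return(result(mid, "solved"))
    }
    if (fm > threshold) lo <- mid else hi <- mid
  }
  result((lo + hi) / 2, "solved")
}

#' @export
print.purity_result <- function(x, ...) {
  if (x$status == "no_crossing") {
    cat(sprintf(paste0("<purity: no crossing of %.4g%% in [%g, %g] h; ",
                       "%s fraction spans %.4g%% - %.4g%%>\n"),
                100 * x$threshold, x$bracket_h[1], x$bracket_h[2], x$impurity,
                100 * x$fraction_range[1], 100 * x$fraction_range[2]))
    return(invisible(x))
  }
  cat(sprintf(paste0("<release at %.2f h after reference (%s): %s %.3f MBq, ",
                     "%s %.3f MBq = %.4g%% of total%s>\n"),
              x$release_time_h, x$status, x$product, x$product_activity_MBq,
              x$impurity, x$impurity_activity_MBq, 100 * x$impurity_fraction,
              if (x$status == "already_pure") " (below threshold at bracket start)" else ""))
  invisible(x)
}

#' Experiment-versus-simulation relative difference
#'
#' The difference statistic used when comparing measured and simulated
#' activities: \eqn{|A_{sim} - A_{exp}| / A_{exp} \cdot 100}.
#'
#' @param experimental measured activity, > 0.
#' @param simulated simulated activity.
#' @return non-negative percentage.
#' @examples
#' relative_difference(20.72, 33.30)  # 60.71
#' @export
relative_difference <- function(experimental, simulated) {
  if (any(!is.numeric(experimental)) || any(experimental <= 0)) {
    stop("'experimental' must be > 0")
  }
  abs(simulated - experimental) / experimental * 100
}

#' Read / write inventory CSV files
#'
#' Format: `symbol,half_life,unit,activity_MBq`, with an optional
#' `decay_modes` column (`mode:percent` pairs separated by `";"`).
#'
#' @param file CSV path.
#' @param reference_time_h reference time of the stored activities.
#' @return an [activity_inventory()] for `read_inventory_csv`; `file`
#'   invisibly for `write_inventory_csv`.
#' @export
read_inventory_csv <- function(file, reference_time_h = 0) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("symbol", "half_life", "unit", "activity_MBq")
  if (!all(need %in% names(df))) {
    stop("inventory CSV must have columns ", paste(need, collapse = ","))
  }
  nucs <- lapply(seq_len(nrow(df)), function(i) {
    nuclide(df$symbol[i], df$half_life[i], df$unit[i],
            if ("decay_modes" %in% names(df)) df$decay_modes[i])
  })
  activity_inventory(nucs, df$activity_MBq, reference_time_h)
}

#' @rdname read_inventory_csv
#' @param inv an [activity_inventory()] (for `write_inventory_csv`).
#' @export
write_inventory_csv <- function(inv, file) {
  df <- as.data.frame(inv)
  utils::write.csv(data.frame(symbol = df$symbol,
                              half_life = df$half_life_h, unit = "h",
                              activity_MBq = df$activity_MBq),
                   file, row.names = FALSE)
  invisible(file)
}
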