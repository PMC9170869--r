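#' Convert a duration to hours
#'
#' All inventory bookkeeping in the package is done in hours; half-lives are
#' accepted in any of the units that appear in nuclide data sheets.
#'
#' @param value numeric duration value(s), must be positive.
#' @param unit character unit, one of `"ms"`, `"s"`, `"min"`, `"h"`, `"d"`,
#'   `"y"` (recycled against `value`).
#' @return numeric vector of durations in hours.
#' @examples
#' duration_to_hours(4.2, "d")   # 100.8
#' duration_to_hours(806.7, "ms")
#' @export
duration_to_hours <- function(value, unit) {
  factors <- c(ms = 1 / 3.6e6, s = 1 / 3600, min = 1 / 60, h = 1, d = 24,
               y = 24 * 365.25)
  unit <- as.character(unit)
  bad <- !(unit %in% names(factors))
  if (any(bad)) {
    stop("unknown duration unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         " (expected one of ", paste(names(factors), collapse = ", "), ")")
  }
  unname(as.numeric(value) * factors[unit])
}

# internal: run expr with a fixed RNG seed, restoring global RNG state after
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}
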