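# Nuclide objects: the unit of all activity bookkeeping.

#' Create a nuclide
#'
#' A nuclide carries its half-life (stored internally in hours), the derived
#' decay constant \eqn{\lambda = \ln 2 / T_{1/2}}, and optionally a set of
#' decay modes with branching percentages.
#'
#' @param symbol nuclide symbol, e.g. `"I-124"`.
#' @param half_life positive half-life value.
#' @param unit unit of `half_life`: `"ms"`, `"s"`, `"min"`, `"h"`, `"d"` or `"y"`.
#' @param decay_modes optional; either a data.frame with columns `mode` and
#'   `percent`, or a string of `mode:percent` pairs separated by `";"`,
#'   e.g. `"B-:93.1;ECB+:6.9"`. Branching percentages must sum to 100 (±0.01).
#' @return object of class `"nuclide"` with fields `symbol`, `half_life_h`,
#'   `decay_constant_per_h`, `decay_modes`.
#' @examples
#' i124 <- nuclide("I-124", 4.2, "d")
#' i124$half_life_h          # 100.8
#' i124$decay_constant_per_h # log(2)/100.8
#' @export
nuclide <- function(symbol, half_life, unit = "h", decay_modes = NULL) {
  if (!is.character(symbol) || length(symbol) != 1L || !nzchar(symbol)) {
    stop("'symbol' must be a non-empty string")
  }
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0) {
    stop("nuclide '", symbol, "': half-life must be a positive number, got ",
         format(half_life))
  }
  hl_h <- duration_to_hours(half_life, unit)
  modes <- parse_decay_modes(decay_modes, symbol = symbol)
  structure(list(
    symbol = symbol,
    half_life_h = hl_h,
    decay_constant_per_h = log(2) / hl_h,
    decay_modes = modes
  ), class = "nuclide")
}

# internal: normalize decay-mode input to a data.frame and validate branching
parse_decay_modes <- function(x, symbol = "?") {
  if (is.null(x) || (is.character(x) && length(x) == 1L && !nzchar(x))) {
    return(NULL)
  }
  if (is.character(x)) {
    pairs <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    ok <- vapply(pairs, length, 0L) == 2L
    if (!all(ok)) {
      stop("nuclide '", symbol, "': decay modes must be 'mode:percent' pairs ",
           "separated by ';', got '", x, "'")
    }
    x <- data.frame(mode = vapply(pairs, `[`, "", 1L),
                    percent = as.numeric(vapply(pairs, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || !all(c("mode", "percent") %in% names(x))) {
    stop("nuclide '", symbol,
         "': decay_modes must be a 'mode:percent' string or a data.frame")
  }
  if (any(!is.finite(x$percent)) || any(x$percent < 0)) {
    stop("nuclide '", symbol, "': branching percentages must be non-negative")
  }
  if (abs(sum(x$percent) - 100) > 0.01) {
    stop("nuclide '", symbol, "': branching percentages sum to ",
         format(sum(x$percent)), ", expected 100 (+-0.01)")
  }
  x
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s  T1/2 = %g h  lambda = %g /h>\n",
              x$symbol, x$half_life_h, x$decay_constant_per_h))
  if (!is.null(x$decay_modes)) {
    cat("  decay: ",
        paste(sprintf("%s %.4g%%", x$decay_modes$mode, x$decay_modes$percent),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a nuclide table from CSV
#'
#' Expected header: `symbol,half_life,unit` and optionally `decay_modes`
#' (`mode:percent` pairs separated by `";"`). Duplicate symbols and
#' non-positive half-lives are rejected with the offending row named.
#'
#' @param file path to a CSV file.
#' @return named list of [nuclide()] objects.
#' @seealso [write_nuclide_table()], [default_nuclides()]
#' @export
read_nuclide_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("symbol", "half_life", "unit")
  if (!all(need %in% names(df))) {
    stop("nuclide table must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$symbol)) {
    stop("duplicate nuclide symbol(s): ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      nuclide(df$symbol[i], df$half_life[i], df$unit[i],
              if ("decay_modes" %in% names(df)) df$decay_modes[i]),
      error = function(e) stop("row ", i, " of '", basename(file), "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  names(out) <- df$symbol
  out
}

#' Write a nuclide table to CSV
#'
#' Inverse of [read_nuclide_table()]: round-trips all fields (half-lives are
#' written in hours).
#'
#' @param nuclides named list of [nuclide()] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_nuclide_table <- function(nuclides, file) {
  fmt_modes <- function(n) {
    if (is.null(n$decay_modes)) return("")
    paste(sprintf("%s:%.15g", n$decay_modes$mode, n$decay_modes$percent),
          collapse = ";")
  }
  df <- data.frame(
    symbol = vapply(nuclides, `[[`, "", "symbol"),
    half_life = vapply(nuclides, `[[`, 0, "half_life_h"),
    unit = "h",
    decay_modes = vapply(nuclides, fmt_modes, ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Bundled nuclide constants
#'
#' The package ships a versioned table of evaluated (NNDC-style) half-lives
#' for the nuclides appearing in TeO2 proton-irradiation inventories. These
#' are the library defaults; reference inventories loaded with
#' [load_fixture()] carry their own per-table half-lives.
#'
#' @return named list of [nuclide()] objects.
#' @examples
#' default_nuclides()[["I-124"]]$half_life_h / 24  # 4.176 d
#' @export
default_nuclides <- function() {
  if (is.null(.cy_cache$nuclides)) {
    path <- system.file("extdata", "nuclides.csv", package = "cycloyield",
                        mustWork = TRUE)
    .cy_cache$nuclides <- read_nuclide_table(path)
  }
  .cy_cache$nuclides
}

#' Look up a bundled nuclide by symbol
#'
#' @param symbol nuclide symbol, e.g. `"I-123"`.
#' @return a [nuclide()] object.
#' @export
get_nuclide <- function(symbol) {
  tab <- default_nuclides()
  if (!symbol %in% names(tab)) {
    stop("nuclide '", symbol, "' not in the bundled table; build it with nuclide()")
  }
  tab[[symbol]]
}
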