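# Excitation-function tables: the kernel of the thick-target yield integral.

#' Create a cross-section (excitation function) table
#'
#' Tabulated reaction cross section versus proton energy for one production
#' channel, e.g. `Te-124(p,n)I-124`. Between grid points the cross section is
#' interpolated linearly; outside the grid it is zero (no extrapolation) --
#' conservative and reproducible.
#'
#' @param channel channel label, e.g. `"Te-124(p,n)I-124"`.
#' @param product the product [nuclide()].
#' @param energies strictly increasing energy grid in MeV (>= 3 points).
#' @param sigma_mb non-negative cross sections in millibarn, same length.
#' @param source free-text provenance tag (`"synthetic"`, `"user"`, ...).
#' @return object of class `"xs_table"`.
#' @export
cross_section_table <- function(channel, product, energies, sigma_mb,
                                source = "user") {
  stopifnot(inherits(product, "nuclide"))
  if (length(energies) < 3L) stop("need at least 3 grid points")
  if (length(energies) != length(sigma_mb)) {
    stop("'energies' and 'sigma_mb' must have the same length")
  }
  if (any(diff(energies) <= 0)) stop("'energies' must be strictly increasing")
  if (any(sigma_mb < 0) || any(!is.finite(sigma_mb))) {
    stop("'sigma_mb' must be finite and non-negative")
  }
  structure(list(channel = channel, product = product,
                 energies_MeV = as.numeric(energies),
                 sigma_mb = as.numeric(sigma_mb),
                 source = source),
            class = "xs_table")
}

#' Interpolate an excitation function
#'
#' @param xs an [cross_section_table()].
#' @param energy energies in MeV (vectorized).
#' @return cross section in mb; zero outside the tabulated grid.
#' @export
sigma_at <- function(xs, energy) {
  stopifnot(inherits(xs, "xs_table"))
  out <- stats::approx(xs$energies_MeV, xs$sigma_mb, xout = energy,
                       method = "linear", yleft = 0, yright = 0)$y
  out[is.na(out)] <- 0
  out
}

#' @export
print.xs_table <- function(x, ...) {
  cat(sprintf("<excitation function %s  %d points on [%g, %g] MeV  peak %.1f mb  (%s)>\n",
              x$channel, length(x$energies_MeV), min(x$energies_MeV),
              max(x$energies_MeV), max(x$sigma_mb), x$source))
  invisible(x)
}

#' Read / write excitation-function CSV files
#'
#' The CSV carries the numeric table (`energy_MeV,sigma_mb`, one channel per
#' file); channel metadata lives in a sidecar JSON with fields `channel`,
#' `product` and `product_half_life_h`. `read_xs_csv()` looks for
#' `<file-sans-ext>.json` when `sidecar` is not given.
#'
#' @param file CSV path.
#' @param sidecar optional path of the metadata JSON.
#' @return [cross_section_table()] for `read_xs_csv`; `file` invisibly for
#'   `write_xs_csv`.
#' @export
read_xs_csv <- function(file, sidecar = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("energy_MeV", "sigma_mb") %in% names(df))) {
    stop("cross-section CSV must have columns energy_MeV,sigma_mb")
  }
  if (is.null(sidecar)) {
    sidecar <- paste0(tools::file_path_sans_ext(file), ".json")
  }
  if (!file.exists(sidecar)) {
    stop("missing channel metadata sidecar: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  prod <- nuclide(meta$product, meta$product_half_life_h, "h")
  cross_section_table(meta$channel, prod, df$energy_MeV, df$sigma_mb,
                      source = basename(file))
}

#' @rdname read_xs_csv
#' @param xs an [cross_section_table()] (for `write_xs_csv`).
#' @export
write_xs_csv <- function(xs, file, sidecar = NULL) {
  utils::write.csv(data.frame(energy_MeV = xs$energies_MeV,
                              sigma_mb = xs$sigma_mb),
                   file, row.names = FALSE)
  if (is.null(sidecar)) {
    sidecar <- paste0(tools::file_path_sans_ext(file), ".json")
  }
  jsonlite::write_json(list(channel = xs$channel,
                            product = xs$product$symbol,
                            product_half_life_h = xs$product$half_life_h),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
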