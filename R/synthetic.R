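# Synthetic inputs: calibrated toy excitation functions, randomized
# inventories, and the bundled reference datasets.

#' Calibrated toy excitation function
#'
#' A single-peaked Gaussian excitation function
#' \deqn{\sigma(E) = \sigma_p \exp\!\left(-\frac{(E - E_p)^2}{2 w^2}\right)}
#' whose width and peak height are solved analytically from two anchor
#' constraints on the Te-124(p,n)I-124 channel: the cross section is about
#' 300 mb at 14 MeV and about three times lower at 18 MeV; the peak sits
#' near 13 MeV. The Gaussian shape is chosen for analytic tractability --
#' it is *not* a fit to the evaluated excitation function, and quantitative
#' yield claims use only the anchored constraints.
#'
#' @param peak_energy peak position in MeV, in (10, 16).
#' @param grid tabulation grid in MeV (default 0.1 MeV steps over 4-20 MeV).
#' @param anchor_energy,anchor_sigma_mb the absolute anchor
#'   (default sigma(14 MeV) = 300 mb).
#' @param ratio_energy,ratio the relative anchor (default
#'   sigma(14)/sigma(18) = 3).
#' @param product product [nuclide()] (default bundled I-124).
#' @return a [cross_section_table()] with `source = "synthetic"`.
#' @examples
#' xs <- calibrated_toy_xs()
#' sigma_at(xs, 14)          # 300
#' sigma_at(xs, 14) / sigma_at(xs, 18)  # 3
#' @export
calibrated_toy_xs <- function(peak_energy = 13,
                              grid = seq(4, 20, by = 0.1),
                              anchor_energy = 14, anchor_sigma_mb = 300,
                              ratio_energy = 18, ratio = 3,
                              product = get_nuclide("I-124")) {
  if (peak_energy <= 10 || peak_energy >= 16) {
    stop("'peak_energy' must lie in (10, 16) MeV")
  }
  d_ratio2 <- (ratio_energy - peak_energy)^2
  d_anchor2 <- (anchor_energy - peak_energy)^2
  w2 <- (d_ratio2 - d_anchor2) / (2 * log(ratio))
  if (!is.finite(w2) || w2 <= 0) {
    stop("no Gaussian satisfies the anchors for peak_energy = ", peak_energy)
  }
  peak_sigma <- anchor_sigma_mb * exp(d_anchor2 / (2 * w2))
  sig <- peak_sigma * exp(-(grid - peak_energy)^2 / (2 * w2))
  xs <- cross_section_table("Te-124(p,n)I-124", product, grid, sig,
                            source = "synthetic")
  xs$peak_energy_MeV <- peak_energy
  xs$peak_sigma_mb <- peak_sigma
  xs$width_MeV <- sqrt(w2)
  xs
}

#' Random decay inventory
#'
#' Samples a synthetic activity inventory with half-lives and activities
#' drawn log-uniformly over the given ranges, emulating the structure of an
#' end-of-bombardment inventory: half-lives spanning seconds to months and
#' activities spanning several orders of magnitude. Fully reproducible for a
#' fixed seed; the global RNG state is left untouched.
#'
#' @param n_nuclides number of nuclides, >= 1.
#' @param half_life_range_h positive increasing range of half-lives (h).
#' @param activity_range_MBq positive increasing range of activities (MBq).
#' @param seed mandatory RNG seed.
#' @return an [activity_inventory()] with symbols `SYN-1 ... SYN-n`.
#' @export
random_inventory <- function(n_nuclides,
                             half_life_range_h = c(0.01, 2000),
                             activity_range_MBq = c(0.1, 5000),
                             seed) {
  if (!is.numeric(n_nuclides) || n_nuclides < 1) stop("'n_nuclides' must be >= 1")
  check_range <- function(r, what) {
    if (length(r) != 2L || any(r <= 0) || r[2] <= r[1]) {
      stop("'", what, "' must be a positive increasing range")
    }
  }
  check_range(half_life_range_h, "half_life_range_h")
  check_range(activity_range_MBq, "activity_range_MBq")
  draws <- with_local_seed(seed, {
    list(hl = exp(stats::runif(n_nuclides, log(half_life_range_h[1]),
                               log(half_life_range_h[2]))),
         act = exp(stats::runif(n_nuclides, log(activity_range_MBq[1]),
                                log(activity_range_MBq[2]))))
  })
  nucs <- lapply(seq_len(n_nuclides), function(i) {
    nuclide(paste0("SYN-", i), draws$hl[i], "h")
  })
  activity_inventory(nucs, draws$act)
}

# fixture registry: name -> loader
fixture_registry <- function() {
  inv_loader <- function(csv) {
    force(csv)
    function() {
      df <- read_fixture_csv(csv)
      nucs <- lapply(seq_len(nrow(df)), function(i) {
        nuclide(df$symbol[i], df$half_life[i], df$unit[i], df$decay_modes[i])
      })
      inv <- activity_inventory(nucs, df$eob_MBq)
      attr(inv, "table") <- df
      inv
    }
  }
  list(
    inventory_enriched_10uA = inv_loader("inventory_enriched_10uA.csv"),
    inventory_enriched_15uA = inv_loader("inventory_enriched_15uA.csv"),
    inventory_natural_10uA  = inv_loader("inventory_natural_10uA.csv"),
    inventory_natural_15uA  = inv_loader("inventory_natural_15uA.csv"),
    eos_runs           = function() read_fixture_csv("eos_runs.csv"),
    release_plan       = function() read_fixture_csv("release_plan.csv"),
    foil_properties    = function() read_fixture_csv("foil_properties.csv"),
    target_masses      = function() read_fixture_csv("target_masses.csv"),
    te_abundances      = function() read_fixture_csv("te_abundances.csv"),
    product_waste_runs = function() read_fixture_csv("product_waste_runs.csv"),
    teo2       = function() material_teo2(),
    havar      = function() material_havar(),
    aluminum   = function() material_aluminum(),
    molybdenum = function() material_molybdenum(),
    toy_xs     = function() calibrated_toy_xs()
  )
}

read_fixture_csv <- function(name) {
  path <- system.file("extdata", name, package = "cycloyield", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' List the bundled reference datasets
#'
#' @return character vector of fixture names accepted by [load_fixture()].
#' @export
list_fixtures <- function() names(fixture_registry())

#' Load a bundled reference dataset
#'
#' The package ships, as plain-text tables, the reference datasets of a
#' I-124 production campaign on an 18 MeV medical cyclotron (natural and
#' Te-124-enriched TeO2 + Al2O3 targets, 0.2 mm Havar degrader, 1.5 h
#' irradiations at 10 and 15 uA):
#'
#' * `inventory_enriched_10uA`, `inventory_enriched_15uA`,
#'   `inventory_natural_10uA`, `inventory_natural_15uA`: simulated
#'   end-of-bombardment inventories ([activity_inventory()] at the EOB
#'   activities; the full table, including the published 72 h decay columns
#'   and per-table half-lives, is attached as attribute `"table"`).
#'   A few published 72 h cells are internally inconsistent with decay
#'   arithmetic (cross-table contradictions); these are marked in the
#'   `anomaly` column. The I-130 half-life is recorded as 12.36 h, the
#'   value consistent with the published decay columns (the table header
#'   rounds it to 12.4 h).
#' * `eos_runs`: per-run end-of-separation activities, measured and
#'   simulated, with EOB-to-EOS delays and the published relative
#'   differences.
#' * `release_plan`: published release times and activities at the 0.35%
#'   I-123 purity threshold (`consistent` flags the rows whose printed
#'   values agree with decay arithmetic).
#' * `product_waste_runs`: per-run product/waste separation activities.
#' * `foil_properties`, `target_masses`, `te_abundances`: degrader-foil
#'   characteristics, target thickness-to-mass table, natural Te isotopic
#'   abundances.
#' * `teo2`, `havar`, `aluminum`, `molybdenum`: the bundled [material()]s.
#' * `toy_xs`: the default [calibrated_toy_xs()].
#'
#' @param name fixture name; see [list_fixtures()].
#' @return an [activity_inventory()], data.frame, [material()] or
#'   [cross_section_table()] depending on the fixture.
#' @examples
#' load_fixture("target_masses")
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]()
}
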