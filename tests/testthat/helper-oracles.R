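# Independent oracles used by the tests. These deliberately re-derive the
# physics from scratch (different parameterization, own element constants,
# fixed-step integration) so that agreement with the package is a real check
# and not a tautology.

# element constants used only by the oracles
.ORACLE_EL <- data.frame(
  sym = c("Al", "O", "Te", "Co", "Cr", "Fe", "Ni", "W", "Mo", "Mn"),
  Z   = c(13, 8, 52, 27, 24, 26, 28, 74, 42, 25),
  M   = c(26.982, 15.999, 127.60, 58.933, 51.996, 55.845, 58.693,
          183.84, 95.95, 54.938),
  I   = c(166, 95, 485, 297, 257, 286, 311, 727, 424, 272)
)

# mass stopping power via the K = 4 pi N_A r_e^2 m_e c^2 = 0.307075
# MeV mol^-1 cm^2 parameterization (vs the package's SI k0/e derivation)
oracle_stopping <- function(fracs, energy) {
  K <- 0.307075
  me <- 0.51099895
  Mp <- 938.272081
  i <- match(names(fracs), .ORACLE_EL$sym)
  stopifnot(!anyNA(i))
  zm <- .ORACLE_EL$Z[i] / .ORACLE_EL$M[i]
  za <- sum(fracs * zm)
  lnI <- sum(fracs * zm * log(.ORACLE_EL$I[i])) / za
  g <- 1 + energy / Mp
  b2 <- 1 - 1 / g^2
  K * za / b2 * (log(2 * me * 1e6 * b2 * g^2 / exp(lnI)) - b2)
}

# CSDA range by fixed 1 keV trapezoid of the inverse stopping power, in um
oracle_range_um <- function(fracs, rho, energy, cutoff = 0.25) {
  E <- seq(cutoff, energy, by = 0.001)
  if (E[length(E)] < energy) E <- c(E, energy)
  f <- 1 / oracle_stopping(fracs, E)
  h <- diff(E)
  sum(h * (f[-1] + f[-length(f)]) / 2) / rho * 1e4
}

# depth-slab activation oracle: 1 um slabs, midpoint energy stepping, sigma
# evaluated at the slab-entry energy
oracle_slab_activity_MBq <- function(xs, fracs, rho, thickness_mm,
                                     n_parent_per_g, energy_in,
                                     current_uA, time_h, lambda_per_h,
                                     cutoff = 0.25, dx_um = 1) {
  sigma_of <- function(E) {
    s <- approx(xs$energies_MeV, xs$sigma_mb, xout = E, yleft = 0, yright = 0)$y
    ifelse(is.na(s), 0, s)
  }
  dx_cm <- dx_um * 1e-4
  n_slabs <- ceiling(thickness_mm / 10 / dx_cm)
  E <- energy_in
  p <- 0
  for (i in seq_len(n_slabs)) {
    if (E <= cutoff) break
    p <- p + n_parent_per_g * rho * dx_cm * sigma_of(E) * 1e-27
    s1 <- oracle_stopping(fracs, E) * rho            # MeV/cm at entry
    Emid <- max(E - s1 * dx_cm / 2, cutoff)
    E <- E - oracle_stopping(fracs, Emid) * rho * dx_cm
  }
  rate <- current_uA * 1e-6 / 1.602176634e-19 * p    # reactions/s
  rate * (1 - exp(-lambda_per_h * time_h)) / 1e6
}

# purity release time by brute-force 0.01 h scan: first time the impurity
# fraction is at or below the threshold
oracle_purity_scan <- function(inv, impurity, threshold = 0.0035,
                               bracket = c(0.5, 1000), step = 0.01) {
  hl <- vapply(inv$nuclides, `[[`, 0, "half_life_h")
  a0 <- inv$activities_MBq
  ts <- seq(bracket[1], bracket[2], by = step)
  amat <- outer(1 / hl, ts)              # t / T per nuclide x time
  act <- a0 * 2^(-amat)
  frac <- act[impurity, ] / colSums(act)
  i <- which(frac <= threshold)[1]
  if (is.na(i)) return(NA_real_)
  ts[i]
}

# shared toy materials (mass fractions only; oracles add their own physics)
TEO2_FR  <- c(Te = 127.60 / 159.598, O = 31.998 / 159.598)
HAVAR_FR <- c(Co = 0.425, Cr = 0.200, Fe = 0.179, Ni = 0.130,
              W = 0.028, Mo = 0.022, Mn = 0.016)
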