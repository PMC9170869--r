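---
title: "Modelling solid-target radionuclide production: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling solid-target radionuclide production: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloyield)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical machinery, and what the bundled
synthetic data can and cannot tell you about real production runs. The worked
case throughout is ¹²⁴I production from TeO₂ on an 18 MeV medical cyclotron,
but every component is generic over materials, channels and nuclides.

## 1. Stopping power and range

### Model

Protons slowing down in matter lose energy at the Bethe rate

$$-\frac{dE}{dx} = \frac{4\pi n k_0^2 z^2 e^4}{m_ec^2\beta^2}
\left[\ln\frac{2m_ec^2\beta^2}{I(1-\beta^2)}-\beta^2\right],$$

with $\beta^2$ computed relativistically from the proton kinetic energy and
the material entering through its electron density $n$ and mean excitation
energy $I$. We evaluate the formula directly from the SI constants
($k_0$, $e$, $m_ec^2$), and the tests cross-check against the independent
$4\pi N_A r_e^2 m_ec^2 = 0.307075$ MeV·mol⁻¹·cm² parameterization.

Two deliberate simplifications:

* **No shell correction.** It matters mostly below ~1 MeV, which sits below
  the low-energy cutoff (next section) and contributes micrometres of range.
* **No density-effect correction.** Negligible for protons below 30 MeV.

These omissions are the dominant model error and are the reason the CSDA
range is only claimed to a few per cent (the package reproduces the
transport-code reference value of 813 μm for 14.8 MeV protons in TeO₂ glass
at −3.8 %, comfortably inside the ±7 % band the reference comparison allows).

Compound media use Bragg additivity: electron densities add as
$n_g=\sum_i w_iN_AZ_i/M_i$ and $\ln I$ is the electron-fraction-weighted mean
of the elemental $\ln I_i$, with elemental $I$ values from the ICRU
recommendations bundled in `element_table()`. Mass fractions must sum to 1
within 10⁻⁶; the constructor refuses to renormalize silently because a
mistyped composition should fail loudly, not be papered over.

### Numerical settings

`stopping_model()` exposes three knobs:

* `low_energy_cutoff` (MeV, default **0.25**, floor 0.1): the Bethe
  logarithm turns unphysical at very low energies, so the range integral is
  truncated there and the sub-cutoff residual set to zero. At 0.25 MeV the
  discarded residual is below ~2 μm in TeO₂ — far below the model error.
* `energy_grid_step` (MeV, default **0.01**): step of the precomputed
  energy↔range table.
* `energy_max` (MeV, default **30**): upper end of the declared validity
  window. Energies outside the window raise errors; there is no silent
  extrapolation in either direction.

The range engine builds, once per material (cached), a cumulative-trapezoid
table of mass range versus energy on that grid and interpolates it with
monotone Hyman splines in both directions. Using one shared table for
$R(E)$ and its inverse makes slab composition self-consistent: degrading
through 0.1 mm twice equals degrading through 0.2 mm to well within the
10⁻³ MeV tolerance the tests assert, and quadrature agrees with a fixed-step
1 keV brute-force integrator to 0.1 %.

A beam absorbed inside a slab is a *tagged outcome* (`NA` with a `stopped`
attribute, tested via `is_stopped()`), not an exception — thickness sweeps
legitimately cross the stopping boundary, and a sweep should record the fact
rather than abort.

### Straggling

`simulate_range_distribution()` draws stopping depths as Gaussian deviates
about the CSDA range with the Bohr-straggling standard deviation
$\sigma_R^2=\int_0^{E_0}\kappa\,(dE/d(\rho x))^{-3}dE$,
$\kappa=4\pi r_e^2(m_ec^2)^2 n_g$. This is an explicit, documented
approximation to condensed-history transport: it reproduces the location and
rough width of the stopping peak (σ ≈ 11.5 μm in TeO₂ at 14.8 MeV, against
~15 μm from full transport, which also includes multiple-scattering path
wandering) and is used only for qualitative comparison. The quantitative
output is always the CSDA range. Seeds are mandatory arguments, and the
sampler restores the global RNG state.

## 2. Thick-target activation

The end-of-bombardment activity of one channel is

$$A_\mathrm{EOB}=\frac{I_\mathrm{beam}}{e}\,(1-e^{-\lambda t_\mathrm{irr}})\,
\frac{N_Awf_a}{M}\int_{E_\mathrm{out}}^{E_\mathrm{in}}
\frac{\sigma(E)}{dE/d(\rho x)}\,dE,$$

with the energy window from the range-inversion degradation of the beam
across the target. Assumptions, all standard for production planning at
these energies:

* each (p,xn) channel is computed independently from its own σ table —
  no secondary-neutron reactions, no beam-intensity attenuation;
* σ(E) is interpolated **linearly** between grid points and is **zero
  outside the grid**. Conservative and reproducible; a window clipped by
  the grid is flagged in the result (`clipped`), and an empty window
  returns a zero-yield result with a warning rather than an error.

The integral runs on a ~2000-point trapezoid grid refined with the σ-table
nodes, using the same stopping engine as the range integral. Correctness is
pinned by three independent routes in the tests: the thin-target closed form
$A=(I/e)(1-e^{-\lambda t})\,n_\mathrm{areal}\,\sigma$ (≤ 0.1 %), a 1 μm
depth-slab brute-force oracle (≤ 0.5 % over randomized cases), and exact
algebraic properties (linearity in current, linearity in parent abundance,
saturation in irradiation time).

The abundance linearity is also the enriched-versus-natural story: EOB
activity scales exactly with the parent isotopic abundance, so a 99.5 %
enriched target outproduces the 4.74 % natural one by exactly the abundance
ratio (~21×) *per channel* — the package asserts the exact scaling and makes
no claim about the impurity spectrum, which changes with the target's other
isotopes. Where an enriched target is needed in examples we take 99.5 %
abundance, a typical commercial enrichment; it is an argument, not a
constant.

### The degrader-foil optimum

With an excitation function peaked near 13 MeV, where the beam should land
depends on the target thickness. A *thin* target (≲ 0.3 mm) samples a narrow
energy window, so the yield is maximized by centring that window on the
peak: from 18 MeV that takes 0.2–0.3 mm of Havar, which the sweep test
verifies with a 0.3 mm target. A *0.5 mm* target already spans ~7 MeV of
window; its optimum shifts to thinner foils (~0.1–0.15 mm) because the wide
window wants its upper edge well above the peak. The package checks the
0.2–0.3 mm optimum in the thin-target regime where it is the physically
correct statement.

## 3. Decay inventories and release planning

Inventories decay entry-wise, $A_i(t)=A_i(0)\,2^{-t/T_{1/2,i}}$, with no
Bateman ingrowth. This is a modelling decision, not an oversight: the
bundled reference inventories are themselves exactly entry-wise exponential
(their published 72 h columns confirm it numerically), and the
parent→daughter feeds present in this system (e.g. ¹²⁹Te→¹²⁹I) involve
activities orders of magnitude below the release-relevant species.

`purity_time()` solves the Ph. Eur. release-time problem: the first time at
which a named impurity falls to a threshold (default 0.35 %) **of the total
remaining activity** — all species in the denominator, matching how
pharmacopoeial radionuclidic purity is defined. Numerics: a 1024-point scan
over the bracket (default 0.5–1000 h) locates the first *downward* crossing;
bisection refines it to |fraction − threshold| ≤ 10⁻⁶. The scan-then-bisect
split exists because a general inventory can cross the threshold more than
once (a long-lived impurity can grow back in relative terms); the
first-crossing rule plus a 0.01 h brute-force scan oracle in the tests guard
that case. Degenerate inputs get explicit outcomes rather than errors: an
inventory already at or below threshold returns an `already_pure` result at
the bracket start, and a trajectory that never crosses returns a
`no_crossing` result carrying the fraction range seen.

The experiment-versus-simulation comparison statistic is
$|A_\mathrm{sim}-A_\mathrm{exp}|/A_\mathrm{exp}\cdot100$, the convention the
bundled end-of-separation table uses on every row.

### Half-life bookkeeping in the reference data

The package bundles two kinds of nuclide constants, and keeps them apart
deliberately:

* `default_nuclides()`: evaluated (NNDC-style) values — the library
  defaults for new work;
* per-table half-lives inside each reference-inventory fixture — used when
  reproducing that table, because reproduction should use the table's own
  constants.

The reference tables round half-lives inconsistently (¹²⁴I appears as both
4.18 d and 4.2 d; ¹³⁰I prints as 12.4 h while its decay columns are only
consistent with 12.36 h, which the fixture therefore records). Beyond
rounding, five printed 72 h cells and one percentage cell are arithmetically
inconsistent with *any* half-life — cross-table contradictions of the
copy-error kind (one value appears verbatim in three different rows). The
fixtures transcribe them as printed and mark them in an `anomaly` column;
the reproduction tests assert every other cell to 1.5 % and skip the marked
ones. Misreporting those cells as reproducible would require fitting
nonphysical half-lives, which we refuse to do.

## 4. What the synthetic data does and does not emulate

`calibrated_toy_xs()` is a Gaussian excitation function whose width and peak
height are *solved*, not fitted, from two anchors: σ(14 MeV) = 300 mb and
σ(14)/σ(18) = 3, with the peak near 13 MeV. That gives the right scale, peak
position and high-energy fall-off for the ¹²⁴Te(p,n)¹²⁴I channel — enough to
exercise every downstream computation and to make qualitative statements
(e.g. the degrader-optimum placement). It is **not** the evaluated excitation
function: the real (p,n) shape is asymmetric with a threshold near 4 MeV,
and absolute yields computed from the toy curve are illustrations. For
quantitative yield prediction, supply an evaluated table (TENDL/IAEA-style)
through `read_xs_csv()`; every operation applies unchanged. Consequently,
passing tests demonstrate the correctness of the *machinery* (integration,
windows, saturation, normalization) and of the decay/purity bookkeeping
against the published campaign — they do not validate evaluated nuclear
data, which the package treats as input.

`random_inventory()` samples half-lives and activities log-uniformly
(defaults: 0.01–2000 h and 0.1–5000 MBq, the spans the reference EOB
inventories cover). It emulates the *structure* of an EOB inventory — many
decades of half-life and activity — not the correlations of a real one
(short-lived species tending to dominate EOB activity). It exists to make
property tests (semigroup, ordering, solver-versus-oracle) run over a wide,
reproducible family of cases.

Problem sizes used by the shipped tests are chosen for coverage at
interactive runtimes: 10⁵ protons for straggling histograms, 20 randomized
cases against each brute-force oracle, 100 randomized cases for the
activation property suite.

## 5. Known limitations

* Stopping physics: no shell/density corrections (few-per-cent range
  accuracy), no lateral scattering, no nuclear attenuation of the beam.
  CSDA path length is reported as depth.
* Activation: no target heating, blackening or material-loss effects; the
  chemical-separation efficiency (>75 % in the reference campaign) is not
  modelled — apply it as a scalar on reported activities if needed.
* Inventories: no ingrowth; back-extrapolation before the reference time is
  refused by design.
* The toy excitation function is calibrated, not evaluated (above).

## 6. Interfaces

All pipeline stages are plain functions; `run_plan()` chains them
(degrade → window → yield → decay → purity) from a flat configuration list
that mirrors the function arguments, resolves every file/fixture reference
before running any stage, echoes the configuration (with seed) into the
report, and serializes to JSON with `write_report()`. Reports carry units in
every field name and contain no timestamps, so identical configurations
produce byte-identical reports. On-disk formats are plain text: CSV for
nuclide tables, inventories and σ tables (with a JSON metadata sidecar), and
JSON for materials, configurations and reports.
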