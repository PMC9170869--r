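# cycloyield

Physics of medical-cyclotron radionuclide production on solid targets, built
around the ¹²⁴I-from-TeO₂ route used on small 18 MeV machines. The package is
for radiopharmacy physicists and production planners who want to answer, with
a few lines of R, questions like: *what energy does the beam have after the
degrader foil? how deep do the protons go in the target glass? how much
activity does a given foil/target/current/time combination produce? and when
does the decayed product meet the Ph. Eur. radionuclidic-purity limit for
release?*

## What it computes

**Stopping and range.** Proton mass stopping power from the Bethe formula

$$-\frac{dE}{dx} \;=\; \frac{4\pi n k_0^2 z^2 e^4}{m_ec^2\,\beta^2}
\left[\ln\frac{2m_ec^2\beta^2}{I\,(1-\beta^2)} - \beta^2\right],$$

with the electron density $n = \sum_i w_i N_A Z_i/M_i$ and the mean
excitation energy $I$ of compounds from Bragg additivity on $\ln I$. The CSDA
range is the quadrature of the inverse stopping power,
$R(E_0)=\int_0^{E_0}(dE/dx)^{-1}dE$, and degrader foils are handled by range
inversion, $E_\mathrm{out} = R^{-1}\!\left(R(E_\mathrm{in})-\rho t\right)$.
No shell or density-effect corrections are applied; the model is declared for
1–30 MeV protons.

**Activation.** Thick-target end-of-bombardment activity of a channel with
excitation function $\sigma(E)$ over the in-target energy window
$[E_\mathrm{out}, E_\mathrm{in}]$, with the saturation factor:

$$A_\mathrm{EOB} = \frac{I_\mathrm{beam}}{e}\,
\left(1-e^{-\lambda t_\mathrm{irr}}\right)\frac{N_A\,w\,f_a}{M}
\int_{E_\mathrm{out}}^{E_\mathrm{in}} \frac{\sigma(E)}{dE/d(\rho x)}\,dE ,$$

normalized to MBq/μAh, plus grid sweeps over foil and target thicknesses.

**Inventories and purity.** Multi-nuclide activity inventories decay
entry-wise ($A_i(t)=A_i(0)\,2^{-t/T_{1/2,i}}$, no ingrowth), with totals,
per-nuclide fractions, and a bisection solver for the first time at which an
impurity (Ph. Eur.: ¹²³I ≤ 0.35 % of total activity) drops to its release
threshold.

**Synthetic inputs and reference data.** A calibrated single-peak toy
excitation function (σ(14 MeV) = 300 mb, σ(14)/σ(18) = 3, peak near 13 MeV),
randomized decay inventories for property testing, and the bundled reference
datasets of a natural/enriched TeO₂ production campaign (EOB inventories,
end-of-separation runs, release plan, foil and target tables) available via
`load_fixture()`.

## Worked example

An 18 MeV, 15 μA, 1.5 h irradiation through 0.2 mm Havar onto 0.5 mm of
natural TeO₂, followed by decay and release planning on the bundled
15 μA reference inventory:

```r
library(cycloyield)
rep <- run_plan(list(
  beam   = list(energy_MeV = 18, current_uA = 15, time_h = 1.5),
  foil   = list(material = "havar", thickness_mm = 0.2),
  target = list(material = "teo2", thickness_mm = 0.5, parent_abundance = 0.0474),
  xs     = "fixture:toy_xs",
  inventory    = "inventory_natural_15uA",
  decay_times_h = 72,
  purity = list(impurity = "I-123"),
  seed   = 1))
rep
#> <production run report  cycloyield 0.2.0 >
#>   degrader: Havar 0.2 mm, 18 -> 14.71 MeV
#>   target window: 14.71 -> 8.012 MeV
#>   yield [Te-124(p,n)I-124]: EOB 12.37 MBq, 0.5498 MBq/uAh
#>   inventory at 72 h: total 50.24 MBq
#>   purity: I-123 at 0.35% of total at 121.61 h (I-124 15.42 MBq)
```

Reading the report: the Havar foil degrades the nominal 18 MeV beam to
14.7 MeV; across the 0.5 mm target the beam slows from 14.7 to 8.0 MeV (the
window the yield integral runs over); the *toy* excitation function gives an
EOB activity of 12.4 MBq (0.55 MBq/μAh — a shape-calibrated illustration, not
an evaluated-data prediction; supply a measured σ(E) table via `read_xs_csv()`
for quantitative yields); the bundled 15 μA inventory decays to 50.2 MBq
total after 72 h; and the ¹²³I impurity falls to 0.35 % of the total activity
121.6 h after EOB, at which point 15.4 MBq of ¹²⁴I remain — matching the
reference campaign's published release point (122 h, 15.3 MBq).

Individual stages are ordinary functions:

```r
csda_range(material_teo2(), 14.8)                      # 781.96 um
energy_after_slab(material_havar(), 0.2, 18)           # 14.707 MeV
yield_per_uAh(35.594, 15, 1.5)                         # 1.582 MBq/uAh
simulate_range_distribution(material_teo2(), 14.8, 1e5, seed = 1)
#> <range distribution  mode 781.7 um  mean 781.9 um  sd 11.5 um  (CSDA 782.0 um, ...)>
```

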