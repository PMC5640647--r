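# magcyto

Flow-cytometry (FCM) analysis toolkit for the physiology of the
magnetotactic bacterium *Magnetospirillum gryphiswaldense* MSR-1 — and, more
broadly, for any single-laser bacterial cytometry workflow built on the same
stains. It is aimed at bioprocess and microbial-physiology researchers who
need fast, growth-independent readouts of culture state: MSR-1 takes 7–10
days to form colonies, and plate counts miss viable-but-non-culturable
cells, so cytometric snapshots are the practical way to monitor magnetosome
production cultures.

The package implements, as tested and composable functions:

* **Viability** by BOX/PI quadrant gating. BOX (DiBAC₄(3), FL1) enters only
  membrane-depolarised cells; propidium iodide (PI, FL3) only
  membrane-compromised ones. Events split into healthy (BOX⁻PI⁻), injured
  (BOX⁺PI⁻), dead (BOX⁺PI⁺) and anomalous (BOX⁻PI⁺); cuts are placed at the
  99.5th nearest-rank percentile of a dye-negative control.
* **Relative PHA content** from pyrromethene-546 fluorescence, with 1- vs
  2-subpopulation detection by a seeded EM Gaussian-mixture fit on log₁₀
  intensities, selected by BIC.
* **Relative chelatable iron** from phen green SK (PG-SK), whose signal is
  quenched by Fe²⁺/Fe³⁺ via a Stern–Volmer model
  `F = f0 / (1 + K_sv·[Fe])`; the iron index inverts it against an
  iron-free reference.
* **Cell concentration** from OD₅₆₅ through packaged or fitted
  through-origin calibrations (`1 OD₅₆₅ = 1.16×10⁹ cells·mL⁻¹` for unstained
  FCM events), and volumetric counting from flow rate × duration × dilution.
* **Morphology** summaries of forward/side scatter (mean, CV, heterogeneity
  index) separating homogeneous liquid-grown from polydisperse plate-grown
  populations.
* **Cellular magnetic response** `C_mag = OD₅₆₅(parallel) /
  OD₅₆₅(perpendicular)` from magneto-spectrophotometric OD pairs; values
  above 1 indicate magnetic cells.
* A **synthetic cytometer** (log-normal subpopulations, staining-saturation
  kinetics, iron quenching, paired OD readings, dilution series) plus a
  packaged scenario registry, so the whole battery runs and is testable at
  desk scale without instrument data. FCS 3.0/3.1 and an annotated CSV
  dialect are supported for event I/O.

See `vignettes/magcyto-methods.Rmd` for the models, parameter defaults and
design decisions.

## Worked example

```r
library(magcyto)

# thresholds from a dye-negative control, then gate a growing culture
control <- generate_scenario(load_scenario("unstained_control", 25000, seed = 1))
thr <- estimate_thresholds(control, percentile = 99.5,
                           control_id = "unstained_control")
thr
#> <quadrant_thresholds> FL1 (BOX) > 43.27, FL3 (PI) > 43.45  [p99.5 of unstained_control, n=25000]

growing <- generate_scenario(load_scenario("growing_magnetic", 25000, seed = 11))
classify_viability(growing, thr)
#> <viability_fractions> n = 25000 events
#>   healthy    86.90%
#>   injured     6.88%
#>   dead        3.82%
#>   anomalous   2.39%

# two discrete PHA populations in a starved magnetic culture
pha <- generate_scenario(load_scenario("magnetic_pha", 25000, seed = 17))
fit_subpopulations(pha, "FL1_A")
#> <mixture_fit> FL1_A, k = 2 (BIC k1: 70850.4, k2: 24153.8), n = 25000
#>   component 1: weight 0.395, mean 1.499 log10, sd 0.200
#>   component 2: weight 0.605, mean 3.499 log10, sd 0.201

# OD to cells/mL via the packaged calibration
od_to_concentration(0.8, load_calibration("fcm_unstained"))
#> # A tibble: 1 × 3
#>   od565 concentration mode
#>   <dbl>         <dbl> <chr>
#> 1   0.8     928000000 FCM

# C_mag from triplicate paired OD readings of a strongly magnetic culture
od <- generate_od_pairs(od_base = 0.4, magnetic_fraction = 1,
                        alignment_contrast = 1, noise_cv = 0.01, n = 3, seed = 5)
compute_cmag(od)
#> # A tibble: 3 × 5
#>   sample_id od_parallel od_perpendicular  cmag magnetic
#>   <chr>           <dbl>            <dbl> <dbl> <chr>
#> 1 pair_01         0.794            0.397  2.00 magnetic
#> 2 pair_02         0.825            0.406  2.03 magnetic
#> 3 pair_03         0.785            0.395  1.99 magnetic
```

Reading them: the gated culture is ~87% healthy with small injured/dead
fractions — the signature of an actively growing culture; the mixture fit
recovers the two PHA subpopulations (≈40/60 at log₁₀ means 1.5/3.5) and BIC
strongly prefers two components; an OD₅₆₅ of 0.8 corresponds to
9.3×10⁸ cells·mL⁻¹; and C_mag ≈ 2 is a strongly magnetic culture.

`run_condition()` / `run_condition_set()` compose everything per condition
into JSON-serialisable reports and a long comparison table
(`compare_conditions()`), e.g. the packaged headspace (O₂-availability) and
medium-shift series. `plot_quadrants()`, `plot_scatter()`,
`autoplot()` and `plot_comparison()` give the standard figures. A thin CLI
over the same functions is at `inst/cli/magcyto.R`
(`simulate`, `gate`, `quantify`, `cmag`, `run`, `compare` subcommands).

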