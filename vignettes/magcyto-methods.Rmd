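---
title: "Methods: cytometric physiology analysis for magnetotactic bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytometric physiology analysis for magnetotactic bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcyto)
```

## What the package measures

`magcyto` implements a battery of flow-cytometry (FCM) analyses for the
physiology of *Magnetospirillum gryphiswaldense* MSR-1 and similar
magnetotactic bacteria, designed for bioprocess monitoring where plate counts
are too slow (MSR-1 colonies take 7–10 days) and miss viable-but-non-culturable
(VBNC) cells. The battery covers:

* **Viability** by BOX/PI quadrant gating. BOX (DiBAC₄(3)) is an anionic
  lipophilic dye that only enters membrane-depolarised cells (green, FL1);
  propidium iodide (PI) is excluded by intact membranes (red, FL3). Quadrants:
  healthy (BOX⁻PI⁻), injured (BOX⁺PI⁻), dead (BOX⁺PI⁺), anomalous (BOX⁻PI⁺).
* **Relative PHA content** from pyrromethene-546 (Pyr-546) fluorescence, a
  lipophilic green stain for intracellular polyhydroxyalkanoate granules,
  including detection of discrete low/high-PHA subpopulations.
* **Relative chelatable iron** from phen green SK (PG-SK), whose fluorescence
  is *quenched* by Fe²⁺/Fe³⁺ — low signal means high free iron.
* **Cell concentration** by the proportionality between OD₅₆₅ and volumetric
  FCM event counts, plus direct volumetric counting from flow rate, duration
  and dilution.
* **Morphology** from forward/side scatter summaries (liquid-grown cells are
  small and homogeneous; plate-grown cells polydisperse and filamentous).
* **Cellular magnetic response** `C_mag`: the ratio of OD₅₆₅ with cells
  magnetically aligned parallel versus perpendicular to the light beam.
  Magnetic cells realign between the two Helmholtz-coil orientations and
  change the suspension's optical density; `C_mag > 1` indicates magnetic
  cells, `C_mag = 1` non-magnetic ones.

All intensities are stored on the linear instrument scale; decade (log₁₀)
transforms are applied only at gating, fitting and display time through
`log_display()`, which floors values at 1 a.u. so the transform stays
defined at zero. The assumed channel layout (single 488 nm laser plus a
640 nm laser for Syto62) is in `reference_channels()`.

## Quadrant gating

The instrument literature rarely states how quadrant cuts are placed, so the
package makes the rule explicit and testable: each cut is the **99.5th
nearest-rank percentile** of a dye-negative control's FL1 and FL3 intensities
(`estimate_thresholds()`). Nearest-rank (the `⌈p/100·n⌉`-th order statistic)
is used instead of an interpolated quantile because it is exactly
reproducible against a brute-force oracle and never invents intensity values.
Consequences worth knowing:

* About 0.5% of genuinely dye-negative events per channel will land above the
  cut, so a population generated as 88% healthy reads back ≈ 87%. This bias
  is a property of percentile gating itself, not of the implementation.
* Boundary convention: an event exactly *on* a cut is **negative** (positivity
  is a strict inequality). The convention is arbitrary but must be fixed for
  exact tests.
* BOX⁻PI⁺ events are reported as `anomalous` and never folded into `dead`:
  the biology of PI-positive but polarised cells is unresolved, and folding
  them away would silently inflate death estimates.

The Syto62 noise gate (`noise_gate()`) precedes gating when configured: a
permeant far-red DNA stain separates cells from noise particles of similar
size, keeping events with `FL4_A` above a cut (or `FSC_A` in scatter mode).
The pipeline applies a pass-through scatter gate by default, since whether
published MFIs were computed on gated events is generally unstated.

## Fluorescence summaries and subpopulation detection

`summarize_fluorescence()` reports the **arithmetic mean on the linear
scale** as MFI — the instrument-software meaning of "mean fluorescence
intensity" — with dispersion as the coefficient of variation (sample sd /
mean). CV was chosen as the dispersion measure because a single channel's
"covariance" is not meaningful as an error bar; CV is the standard
scale-free cytometry dispersion.

`fit_subpopulations()` detects one versus two discrete populations (e.g.
low/high PHA content) by fitting univariate Gaussian mixtures on the
log-displayed intensities with expectation-maximisation: 10 seeded random
restarts, log-likelihood tolerance 10⁻⁶, component standard deviations
floored at 10⁻⁴ decades to avoid degenerate spikes, and model selection by
BIC between k = 1 (2 parameters) and k = 2 (5 parameters). Components are
returned ordered by mean. An explicit, seeded protocol was preferred over a
packaged mixture fitter so the restart and selection behaviour is fully
specified; an independent mixture implementation is used as a cross-check in
the test suite, and parameter recovery (weights ±0.03, means ±0.05 decades
at 25 000 events) is verified over 20 seeds with at most one failure
tolerated.

## Iron index

Quenching of PG-SK by chelatable iron is modelled as Stern–Volmer
(first-order collisional quenching): expected fluorescence
`F(c) = f0 / (1 + K_sv·c)` with `c` in µM. No functional form is established
for this probe in MSR-1, so the standard first-order model is the default
and both parameters are user-configurable (`quench_model()`, defaults
`f0 = 2000` a.u., `K_sv = 0.1` µM⁻¹). `iron_index()` inverts it: relative to
an iron-free reference culture, `fold_quench = MFI_ref / MFI_sample` and the
iron estimate is `(fold_quench − 1)/K_sv`. The estimate is *relative*
chemistry: it assumes equal staining efficiency in sample and reference, and
it is only as absolute as `K_sv` is.

## Staining kinetics

Dye uptake is modelled first-order: stained fraction `1 − exp(−k·t)`. The
default `k = 0.2 s⁻¹` is anchored to the observed behaviour of Pyr-546 at
0.5 µg·mL⁻¹ — near-complete staining within the 10–15 s it takes to add dye
and acquire, and no measurable increase between 70 and 300 s: with the
default, saturation is ≥ 95% at 15 s and the 70→300 s change is < 2%. The
rate is configurable per stain.

## Count calibrations

`fit_count_calibration()` fits `concentration = slope · OD₅₆₅` **through the
origin** by least squares, because the relation is used as a per-OD
equivalence; `r²` is computed about the mean concentration so it stays
comparable with ordinary regression practice. Three packaged constants ship
with provenance strings: 1 OD₅₆₅ = 1.16×10⁹ cells·mL⁻¹ (unstained FCM
events), 1.03×10⁹ cells·mL⁻¹ (Syto62-gated events) and 3.3×10⁸ CFU·mL⁻¹
(plate counts — lower because VBNC cells form no colonies). Packaged
constants carry `n_points = 0` to mark that they are adopted, not fitted
here. Volumetric counting (`events_to_concentration()`) uses
`n_events · dilution / (flow_rate·duration/60 · 10⁻³ mL)` and refuses
sentinel metadata rather than guessing an acquisition volume.

## C_mag

`cmag_ratio()` is the plain ratio `OD_parallel / OD_perpendicular`; it is
scale-invariant, equals 1 for non-magnetic suspensions, and ≈ 2 for strongly
magnetic ones. `classify_magnetic()` calls a culture magnetic when
`C_mag > 1 + tol` with default `tol = 0.05`: no noise floor is established
for this instrument class, and the default was set so that the weakly
magnetic reading 1.1 is still called magnetic while 2–3% instrument noise is
not. The tolerance is configurable and reported alongside the call.

## The synthetic cytometer

Because no instrument data ship with the package, every analysis is
exercised against a synthetic event generator whose structure matches the
assumptions above:

* **Log-normal channels.** Each subpopulation draws channel `c` as `10^x`,
  `x ~ N(mu_c, sigma_c)` in decades. Cytometric scatter and fluorescence
  distributions are canonically right-skewed, and two parameters per channel
  reproduce the familiar decade-scale clouds. Intensities are positive by
  construction.
* **One multinomial draw per scenario** allocates events to subpopulations,
  so realised composition is tight around the specified fractions even at
  fixture size (25 000 events), rather than per-event independent labels.
* **Stain models applied at generation time**: a simulated Pyr-546 stain
  multiplies the FL1 location of PHA-bearing populations by the saturation
  fraction; a simulated PG-SK stain sets FL1 from the quench model and each
  population's `iron_um`.
* **Determinism**: every generator takes an explicit integer seed and runs
  under a local RNG scope (`withr::with_seed`), leaving global RNG state
  untouched; identical `(spec, seed)` gives bit-identical events.

The packaged scenario registry (`list_scenarios()`,
`inst/extdata/scenarios.yaml`) encodes the reference conditions: actively
growing and starving cultures (magnetic and non-magnetic), the
ethanol-killed control (5% healthy), liquid- versus plate-grown scatter
phenotypes (plate: higher FSC location 2.4 vs 2.0 decades and spread 0.35 vs
0.15, with 17.5% PI⁺), one- versus two-population PHA stains (log₁₀ means
1.5/3.5, weights 0.4/0.6), an iron-free PG-SK reference and a Syto62
cells-plus-debris mixture. Where a condition is characterised by a printed
range (e.g. 86–90% healthy), the registry holds the midpoint. Dye-negative
locations sit at 1.0 decades and positives at 3.2 — more than two decades of
separation, like well-compensated single-stain data.

What the generator does **not** emulate: detector saturation and
digitisation, spillover between fluorescence channels, doublets and
coincidence at high event rates, autofluorescence drift, debris continua, or
any optics (no Mie scattering, no magnetosome crystal model). Tests passing
on synthetic data therefore validate the *analysis logic and its stated
statistical behaviour*, not robustness to instrument artefacts; real
acquisitions should still be inspected for gating pathologies.

The condition registry (`list_conditions()`) packages two comparison series
as generator parameterisations: a headspace series (20–80% headspace in
sealed tubes; biomass rises with O₂ while C_mag falls from 2.0 to ≈ 1, PHA
falls, and PG-SK is most quenched at 80%) and a medium-shift series
(O₂-limited culture shifted to aerobic iron-replete or iron-free medium;
iron-replete cultures burn PHA — a > 3-fold Pyr-546 drop by 24 h — while
iron-free cultures retain 65% of the pre-shift signal). Values not fixed by
the characterised trends (absolute ODs, intermediate C_mag values) were
chosen once as typical magnitudes for MSR-1 shake-tube cultures.

## Orchestration and reproducibility

`run_sample()` composes the battery for one condition (gate → thresholds →
viability → summaries → calibration → C_mag) from a config that names the
control and reference inputs; every stage failure is annotated with the
stage name, and empty inputs produce flagged reports, not crashes.
`run_condition()`/`run_condition_set()` expand packaged conditions into
fixture files and reports; `compare_conditions()` emits the long
`(condition, metric, value, dispersion)` table. Reports serialise to JSON
(`write_report()`, schema `magcyto-report/1`) and identical inputs produce
byte-identical reports. Replicates are treated as separate reports;
`generate_od_pairs()` defaults to triplicate OD readings summarised as
mean ± sd.

## File formats

FCS output is one fixed dialect — FCS 3.1, single dataset, little-endian
32-bit float data, `$PnE/0,0/` (linear) — while the reader also accepts
FCS 3.0, double or integer data segments and big-endian byte order, and
de-logs channels whose `$PnE` declares log amplification. The CSV dialect
keeps fixtures diffable: `#key=value` acquisition metadata lines before a
header row of channel names; the `true_label` column of synthetic data
round-trips verbatim in CSV and is dropped (with a warning) in FCS, which
has no per-event text field. Missing metadata is filled with documented
sentinels (`NA` duration; 35 µL·min⁻¹ medium flow rate) and flagged as
assumed — volumetric counting refuses flagged metadata.

## Problem sizes and test design

Fixture-scale checks run at 25 000 events per sample (the standard
acquisition depth used throughout), distributional checks at 10⁵ draws
within 3 binomial standard deviations, and the mixture-recovery property at
20 seeds; the whole suite completes in about a minute on a single core.
Tolerances follow the source of each expected value: closed forms to 10⁻¹²
relative, law-of-large-numbers checks at 3σ, and recovery checks at the
stated parameter bands.

## Known limitations

* Quadrant placement assumes a representative dye-negative control; drifting
  autofluorescence between control and sample shifts all fractions.
* The iron estimate inherits every Stern–Volmer assumption (purely
  collisional quenching, one fluorophore pool, known `K_sv`).
* Through-origin calibration is only valid in the OD range where optical
  density is linear in biomass; no saturation correction is applied.
* The mixture model is restricted to k ≤ 2 by design; more structured
  histograms should be modelled outside this package.
* The C_mag magnetic call tolerance is an operational default, not an
  instrument-derived noise floor.
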