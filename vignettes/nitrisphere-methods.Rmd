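---
title: "Methods: N2O source partitioning, tracer rates and DNA-SIP gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: N2O source partitioning, tracer rates and DNA-SIP gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrisphere)
library(dplyr)
```

`nitrisphere` implements the quantitative core of a biofilm-nitrification
study design: N₂O isotopocule source partitioning, ¹⁵N tracer rate
estimation, and DNA-SIP buoyant-density gradient analysis, together with a
synthetic-data generator that makes every stage testable end to end. This
vignette documents the models, the defaults and the reasoning behind the
numerical choices.

## N₂O isotopocules and site preference

N₂O is linear (N–N–O); the central (α) and terminal (β) nitrogen positions
acquire different ¹⁵N enrichment depending on the production pathway. All
isotopic quantities are handled in per-mil δ notation relative to
atmospheric ¹⁵N–N₂ (R = 0.0036765),

$$\delta^{15}\mathrm{N} = 1000\,\frac{R_{sample} - R_{standard}}{R_{standard}}\ (\text{‰}),$$

with `delta_from_ratios()`. Bulk δ¹⁵N is the mean of the two position
deltas and the site preference is their difference,
SP = δ¹⁵Nᵅ − δ¹⁵Nᵝ. Every isotopocule table built by the package stores
δᵅ, δᵝ, δ_bulk and SP and keeps them mutually consistent to 10⁻⁹ ‰. All
per-mil values are stored as plain numbers in ‰, never as fractional
deviations; the ×1000 factor is part of the δ definition here because all
downstream endmember values and precisions are quoted in ‰.

Two instrument-facing corrections are provided:

* **Scrambling correction** (`correct_scrambling()`). A fraction γ of NO⁺
  fragment ions carries the β rather than α nitrogen, so the measured
  m/z 31/30 ratio is $r_{31} = (1-\gamma) r^\alpha + \gamma r^\beta$.
  With the bulk constraint $r^\alpha + r^\beta = 2 r_{bulk}$ this 2×2
  linear system is solved exactly; the default γ = 0.085 is typical for
  the IRMS configuration the package targets. γ = 0.5 makes the positions
  indistinguishable and is rejected unless the molecule is symmetric
  (r31 = r_bulk). This is deliberately the two-fragment linear model
  without ¹⁷O/¹⁸O mass-overlap corrections: full vendor-specific
  corrections belong upstream of this package, and users with already
  corrected δᵅ/δᵝ can (and usually should) supply those directly.
* **Two-point SP calibration** (`two_point_calibrate()`). Two reference
  gases with certified δᵅ/δᵝ define an affine map from measured to true
  SP, exact at both standards. The calibration adjusts SP while
  preserving δ_bulk, recentering δᵅ/δᵝ about the unchanged bulk; this
  matches the practice of calibrating the site preference specifically,
  since SP is the downstream quantity and bulk calibration is a separate
  exercise.

## Two-endmember source partitioning

Under oxic incubation conditions (no heterotrophic denitrification),
nitrification-derived N₂O has two sources with distinct SP signatures:
NH₂OH oxidation (high SP) and nitrifier denitrification (low SP). The
linear mixing model

$$F_N = \frac{SP - SP_A}{SP_N - SP_A}, \qquad F_A = 1 - F_N$$

is applied at the endmember means; the defaults are the literature values
SP_A = 35.0 ‰ (range 32.0–38.7 ‰) and SP_N = −5.9 ‰ (range −13.6–1.9 ‰).
The hybrid AOA pathway overlaps these signatures and is not separated
isotopically; where an AOA/AOB attribution of the NH₂OH share is needed it
enters as an external multiplier (e.g. from inhibitor experiments), not
from this model.

```{r}
partition_sp(c(19.81, 26.68)) |> mutate(f_a_pct = 100 * f_a)
```

Observed SP values can fall outside the endmember interval through
measurement noise; the raw fraction is then clamped to [0, 1] and flagged
rather than rejected, because rejection would bias Monte Carlo means near
the endmembers. `f_a + f_n = 1` holds exactly, clamped or not.

### Monte Carlo uncertainty

`monte_carlo_partition()` draws, per sample and per draw, (i) both
endmembers from the configured distribution and (ii) the observed SP from
a normal with sd `sp_sd`, partitions with clamping and summarizes the F_N
draws (mean, sd, 2.5/50/97.5 percentiles). Defaults:

* **10 000 draws**, a size at which the Monte Carlo standard error of the
  mean is ≈ 0.0006 on the F_N scale and a run takes well under a second.
* **Uniform endmember sampling over the quoted ranges.** The ranges are
  the only published constraint; uniform is the least-informative
  distribution consistent with them. `point` (degenerate) and
  `triangular` (mode at the mean) are available alternatives. Note the
  uniform means (35.35 and −5.85 ‰) differ slightly from the quoted
  averages, a ≤ 0.01 shift in F_N that is well inside the propagated
  uncertainty.
* **sp_sd = 0.95 ‰**, the combined precision of the two position deltas
  under independence: √(0.9² + 0.3²), from the typical single-isotopocule
  IRMS precisions of 0.9 ‰ (δᵅ) and 0.3 ‰ (δᵝ).

One seeded generator drives each call; the seed is recorded in the result
and identical seeds give bit-identical summaries. With point endmembers
and zero noise the Monte Carlo mean equals the analytic value exactly,
which the test suite asserts, together with agreement of the 10⁴-draw mean
with a pre-computed 10⁶-draw brute-force oracle within three Monte Carlo
standard errors.

## ¹⁵N tracer rates

Ammonia oxidation is quantified as ¹⁵NO₂⁻ production from ¹⁵NH₄⁺, nitrite
oxidation as ¹⁵NO₃⁻ production from ¹⁵NO₂⁻. The estimator chain is:

1. `background_subtract()` — removes the pre-incubation pool (the wet-lab
   analogue is sulfamic-acid destruction of initial NO₂⁻); the t = 0 pool
   becomes exactly 0. Idempotent; negative corrected values are floored
   at 0 with a warning.
2. `tracer_slope()` — ordinary least squares of pool vs time with
   intercept. Incubation designs often stop at two endpoint times
   (4 h and 8 h, plus the baseline); OLS over all available points equals
   the finite difference for two points and uses all information
   otherwise, which is why it is preferred here over a two-point
   difference. A zero-variance response gets slope 0 and r² = 1 (a
   constant fits a constant perfectly); this is reported via a message,
   not an error.
3. `per_cell_rate()` — `slope × volume × 1e9 / cells` converts
   μmol L⁻¹ h⁻¹ in a `volume`-litre incubation (default 0.05 L, i.e.
   50 mL) into fmol N cell⁻¹ h⁻¹. Cells come from
   `cells_from_16s()` = 16S copies / 4.1, the average rRNA operon number
   per genome.

Pools are μmol L⁻¹ of ¹⁵N atoms; back-calculation from ²⁹N₂ IRMS readings
is assumed done upstream. Group contrasts use `compare_groups()` (one-way
ANOVA + Tukey HSD through `stats::aov()`/`TukeyHSD()`, with compact
letters derived from maximal cliques of the non-significance graph) and
`fold_change()`, which rounds half away from zero at one decimal to match
the reporting convention for "x-fold" statements.

## DNA-SIP gradient analysis

¹³C-assimilating populations shift their DNA towards heavier CsCl
buoyant densities. Profiles are 13 qPCR-quantified fractions per
sample/gene/isotope; `normalize_profile()` divides each fraction's copies
by the profile total (scale-invariant, idempotent, sums to 1).

`peak_density()` offers two peak statistics:

* `argmax` (default) — the density of the maximal fraction; matches the
  "high peak in density window X" way SIP results are described. Ties
  break to the lowest fraction index for reproducibility.
* `centroid` — abundance-weighted mean density of the top k = 3
  fractions; robust to multiplicative qPCR noise and the estimator used
  in the package's own recovery tests.

`density_shift()`/`sip_shift()` difference the heavy and light peak
densities; `classify_labeled()` calls a lineage labeled when the shift
reaches 0.015 g mL⁻¹. That threshold sits midway between the largest
shift reported for poorly fractionated populations (0.012 g mL⁻¹, AOA)
and the smallest clearly labeled shift (0.016 g mL⁻¹, AOB); it is
config-overridable, and the boundary case uses the ≥ convention.
`select_heavy_fractions()` extracts the fractions taken forward to
sequencing, by index (default 9–10) or by density window (e.g.
1.699–1.702 g mL⁻¹). Fraction indices are taken as supplied and profiles
are handled by density; no global index→density rule is assumed, since
fraction collectors differ in direction.

## Synthetic-data generator

The generators in `scenario_config()` et al. are first-class,
seed-reproducible forward models of the three designs:

* **SP observations** — SP = SP_A + F_N (SP_N − SP_A) + N(0, sp_sd), per
  group × replicate, with endmembers drawn per the endmember model and
  site deltas emitted about a configurable bulk (δ_bulk = 20 ‰).
* **Tracer series** — cells lognormal about the group mean
  (log-sd 0.5), slope = rate × cells/(volume × 10⁹), pools
  baseline + slope·t + N(0, 0.05 μmol L⁻¹) floored at 0, sampled at
  0/4/8 h; the matching 16S table (copies = cells × 4.1) is attached so
  the per-cell normalization can be exercised.
* **Gradients** — 13 fractions evenly spaced over 1.660–1.740 g mL⁻¹
  (containing the 1.710 loading density), copies ∝ a Gaussian on the
  density axis (σ = 0.006 g mL⁻¹) at 1.683 (¹²C) or 1.683 + shift (¹³C),
  times lognormal noise (log-sd 0.2). The span and σ were chosen so the
  light (1.680–1.686) and heavy (1.699–1.702) windows are resolvable on a
  13-fraction grid.
* **qPCR abundances** — lognormal about per-gene geometric means; the
  AOB default (3.4 × 10⁴ copies) sits mid-way inside the observed
  0.16 × 10⁴–0.72 × 10⁶ copies L⁻¹ interval.

Defaults mirror the study conditions the package is built around:
4 incubation replicates per group (5 biofilm/seawater groups), 3 SIP
replicates, and group truth values inside the reported ranges (biofilm
F_N 0.53–0.70, seawater ≈ 0.30; plastisphere rates within
1.79–3.59 fmol cell⁻¹ h⁻¹; AOB shifts ≈ 0.017 g mL⁻¹). Noise magnitudes
are instrument-anchored where possible (SP 0.95 ‰; tracer 0.05 μmol L⁻¹,
half the 0.1 μM IRMS detection limit) and order-of-magnitude choices
elsewhere (qPCR log-sd 0.5), all exposed in the config. Additive normal
noise is used for isotopic and tracer measurements and multiplicative
lognormal noise for copy numbers, matching the respective error
structures.

What the generator does **not** emulate: temporal saturation of tracer
pools (production is strictly linear), spatial O₂ microgradients within
biofilms, compositional qPCR biases, gradient asymmetry or GC-content
effects on buoyant density. Passing recovery tests therefore demonstrate
estimator correctness under the stated statistical model, not robustness
to every feature of real measurements.

## Numerical conventions and edge cases

* Validation failures raise classed conditions
  (`nitrisphere_validation_error` etc.); the CLI maps them to exit
  code 2, other errors to 1.
* Degenerate inputs: equal endmembers, γ = 0.5 with an asymmetric
  molecule, identical calibration standards, zero-copy gradients and
  zero cells are errors; empty heavy-fraction selections and missing
  t = 0 baselines are warnings/messages with defined fallbacks.
* Monte Carlo percentiles use the default quantile definition (type 7);
  summaries are pure functions of (data, config, seed).
* Problem sizes in the shipped tests — 10⁴ Monte Carlo draws against a
  frozen 10⁶-draw oracle, 200-replicate recovery studies for rates and
  gradient shifts — were chosen so the full suite completes in well
  under a minute while keeping Monte Carlo error far below the asserted
  tolerances.

## Limitations

* The two-endmember model cannot separate AOA from AOB contributions
  within the NH₂OH pathway, nor include hybrid or heterotrophic sources;
  it presumes the incubation excluded them.
* The scrambling correction is the simplified two-fragment model; raw-ion
  inputs measured on instruments needing ¹⁷O corrections should be
  corrected upstream.
* SIP labeling calls are threshold-based on the peak shift; they do not
  model atom-fraction excess (qSIP) and inherit the 13-fraction grid's
  resolution (≈ 0.007 g mL⁻¹ spacing).
* Rate estimation assumes linear production over the incubation; substrate
  depletion or lags violate this and would bias slopes downward.
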