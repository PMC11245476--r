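# nitrisphere

Quantitative analysis of nitrification and its N₂O footprint in estuarine
biofilms — including the plastisphere, the microbial biofilm on floating
plastic debris — and the surrounding seawater.

Estuarine surfaces (plastic, stone, wood, glass) host dense biofilms whose
nitrifiers can behave very differently from their planktonic counterparts.
Three measurement streams are commonly combined to characterize this:

1. **N₂O isotopocules.** The site preference
   SP = δ¹⁵Nᵅ − δ¹⁵Nᵝ of N₂O discriminates its microbial source. With two
   endmembers — hydroxylamine (NH₂OH) oxidation, SP_A = 35.0 ‰
   (range 32.0–38.7), and nitrifier denitrification, SP_N = −5.9 ‰
   (range −13.6–1.9) — the nitrifier-denitrification share of emitted N₂O
   is

   ```
   F_N = (SP − SP_A) / (SP_N − SP_A),   F_A = 1 − F_N
   ```

   `nitrisphere` computes SP from calibrated or raw (scrambling-corrected)
   isotopocule measurements, partitions each sample, and propagates
   endmember and measurement uncertainty by Monte Carlo (10 000 draws by
   default).
2. **¹⁵N tracer incubations.** Ammonia- and nitrite-oxidation rates are
   the least-squares slopes of ¹⁵NO₂⁻/¹⁵NO₃⁻ pool production over 0/4/8 h,
   converted to per-cell rates (fmol N cell⁻¹ h⁻¹) using cell numbers
   estimated as 16S rRNA gene copies / 4.1.
3. **DNA-SIP gradients.** ¹³C-labelled, actively growing populations shift
   their DNA to heavier CsCl buoyant densities. The package normalizes
   13-fraction qPCR profiles, locates peak densities (argmax or top-k
   centroid), quantifies the ¹²C→¹³C shift and calls labeling
   (default threshold 0.015 g mL⁻¹).

A seed-reproducible synthetic-data generator emulates all three designs
(grouped incubations with n = 4 replicates, SIP with n = 3), so the whole
pipeline can be exercised and validated without any external data.

All user-facing functions are data-frame-first and return tibbles; fitted
results have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Partition the two seawater site-mean SP values through the mixing model
and propagate uncertainty:

```r
library(nitrisphere)
library(dplyr)

seawater <- tibble::tibble(
  sample_id = c("sw1", "sw2"), group = "seawater",
  delta_alpha_permil = 20 + c(19.81, 26.68) / 2,
  delta_beta_permil  = 20 - c(19.81, 26.68) / 2
) |> as_isotopocule_table()

partition_n2o(seawater) |> mutate(f_a_pct = 100 * f_a) |> pull(f_a_pct)
#> [1] 62.86064 79.65770

mc <- monte_carlo_partition(seawater, n_draws = 10000, seed = 42)
tidy(mc) |> select(sample_id, f_n_mean, f_n_sd, f_n_q025, f_n_q975)
#> # A tibble: 2 × 5
#>   sample_id f_n_mean f_n_sd f_n_q025 f_n_q975
#>   <chr>        <dbl>  <dbl>    <dbl>    <dbl>
#> 1 sw1          0.380 0.0564    0.278    0.493
#> 2 sw2          0.212 0.0507    0.120    0.313
```

So 62.9 % and 79.7 % of nitrification-derived N₂O in these seawater
samples is attributed to NH₂OH oxidation; the Monte Carlo sd of the
complementary nitrifier-denitrification fraction is about 5–6 percentage
points once the endmember ranges and the 0.95 ‰ SP measurement precision
are propagated.

Per-cell rates and fold changes follow the same tibble-first style:

```r
per_cell_rate(slope = 0.5, volume = 0.05, cells = cells_from_16s(4.1e7))
#> [1] 2.5          # fmol N / cell / h
fold_change(3.5, 2.2)
#> [1] 1.6          # plastisphere vs seawater per-cell N2O emission
```

End-to-end runs go through `run_all()` (or the thin CLI in
`inst/exec/nitrisphere`) from four CSV schemas — `isotopocules.csv`,
`tracer.csv`, `qpcr.csv`, `gradient.csv` — to CSV tables plus a JSON
report; `write_simulated_scenario()` generates a complete synthetic input
set.

## Documentation

The methods vignette (`vignettes/nitrisphere-methods.Rmd`) describes the
mixing model and its assumptions, the rate and SIP estimators, the noise
models behind the synthetic-data generator, and the package's numerical
conventions and limitations.
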