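# Small in-code fixtures shared across test files.

# 13-fraction gradient profile with a discretized Gaussian peak
make_profile <- function(peak, isotope = "12C", gene = "AOB_amoA",
                         sample_id = "s1", sigma = 0.006,
                         densities = seq(1.660, 1.740, length.out = 13),
                         noise = NULL) {
  copies <- 1e5 * stats::dnorm(densities, peak, sigma)
  if (!is.null(noise)) copies <- copies * noise
  tibble::tibble(
    sample_id = sample_id, gene = gene, isotope = isotope,
    fraction_index = seq_along(densities),
    density_g_per_mL = densities, copies = copies
  )
}

# spike profile: all copies in the fraction whose density is nearest `at`
make_spike_profile <- function(at, ...) {
  p <- make_profile(1.7, ...)
  p$copies <- ifelse(
    abs(p$density_g_per_mL - at) == min(abs(p$density_g_per_mL - at)), 100, 0
  )
  p
}

# exact-linear tracer series
make_series <- function(slope, baseline = 0, times = c(0, 4, 8),
                        sample_id = "s1", group = "g", analyte = "nitrite_15N") {
  tibble::tibble(
    sample_id = sample_id, group = group, analyte = analyte,
    time_h = times, pool_umol_per_L = baseline + slope * times
  )
}

make_iso_table <- function(sp, bulk = 20, group = "seawater") {
  ab <- site_deltas_from_bulk_sp(bulk, sp)
  tibble::tibble(
    sample_id = paste0("s", seq_along(sp)), group = group,
    delta_alpha_permil = ab$delta_alpha, delta_beta_permil = ab$delta_beta
  ) |> as_isotopocule_table()
}
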