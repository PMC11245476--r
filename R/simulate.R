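# Seed-reproducible synthetic data with the statistical structure the
# analysis assumes: grouped incubations (SP observations via the forward
# mixing model), linear 15N-pool production, 13-fraction CsCl gradients and
# qPCR gene abundances.

#' Default group truth table for the synthetic scenario
#'
#' One row per incubation compartment with the "true" parameters the
#' generators embed: the nitrifier-denitrification fraction of N2O
#' (`true_f_n`), per-cell ammonia- and nitrite-oxidation rates (fmol N
#' cell^-1 h^-1), the 12C -> 13C buoyant-density shift (g mL^-1) and mean
#' cell numbers. Values are anchored to the measured ranges of the study
#' system: biofilm f_n 0.53-0.70 vs seawater ~0.3, plastisphere rates
#' within 1.79-3.59 fmol cell^-1 h^-1, AOB density shifts 0.016-0.022.
#'
#' @return A tibble with columns `label`, `true_f_n`, `true_rate_nh3`,
#'   `true_rate_no2`, `true_shift`, `mean_cells`.
#' @export
default_scenario_groups <- function() {
  tibble(
    label = c("plastisphere", "stone", "wood", "glass", "seawater"),
    true_f_n = c(0.65, 0.60, 0.55, 0.53, 0.30),
    true_rate_nh3 = c(2.7, 2.5, 0.8, 0.6, 1.2),
    true_rate_no2 = c(2.6, 2.0, 0.7, 0.5, 1.0),
    true_shift = c(0.017, 0.016, 0.014, 0.013, 0.017),
    mean_cells = c(1e7, 2e7, 8e6, 5e6, 6e6)
  )
}

#' Configure a synthetic experiment scenario
#'
#' Bundles the group truth table, replication, noise levels and incubation
#' design shared by all generators. Defaults emulate the grouped lab
#' incubations (4 replicates, sampling at 0/4/8 h, 50 mL liquid volume,
#' SP measurement sd 0.95 per mil) and the SIP design (3 replicates,
#' 13 fractions spanning 1.660-1.740 g mL^-1, Gaussian peak sd 0.006).
#'
#' @param groups Truth table as in [default_scenario_groups()].
#' @param replicates Incubation replicates per group (default 4).
#' @param sip_replicates SIP replicates per group (default 3).
#' @param sp_sd SP measurement noise, per mil (default 0.95).
#' @param tracer_sd Additive noise on 15N pools, umol L^-1 (default 0.05).
#' @param qpcr_log_sd Lognormal sd of qPCR copies / cell numbers on the
#'   log scale (default 0.5).
#' @param gradient_log_sd Lognormal sd of per-fraction gradient copies
#'   (default 0.2).
#' @param times Sampling times in hours (default 0, 4, 8).
#' @param volume Incubation volume in L (default 0.05).
#' @param delta_bulk Bulk delta15N about which synthetic site deltas are
#'   centered, per mil (default 20).
#' @param baseline Pre-incubation pool background, umol L^-1 (default 0.2).
#' @param density_range 13-fraction gradient density span, g mL^-1.
#' @param light_peak 12C peak density, g mL^-1 (default 1.683).
#' @param peak_sd Gaussian peak sd on the density axis, g mL^-1.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(groups = default_scenario_groups(),
                            replicates = 4, sip_replicates = 3,
                            sp_sd = 0.95, tracer_sd = 0.05,
                            qpcr_log_sd = 0.5, gradient_log_sd = 0.2,
                            times = c(0, 4, 8), volume = 0.05,
                            delta_bulk = 20, baseline = 0.2,
                            density_range = c(1.660, 1.740),
                            light_peak = 1.683, peak_sd = 0.006,
                            seed = NULL) {
  check_columns(
    groups,
    c("label", "true_f_n", "true_rate_nh3", "true_rate_no2", "true_shift",
      "mean_cells"),
    "scenario group table"
  )
  if (replicates < 1 || sip_replicates < 1) {
    validation_error("replicates must be at least 1")
  }
  if (any(c(sp_sd, tracer_sd, qpcr_log_sd, gradient_log_sd) < 0)) {
    validation_error("noise sds must be non-negative")
  }
  if (any(groups$true_f_n < 0 | groups$true_f_n > 1)) {
    validation_error("true_f_n must lie in [0, 1]")
  }
  if (length(times) < 2 || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    validation_error("times must be >= 2 non-negative strictly increasing hours")
  }
  structure(
    list(
      groups = as_tibble(groups), replicates = as.integer(replicates),
      sip_replicates = as.integer(sip_replicates), sp_sd = sp_sd,
      tracer_sd = tracer_sd, qpcr_log_sd = qpcr_log_sd,
      gradient_log_sd = gradient_log_sd, times = times, volume = volume,
      delta_bulk = delta_bulk, baseline = baseline,
      density_range = density_range, light_peak = light_peak,
      peak_sd = peak_sd, seed = seed
    ),
    class = "scenario_config"
  )
}

#' Simulate SP observations via the forward mixing model
#'
#' Per replicate, endmembers are drawn from the endmember model's
#' distribution, the observed SP is set to
#' `SP_A + true_f_n * (SP_N - SP_A)` plus normal measurement noise, and
#' position-specific deltas are emitted about the configured bulk delta.
#' With point endmembers and zero noise, [partition_n2o()] on the output
#' recovers `true_f_n` exactly.
#'
#' @param config A [scenario_config()].
#' @param endmembers An [endmember_model()].
#' @return An isotopocule table (see [as_isotopocule_table()]).
#' @export
simulate_sp_observations <- function(config,
                                     endmembers = endmember_model()) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    grid <- tidyr::expand_grid(
      group = config$groups$label,
      replicate = seq_len(config$replicates)
    ) %>%
      left_join(
        config$groups %>% select(group = "label", "true_f_n"),
        by = "group"
      )
    em <- .draw_endmembers(nrow(grid), endmembers)
    sp <- em$sp_a + grid$true_f_n * (em$sp_n - em$sp_a) +
      rnorm(nrow(grid), 0, config$sp_sd)
    ab <- site_deltas_from_bulk_sp(config$delta_bulk, sp)
    tibble(
      sample_id = sprintf("%s_r%d", grid$group, grid$replicate),
      group = grid$group,
      delta_alpha_permil = ab$delta_alpha,
      delta_beta_permil = ab$delta_beta
    ) %>%
      as_isotopocule_table()
  })
}

#' Simulate 15N tracer time series
#'
#' Per replicate and analyte, cell numbers are drawn lognormally around
#' the group mean, the volumetric slope implied by the true per-cell rate
#' is obtained by inverting [per_cell_rate()]
#' (`slope = rate * cells / (volume * 1e9)`), and pools follow
#' `baseline + slope * t` plus additive noise, floored at 0. The matching
#' 16S qPCR table (copies = cells x 4.1) is attached as attribute
#' `"qpcr"` so the per-cell normalization can be exercised end-to-end.
#'
#' @param config A [scenario_config()].
#' @param operon_factor 16S operons per cell used to emit the companion
#'   qPCR table (default 4.1).
#' @return A tracer table (`sample_id`, `group`, `analyte`, `time_h`,
#'   `pool_umol_per_L`, `volume_L`) with a `"qpcr"` attribute.
#' @export
simulate_tracer_series <- function(config, operon_factor = 4.1) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    samples <- tidyr::expand_grid(
      group = config$groups$label,
      replicate = seq_len(config$replicates)
    ) %>%
      left_join(
        config$groups %>%
          select(group = "label", "true_rate_nh3", "true_rate_no2",
            "mean_cells"),
        by = "group"
      ) %>%
      mutate(
        sample_id = sprintf("%s_r%d", .data$group, .data$replicate),
        cells = rlnorm(dplyr::n(), log(.data$mean_cells), config$qpcr_log_sd)
      )
    tracer <- samples %>%
      tidyr::pivot_longer(
        c("true_rate_nh3", "true_rate_no2"),
        names_to = "analyte", values_to = "rate"
      ) %>%
      mutate(analyte = ifelse(
        .data$analyte == "true_rate_nh3", "nitrite_15N", "nitrate_15N"
      )) %>%
      tidyr::expand_grid(time_h = config$times) %>%
      mutate(
        slope = .data$rate * .data$cells / (config$volume * 1e9),
        pool_umol_per_L = pmax(
          config$baseline + .data$slope * .data$time_h +
            rnorm(dplyr::n(), 0, config$tracer_sd),
          0
        ),
        volume_L = config$volume
      ) %>%
      select("sample_id", "group", "analyte", "time_h", "pool_umol_per_L",
        "volume_L")
    qpcr <- samples %>%
      mutate(gene = "16S", copies = .data$cells * operon_factor) %>%
      select("sample_id", "group", "gene", "copies")
    attr(tracer, "qpcr") <- qpcr
    tracer
  })
}

#' Simulate 13-fraction CsCl gradient profiles
#'
#' Densities are evenly spaced over the configured span (containing the
#' 1.710 g mL^-1 loading density). Per SIP replicate and isotope, copies
#' follow a discretized Gaussian on the density axis centered at the light
#' peak (12C) or at `light_peak + true_shift` (13C), times multiplicative
#' lognormal qPCR noise.
#'
#' @param config A [scenario_config()].
#' @param gene Target gene label (default "AOB_amoA").
#' @param total_copies Total copies per profile before noise.
#' @return A gradient table (see [read_gradient()]).
#' @export
simulate_gradient <- function(config, gene = "AOB_amoA",
                              total_copies = 1e6) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    densities <- seq(config$density_range[1], config$density_range[2],
      length.out = 13
    )
    grid <- tidyr::expand_grid(
      group = config$groups$label,
      replicate = seq_len(config$sip_replicates),
      isotope = c("12C", "13C")
    ) %>%
      left_join(
        config$groups %>% select(group = "label", "true_shift"),
        by = "group"
      ) %>%
      mutate(peak = config$light_peak +
        ifelse(.data$isotope == "13C", .data$true_shift, 0))
    grid %>%
      tidyr::expand_grid(
        tibble(fraction_index = 1:13, density_g_per_mL = densities)
      ) %>%
      mutate(
        shape = stats::dnorm(
          .data$density_g_per_mL, .data$peak, config$peak_sd
        ),
        copies = total_copies * .data$shape /
          sum(stats::dnorm(densities, config$light_peak, config$peak_sd)) *
          rlnorm(dplyr::n(), 0, config$gradient_log_sd),
        sample_id = sprintf("%s_sip%d", .data$group, .data$replicate),
        gene = gene
      ) %>%
      select("sample_id", "group", "gene", "isotope", "fraction_index",
        "density_g_per_mL", "copies")
  })
}

#' Simulate qPCR gene abundances
#'
#' Lognormal copies per gene and group around configured geometric means;
#' the AOB default (geometric mean 3.4e4 copies, log-sd from the config)
#' sits mid-way inside the observed abundance interval
#' 0.16e4 - 0.72e6 copies L^-1.
#'
#' @param config A [scenario_config()].
#' @param gene_means Named numeric vector of geometric-mean copies per
#'   gene; `16S` defaults to `mean_cells x 4.1` per group.
#' @return A qPCR table: `sample_id`, `group`, `gene`, `copies`.
#' @export
simulate_qpcr_abundance <- function(config,
                                    gene_means = c(
                                      AOB_amoA = 3.4e4,
                                      AOA_amoA = 1.5e3,
                                      COM_amoA = 5e2
                                    )) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    grid <- tidyr::expand_grid(
      group = config$groups$label,
      replicate = seq_len(config$replicates),
      gene = c("16S", names(gene_means))
    ) %>%
      left_join(
        config$groups %>% select(group = "label", "mean_cells"),
        by = "group"
      ) %>%
      mutate(
        gmean = ifelse(
          .data$gene == "16S", .data$mean_cells * 4.1,
          unname(gene_means[.data$gene])
        ),
        copies = rlnorm(dplyr::n(), log(.data$gmean), config$qpcr_log_sd),
        sample_id = sprintf("%s_r%d", .data$group, .data$replicate)
      ) %>%
      select("sample_id", "group", "gene", "copies")
    grid
  })
}
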