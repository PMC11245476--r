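# Pipeline layer: run every stage from CSV inputs under a single run
# config, writing CSV tables and a machine-readable JSON report.

#' Build a run configuration
#'
#' Collects input paths and stage settings for the pipeline runners. Any
#' field can be overridden; unknown fields are rejected. Configs can also
#' be read from a YAML file with [read_run_config()].
#'
#' @param isotopocules,tracer,qpcr,gradient Paths to the stage input CSVs
#'   (any may be `NULL` when that stage is not run; `qpcr` is optional for
#'   the rates stage).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in every output and used for the
#'   Monte Carlo stage.
#' @param ... Stage settings overriding the defaults: `sp_a_mean`,
#'   `sp_a_lo`, `sp_a_hi`, `sp_n_mean`, `sp_n_lo`, `sp_n_hi`,
#'   `endmember_dist`, `n_draws`, `sp_sd`, `operon_factor`, `volume`,
#'   `reference_group`, `sip_method`, `sip_k`, `sip_threshold`, `raw_ions`,
#'   `gamma`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(isotopocules = NULL, tracer = NULL, qpcr = NULL,
                       gradient = NULL, out_dir = ".", seed = 1, ...) {
  defaults <- list(
    sp_a_mean = 35.0, sp_a_lo = 32.0, sp_a_hi = 38.7,
    sp_n_mean = -5.9, sp_n_lo = -13.6, sp_n_hi = 1.9,
    endmember_dist = "uniform", n_draws = 10000, sp_sd = 0.95,
    operon_factor = 4.1, volume = 0.05, reference_group = "seawater",
    sip_method = "argmax", sip_k = 3, sip_threshold = 0.015,
    raw_ions = FALSE, gamma = 0.085
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown) > 0) {
    validation_error("unknown run_config field(s): %s",
      paste(unknown, collapse = ", ")
    )
  }
  structure(
    c(
      list(
        isotopocules = isotopocules, tracer = tracer, qpcr = qpcr,
        gradient = gradient, out_dir = out_dir, seed = seed
      ),
      modifyList(defaults, extra)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

.config_endmembers <- function(config) {
  endmember_model(
    sp_a_mean = config$sp_a_mean,
    sp_a_range = c(config$sp_a_lo, config$sp_a_hi),
    sp_n_mean = config$sp_n_mean,
    sp_n_range = c(config$sp_n_lo, config$sp_n_hi),
    distribution = config$endmember_dist
  )
}

.check_input <- function(path, stage) {
  if (is.null(path)) {
    validation_error("stage '%s' needs an input path in the run config", stage)
  }
  if (!file.exists(path)) {
    validation_error("input file for stage '%s' not found: %s", stage, path)
  }
  invisible(path)
}

.ensure_out <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  invisible(config$out_dir)
}

.write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Run the SP partitioning stage
#'
#' Reads the isotopocule table, derives SP, partitions each sample with
#' the endmember means, propagates uncertainty by Monte Carlo and writes
#' `partition.csv` plus `partition_summary.json` to the output directory.
#' Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with elements `records`, `partition`
#'   (per-sample table), `mc` (the `mc_partition` object) and `groups`
#'   (per-group percent summary).
#' @export
run_partition <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .check_input(config$isotopocules, "partition")
  .ensure_out(config)
  records <- read_isotopocules(config$isotopocules,
    raw = isTRUE(config$raw_ions), gamma = config$gamma
  )
  if (nrow(records) == 0) validation_error("isotopocule table is empty")
  em <- .config_endmembers(config)
  point <- partition_n2o(records, em)
  mc <- monte_carlo_partition(records,
    endmembers = em, n_draws = config$n_draws,
    seed = config$seed, sp_sd = config$sp_sd
  )
  out <- point %>%
    left_join(
      tidy(mc) %>%
        select("sample_id", "f_n_mean", "f_n_sd", "f_n_q025", "f_n_q50",
          "f_n_q975"),
      by = "sample_id"
    ) %>%
    select("sample_id", "group", "sp_permil", "f_a", "f_n", "clamped",
      "f_n_mean", "f_n_sd", "f_n_q025", "f_n_q50", "f_n_q975")
  groups <- group_partition_summary(point)
  readr::write_csv(out, file.path(config$out_dir, "partition.csv"))
  .write_stage_json(
    list(
      stage = "partition", seed = config$seed, n_draws = config$n_draws,
      sp_sd = config$sp_sd,
      endmembers = unclass(em),
      groups = groups
    ),
    file.path(config$out_dir, "partition_summary.json")
  )
  invisible(list(records = records, partition = out, mc = mc, groups = groups))
}

#' Run the tracer-rate stage
#'
#' Estimates per-cell nitrification rates from the tracer table (and the
#' optional qPCR table), summarizes per group and computes fold changes of
#' each group mean over the reference group. Writes `rates.csv` and
#' `rates_summary.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `rates`, `groups` and `folds` tables.
#' @export
run_rates <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .check_input(config$tracer, "rates")
  .ensure_out(config)
  tracer <- readr::read_csv(config$tracer, show_col_types = FALSE)
  if (nrow(tracer) == 0) validation_error("tracer table is empty")
  qpcr <- if (!is.null(config$qpcr)) {
    # gene labels like "16S" must not be parsed as numbers
    readr::read_csv(.check_input(config$qpcr, "rates"),
      col_types = readr::cols(gene = readr::col_character()),
      show_col_types = FALSE
    )
  }
  rates <- estimate_rates(tracer, qpcr,
    operon_factor = config$operon_factor, volume = config$volume
  )
  value_col <- if (is.null(qpcr)) "slope_umol_per_L_h" else "rate_fmol_per_cell_h"
  groups <- rates %>%
    group_by(.data$group, .data$analyte) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data[[value_col]]),
      sd = stats::sd(.data[[value_col]]),
      .groups = "drop"
    )
  folds <- NULL
  if (config$reference_group %in% groups$group) {
    ref <- groups %>%
      filter(.data$group == config$reference_group) %>%
      select("analyte", ref_mean = "mean")
    folds <- groups %>%
      filter(.data$group != config$reference_group) %>%
      left_join(ref, by = "analyte") %>%
      mutate(
        fold_change = fold_change(.data$mean, .data$ref_mean, digits = NULL),
        fold_change_1dp = fold_change(.data$mean, .data$ref_mean, digits = 1)
      ) %>%
      select("group", "analyte", "fold_change", "fold_change_1dp")
  } else {
    inform(sprintf(
      "reference group '%s' absent; fold changes skipped", config$reference_group
    ))
  }
  readr::write_csv(rates, file.path(config$out_dir, "rates.csv"))
  .write_stage_json(
    list(
      stage = "rates", seed = config$seed, value = value_col,
      per_cell = !is.null(qpcr),
      groups = groups, fold_changes = folds
    ),
    file.path(config$out_dir, "rates_summary.json")
  )
  invisible(list(rates = rates, groups = groups, folds = folds))
}

#' Run the DNA-SIP gradient stage
#'
#' Normalizes gradient profiles, computes 12C -> 13C peak-density shifts
#' per sample/gene, calls labeling, and writes `sip.csv` and
#' `sip_summary.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `profiles` (normalized) and `shifts`.
#' @export
run_sip <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .check_input(config$gradient, "sip")
  .ensure_out(config)
  gradient <- read_gradient(config$gradient)
  if (nrow(gradient) == 0) validation_error("gradient table is empty")
  profiles <- normalize_profile(gradient)
  shifts <- sip_shift(profiles,
    method = config$sip_method, k = config$sip_k,
    threshold = config$sip_threshold
  )
  readr::write_csv(shifts, file.path(config$out_dir, "sip.csv"))
  gene_summary <- shifts %>%
    group_by(.data$gene) %>%
    summarise(
      n = dplyr::n(),
      shift_mean = mean(.data$shift),
      shift_min = min(.data$shift),
      shift_max = max(.data$shift),
      labeled_frac = mean(.data$labeled),
      .groups = "drop"
    )
  .write_stage_json(
    list(
      stage = "sip", seed = config$seed, method = config$sip_method,
      threshold = config$sip_threshold, genes = gene_summary
    ),
    file.path(config$out_dir, "sip_summary.json")
  )
  invisible(list(profiles = profiles, shifts = shifts))
}

#' Run all configured stages and write a combined report
#'
#' Runs the partition, rates and SIP stages for which the config names an
#' input, then writes `report.json` combining the stage summaries with
#' provenance (config hash, seed, package version). Identical config and
#' seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of stage results plus the `report` list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .ensure_out(config)
  results <- list()
  if (!is.null(config$isotopocules)) results$partition <- run_partition(config)
  if (!is.null(config$tracer)) results$rates <- run_rates(config)
  if (!is.null(config$gradient)) results$sip <- run_sip(config)
  if (length(results) == 0) {
    validation_error("run config names no stage inputs")
  }
  report <- list(
    provenance = list(
      package = "nitrisphere",
      version = as.character(utils::packageVersion("nitrisphere")),
      seed = config$seed,
      # hash the scientific settings, not the output location
      config_hash = rlang::hash(
        unclass(config)[setdiff(names(config), "out_dir")]
      )
    ),
    partition = if (!is.null(results$partition)) results$partition$groups,
    rates = if (!is.null(results$rates)) {
      list(groups = results$rates$groups, fold_changes = results$rates$folds)
    },
    sip = if (!is.null(results$sip)) results$sip$shifts
  )
  .write_stage_json(report, file.path(config$out_dir, "report.json"))
  results$report <- report
  invisible(results)
}

#' Write a full synthetic scenario to CSV files
#'
#' Generates the four stage input tables from a [scenario_config()] and
#' writes them (plus a YAML manifest recording the configuration and seed)
#' into a directory, ready for [run_all()].
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory.
#' @param endmembers Endmember model used for the SP generator.
#' @return Invisibly, the named list of written file paths.
#' @export
write_simulated_scenario <- function(config, out_dir,
                                     endmembers = endmember_model()) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  iso <- simulate_sp_observations(config, endmembers)
  tracer <- simulate_tracer_series(config)
  qpcr <- attr(tracer, "qpcr")
  gradient <- simulate_gradient(config)
  paths <- list(
    isotopocules = file.path(out_dir, "isotopocules.csv"),
    tracer = file.path(out_dir, "tracer.csv"),
    qpcr = file.path(out_dir, "qpcr.csv"),
    gradient = file.path(out_dir, "gradient.csv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  readr::write_csv(iso, paths$isotopocules)
  readr::write_csv(as_tibble(tracer), paths$tracer)
  readr::write_csv(qpcr, paths$qpcr)
  readr::write_csv(gradient, paths$gradient)
  manifest <- unclass(config)
  manifest$groups <- as.list(as.data.frame(config$groups))
  manifest$endmembers <- unclass(endmembers)
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}
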