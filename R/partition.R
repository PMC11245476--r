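# Two-endmember SP mixing model: partition nitrification-derived N2O
# between NH2OH oxidation (F_A, high-SP) and nitrifier denitrification
# (F_N, low-SP), with Monte Carlo uncertainty propagation.

#' Define the two-endmember SP mixing model
#'
#' The site preference of N\eqn{_2}O from hydroxylamine oxidation
#' (endmember A) is high (literature mean 35.0 per mil, range 32.0 to
#' 38.7), while nitrifier denitrification (endmember N) is low (mean
#' \eqn{-5.9}, range \eqn{-13.6} to 1.9). Under a two-source model the
#' nitrifier-denitrification fraction of an observed SP is
#' \eqn{F_N = (SP - SP_A)/(SP_N - SP_A)} and \eqn{F_A = 1 - F_N}.
#'
#' `distribution` controls how endmembers are drawn in the Monte Carlo
#' routine: `"uniform"` (default) over the ranges, `"point"` (means only),
#' or `"triangular"` over the ranges with mode at the mean.
#'
#' @param sp_a_mean,sp_a_range Mean and range (length-2) of the
#'   NH\eqn{_2}OH-oxidation endmember SP, per mil.
#' @param sp_n_mean,sp_n_range Mean and range of the
#'   nitrifier-denitrification endmember SP, per mil.
#' @param distribution Endmember sampling distribution.
#' @return An object of class `endmember_model`.
#' @examples
#' em <- endmember_model()
#' partition_sp(19.81, em)
#' @export
endmember_model <- function(sp_a_mean = 35.0, sp_a_range = c(32.0, 38.7),
                            sp_n_mean = -5.9, sp_n_range = c(-13.6, 1.9),
                            distribution = c("uniform", "point", "triangular")) {
  distribution <- match.arg(distribution)
  stopifnot(length(sp_a_range) == 2, length(sp_n_range) == 2)
  sp_a_range <- sort(sp_a_range)
  sp_n_range <- sort(sp_n_range)
  if (sp_a_mean < sp_a_range[1] || sp_a_mean > sp_a_range[2]) {
    validation_error("sp_a_mean must lie inside sp_a_range")
  }
  if (sp_n_mean < sp_n_range[1] || sp_n_mean > sp_n_range[2]) {
    validation_error("sp_n_mean must lie inside sp_n_range")
  }
  if (sp_n_mean >= sp_a_mean) {
    validation_error("the denitrification endmember mean must be below the NH2OH-oxidation mean")
  }
  structure(
    list(
      sp_a_mean = sp_a_mean, sp_a_range = sp_a_range,
      sp_n_mean = sp_n_mean, sp_n_range = sp_n_range,
      distribution = distribution
    ),
    class = "endmember_model"
  )
}

#' @export
print.endmember_model <- function(x, ...) {
  cat("Two-endmember SP mixing model\n")
  cat(sprintf(
    "  NH2OH oxidation (SP_A): %.1f permil [%.1f, %.1f]\n",
    x$sp_a_mean, x$sp_a_range[1], x$sp_a_range[2]
  ))
  cat(sprintf(
    "  nitrifier denitrification (SP_N): %.1f permil [%.1f, %.1f]\n",
    x$sp_n_mean, x$sp_n_range[1], x$sp_n_range[2]
  ))
  cat(sprintf("  Monte Carlo endmember distribution: %s\n", x$distribution))
  invisible(x)
}

#' Partition SP values between the two N2O pathways
#'
#' Applies the linear mixing model at the endmember means. Raw fractions
#' outside `[0, 1]` (an observed SP beyond an endmember) are clamped, with
#' the `clamped` flag set; `f_a + f_n = 1` always holds.
#'
#' @param sp Observed site preference value(s), per mil.
#' @param endmembers An [endmember_model()].
#' @return A tibble with columns `f_a`, `f_n`, `clamped`.
#' @export
partition_sp <- function(sp, endmembers = endmember_model()) {
  stopifnot(inherits(endmembers, "endmember_model"))
  .partition_raw(sp, endmembers$sp_a_mean, endmembers$sp_n_mean)
}

# mixing-model kernel shared by the point estimate and the Monte Carlo draws
.partition_raw <- function(sp, sp_a, sp_n) {
  if (any(abs(sp_a - sp_n) < 1e-12)) {
    abort("endmember SP values coincide; the mixing model is degenerate",
      class = "nitrisphere_degenerate_endmembers"
    )
  }
  f_n_raw <- (sp - sp_a) / (sp_n - sp_a)
  f_n <- pmin(pmax(f_n_raw, 0), 1)
  tibble(f_a = 1 - f_n, f_n = f_n, clamped = f_n_raw < 0 | f_n_raw > 1)
}

#' Partition an isotopocule table
#'
#' Data-frame-first wrapper around [partition_sp()]: appends `f_a`, `f_n`
#' and `clamped` columns computed from `sp_permil`.
#'
#' @param data Isotopocule table with an `sp_permil` column.
#' @param endmembers An [endmember_model()].
#' @return `data` with partition columns appended.
#' @export
partition_n2o <- function(data, endmembers = endmember_model()) {
  check_columns(data, "sp_permil", "isotopocule table")
  bind_cols(as_tibble(data), partition_sp(data$sp_permil, endmembers))
}

# one endmember draw per (sample, draw) cell
.draw_endmembers <- function(n, endmembers) {
  d <- endmembers$distribution
  draw1 <- function(mean, range) {
    switch(d,
      point = rep(mean, n),
      uniform = runif(n, range[1], range[2]),
      triangular = .rtriangular(n, range[1], range[2], mean)
    )
  }
  list(
    sp_a = draw1(endmembers$sp_a_mean, endmembers$sp_a_range),
    sp_n = draw1(endmembers$sp_n_mean, endmembers$sp_n_range)
  )
}

# triangular(lo, hi, mode) via inverse CDF
.rtriangular <- function(n, lo, hi, mode) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(
    u < fc,
    lo + sqrt(u * (hi - lo) * (mode - lo)),
    hi - sqrt((1 - u) * (hi - lo) * (hi - mode))
  )
}

#' Monte Carlo uncertainty propagation for the SP partition
#'
#' For each observed SP, draws `n_draws` realizations: endmembers from the
#' model's distribution (uniform over the literature ranges by default) and
#' the observation from a normal with the IRMS-derived measurement sd
#' (default 0.95 per mil, the combined precision of the two
#' position-specific deltas). Each draw is partitioned with clamping; the
#' resulting \eqn{F_N} draws are summarized per sample.
#'
#' @param data Isotopocule table with `sp_permil` (and ideally `sample_id`,
#'   `group`), or a bare numeric vector of SP values.
#' @param endmembers An [endmember_model()].
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   summaries.
#' @param sp_sd Measurement sd of the observed SP, per mil.
#' @return An object of class `mc_partition`; see [tidy.mc_partition()].
#' @examples
#' mc <- monte_carlo_partition(c(19.81, 26.68), seed = 1)
#' tidy(mc)
#' @export
monte_carlo_partition <- function(data, endmembers = endmember_model(),
                                  n_draws = 10000, seed = NULL,
                                  sp_sd = 0.95) {
  if (is.numeric(data)) {
    data <- tibble(
      sample_id = paste0("s", seq_along(data)),
      group = NA_character_, sp_permil = as.numeric(data)
    )
  }
  check_columns(data, "sp_permil", "isotopocule table")
  if (nrow(data) == 0) validation_error("no SP observations supplied")
  if (!is.numeric(n_draws) || n_draws < 1) {
    validation_error("n_draws must be at least 1")
  }
  if (sp_sd < 0) validation_error("sp_sd must be non-negative")
  n_draws <- as.integer(n_draws)
  if (!"sample_id" %in% names(data)) {
    data$sample_id <- paste0("s", seq_len(nrow(data)))
  }
  if (!"group" %in% names(data)) data$group <- NA_character_

  summary <- with_seed(seed, {
    purrr::pmap(
      list(data$sample_id, data$group, data$sp_permil),
      function(sid, grp, sp_obs) {
        em <- .draw_endmembers(n_draws, endmembers)
        sp <- rnorm(n_draws, sp_obs, sp_sd)
        part <- .partition_raw(sp, em$sp_a, em$sp_n)
        q <- quantile(part$f_n, c(0.025, 0.5, 0.975), names = FALSE)
        tibble(
          sample_id = sid, group = grp, sp_permil = sp_obs,
          f_n_mean = mean(part$f_n),
          f_n_sd = if (n_draws > 1) sd(part$f_n) else 0,
          f_n_q025 = q[1], f_n_q50 = q[2], f_n_q975 = q[3],
          f_a_mean = 1 - mean(part$f_n),
          f_a_sd = if (n_draws > 1) sd(part$f_n) else 0,
          clamped_frac = mean(part$clamped)
        )
      }
    ) %>% bind_rows()
  })

  structure(
    list(
      summary = summary, endmembers = endmembers,
      n_draws = n_draws, seed = seed, sp_sd = sp_sd
    ),
    class = "mc_partition"
  )
}

#' @export
print.mc_partition <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo SP partition: %d sample(s), %d draws, sp_sd = %g permil\n",
    nrow(x$summary), x$n_draws, x$sp_sd
  ))
  print(x$summary, ...)
  invisible(x)
}

#' Tidy a Monte Carlo partition
#'
#' @param x An `mc_partition` object.
#' @param ... Unused.
#' @return One row per sample: mean, sd and 2.5/50/97.5 percentiles of
#'   \eqn{F_N}, the complementary \eqn{F_A} summaries, and the fraction of
#'   clamped draws.
#' @export
tidy.mc_partition <- function(x, ...) {
  x$summary
}

#' @rdname tidy.mc_partition
#' @return For `glance()`: a one-row tibble with draw count, seed,
#'   measurement sd and endmember distribution.
#' @export
glance.mc_partition <- function(x, ...) {
  tibble(
    n_samples = nrow(x$summary),
    n_draws = x$n_draws,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed),
    sp_sd = x$sp_sd,
    endmember_dist = x$endmembers$distribution
  )
}

#' Per-group pathway contribution summary
#'
#' Summarizes partition fractions per compartment, in percent, the way
#' pathway contributions are reported (mean +/- sd per group). Accepts
#' either point-estimate tables (columns `f_a`, `f_n` from
#' [partition_n2o()]) or Monte Carlo summaries (columns `f_a_mean`,
#' `f_n_mean` from `tidy()` on [monte_carlo_partition()]).
#'
#' @param data Partition results carrying a `group` column.
#' @return A tibble with one row per group: `n`, `f_a_mean_pct`,
#'   `f_a_sd_pct`, `f_n_mean_pct`, `f_n_sd_pct`.
#' @export
group_partition_summary <- function(data) {
  check_columns(data, "group", "partition table")
  if (all(c("f_a", "f_n") %in% names(data))) {
    fa <- data$f_a
    fn <- data$f_n
  } else if (all(c("f_a_mean", "f_n_mean") %in% names(data))) {
    fa <- data$f_a_mean
    fn <- data$f_n_mean
  } else {
    validation_error("partition table needs f_a/f_n or f_a_mean/f_n_mean columns")
  }
  if (any(is.na(data$group))) {
    validation_error("every record must carry a group label")
  }
  tibble(group = data$group, f_a = fa, f_n = fn) %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      f_a_mean_pct = 100 * mean(.data$f_a),
      f_a_sd_pct = 100 * stats::sd(.data$f_a),
      f_n_mean_pct = 100 * mean(.data$f_n),
      f_n_sd_pct = 100 * stats::sd(.data$f_n),
      .groups = "drop"
    )
}
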