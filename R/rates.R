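# 15N tracer nitrification rates: ammonia oxidation as 15NO2- production,
# nitrite oxidation as 15NO3- production, normalized per microbial cell.

#' Microbial cell numbers from 16S rRNA gene copies
#'
#' Cell numbers are estimated by dividing the 16S rRNA gene copy number by
#' the average rRNA operon copy number per genome (4.1, from the Ribosomal
#' RNA Operon Copy Number Database).
#'
#' @param copies 16S rRNA gene copies.
#' @param operon_factor Average 16S operons per cell (default 4.1).
#' @return Estimated cell counts.
#' @export
cells_from_16s <- function(copies, operon_factor = 4.1) {
  if (any(operon_factor <= 0)) {
    validation_error("operon_factor must be strictly positive")
  }
  if (any(copies < 0)) validation_error("gene copies must be non-negative")
  copies / operon_factor
}

#' Subtract the pre-incubation background from a tracer series
#'
#' Mirrors the wet-lab background removal (sulfamic acid destroys the
#' initial nitrite pool before detection): per series, the pool at t = 0 is
#' subtracted from every time point, so the corrected series starts at
#' exactly zero. When no t = 0 point exists the earliest time point is used
#' as the baseline and a message is emitted. Corrected values that fall
#' below zero are floored at zero with a warning. The operation is
#' idempotent.
#'
#' @param data Tracer table with columns `sample_id`, `analyte`, `time_h`,
#'   `pool_umol_per_L` (one series per sample/analyte).
#' @return The corrected tracer table.
#' @export
background_subtract <- function(data) {
  check_columns(
    data, c("sample_id", "analyte", "time_h", "pool_umol_per_L"),
    "tracer table"
  )
  .validate_tracer(data)
  out <- data %>%
    as_tibble() %>%
    group_by(.data$sample_id, .data$analyte) %>%
    mutate(
      .baseline = .data$pool_umol_per_L[which.min(.data$time_h)],
      .t0_missing = min(.data$time_h) > 0,
      pool_umol_per_L = .data$pool_umol_per_L - .baseline
    ) %>%
    ungroup()
  if (any(out$.t0_missing)) {
    inform("no t = 0 point in some series; earliest time point used as baseline")
  }
  if (any(out$pool_umol_per_L < 0)) {
    warn("negative background-corrected pools floored at 0")
    out$pool_umol_per_L <- pmax(out$pool_umol_per_L, 0)
  }
  out %>% select(-".baseline", -".t0_missing")
}

.validate_tracer <- function(data) {
  if (any(data$time_h < 0)) validation_error("times must be non-negative")
  if (any(data$pool_umol_per_L < 0)) {
    validation_error("15N pools must be non-negative")
  }
  counts <- data %>%
    group_by(.data$sample_id, .data$analyte) %>%
    summarise(k = dplyr::n_distinct(.data$time_h), .groups = "drop")
  if (any(counts$k < 2)) {
    validation_error("each tracer series needs at least 2 distinct time points")
  }
  invisible(data)
}

#' Least-squares production slope of each tracer series
#'
#' Fits pool vs time by ordinary least squares (with intercept) per
#' series. With exactly two points the slope equals the finite difference.
#' A zero-variance response is reported with slope 0 and r-squared 1 (a
#' constant is a perfect fit of a constant); a message notes the case.
#'
#' @param data Tracer table (see [background_subtract()]); a `group`
#'   column, if present, is carried through.
#' @return One row per series: `sample_id`, (`group`,) `analyte`,
#'   `slope_umol_per_L_h`, `fit_r2`, `n_points`.
#' @export
tracer_slope <- function(data) {
  check_columns(
    data, c("sample_id", "analyte", "time_h", "pool_umol_per_L"),
    "tracer table"
  )
  .validate_tracer(data)
  keys <- intersect(c("sample_id", "group", "analyte"), names(data))
  fits <- data %>%
    as_tibble() %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      .fit = list(.slope_one(.data$time_h, .data$pool_umol_per_L)),
      .groups = "drop"
    ) %>%
    tidyr::unnest(".fit")
  if (any(fits$.zero_var)) {
    inform("zero-variance response in some series; r2 reported as 1")
  }
  fits %>% select(-".zero_var")
}

.slope_one <- function(t, y) {
  if (stats::var(y) < .Machine$double.eps) {
    return(tibble(
      slope_umol_per_L_h = 0, fit_r2 = 1, n_points = length(t),
      .zero_var = TRUE
    ))
  }
  fit <- lm(y ~ t)
  # summary.lm warns on exact-linear data; exact fits are expected here
  tibble(
    slope_umol_per_L_h = unname(coef(fit)[2]),
    fit_r2 = suppressWarnings(summary(fit)$r.squared),
    n_points = length(t),
    .zero_var = FALSE
  )
}

#' Per-cell nitrification rate
#'
#' Converts a volumetric production slope into a per-cell rate:
#' `slope (umol L^-1 h^-1) x volume (L) x 1e9 (fmol/umol) / cells`,
#' in fmol N cell\eqn{^{-1}} h\eqn{^{-1}}.
#'
#' @param slope Production slope, umol L\eqn{^{-1}} h\eqn{^{-1}}.
#' @param volume Incubation liquid volume in L (default 0.05, i.e. 50 mL).
#' @param cells Microbial cell number in the incubation.
#' @return Rate in fmol N cell\eqn{^{-1}} h\eqn{^{-1}}.
#' @examples
#' per_cell_rate(0.5, 0.05, 1e7) # 2.5 fmol N / cell / h
#' @export
per_cell_rate <- function(slope, volume = 0.05, cells) {
  if (any(cells <= 0)) {
    abort("cell count must be positive to express a per-cell rate",
      class = "nitrisphere_undefined_rate"
    )
  }
  if (any(volume <= 0)) validation_error("incubation volume must be positive")
  slope * volume * 1e9 / cells
}

#' Full per-cell rate pipeline on tracer + qPCR tables
#'
#' Background-subtracts each series, fits the production slope, converts
#' 16S rRNA copies to cells and reports per-cell rates. Without a qPCR
#' table the per-cell normalization is skipped and only volumetric slopes
#' are reported (a message notes the downgrade).
#'
#' @param tracer Tracer table: `sample_id`, `group`, `analyte`, `time_h`,
#'   `pool_umol_per_L`, optional `volume_L`.
#' @param qpcr Optional qPCR table: `sample_id`, `gene`, `copies`; rows
#'   with `gene == "16S"` supply the cell counts.
#' @param operon_factor 16S operons per cell (default 4.1).
#' @param volume Fallback incubation volume in L when the tracer table has
#'   no `volume_L` column.
#' @return One row per series with slope, fit r-squared, cells and
#'   `rate_fmol_per_cell_h` (NA when no qPCR table was given).
#' @export
estimate_rates <- function(tracer, qpcr = NULL, operon_factor = 4.1,
                           volume = 0.05) {
  slopes <- tracer %>%
    background_subtract() %>%
    tracer_slope()
  vol <- if ("volume_L" %in% names(tracer)) {
    tracer %>%
      group_by(.data$sample_id) %>%
      summarise(volume_L = .data$volume_L[1], .groups = "drop")
  } else {
    tibble(sample_id = unique(tracer$sample_id), volume_L = volume)
  }
  slopes <- left_join(slopes, vol, by = "sample_id")
  if (is.null(qpcr)) {
    inform("no qPCR table supplied; reporting volumetric slopes only")
    return(slopes %>% mutate(cells = NA_real_, rate_fmol_per_cell_h = NA_real_))
  }
  check_columns(qpcr, c("sample_id", "gene", "copies"), "qPCR table")
  cells <- qpcr %>%
    filter(.data$gene == "16S") %>%
    mutate(cells = cells_from_16s(.data$copies, operon_factor)) %>%
    select("sample_id", "cells")
  slopes %>%
    left_join(cells, by = "sample_id") %>%
    mutate(rate_fmol_per_cell_h = per_cell_rate(
      .data$slope_umol_per_L_h, .data$volume_L, .data$cells
    ))
}

#' Fold change between two group means
#'
#' @param numerator,denominator Group means (e.g. per-cell N\eqn{_2}O
#'   emission of the plastisphere vs seawater).
#' @param digits Decimal places for half-away-from-zero rounding
#'   (default 1, the convention of reported x-fold values); `NULL` leaves
#'   the ratio unrounded.
#' @return The (optionally rounded) ratio.
#' @examples
#' fold_change(3.5, 2.2) # 1.6
#' @export
fold_change <- function(numerator, denominator, digits = 1) {
  if (any(denominator == 0)) {
    validation_error("fold change undefined for zero denominator")
  }
  ratio <- numerator / denominator
  if (is.null(digits)) ratio else round_half_up(ratio, digits)
}

#' One-way ANOVA with Tukey HSD grouping letters
#'
#' Standard reporting companion for grouped incubation measurements:
#' one-way ANOVA across groups followed by Tukey's HSD; groups share a
#' letter iff their Tukey-adjusted p-value is at least `alpha`. Letters are
#' derived from the maximal cliques of the non-significance graph, ordered
#' by decreasing group mean.
#'
#' @param data A data frame with the response and a group column.
#' @param value,group Column names (strings) of response and grouping.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `group_comparison` with `tidy()`/`glance()`
#'   methods; `tidy()` gives per-group mean, sd, n and letters, `glance()`
#'   the ANOVA F and p.
#' @export
compare_groups <- function(data, value, group = "group", alpha = 0.05) {
  check_columns(data, c(value, group), "comparison table")
  df <- tibble(
    y = data[[value]],
    g = factor(data[[group]])
  )
  counts <- table(df$g)
  if (length(counts) < 2 || any(counts < 2)) {
    validation_error("need at least 2 groups with at least 2 replicates each")
  }
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  letters <- .tukey_letters(df, tk, alpha)
  structure(
    list(
      fit = fit,
      f_statistic = an[["F value"]][1],
      p_value = an[["Pr(>F)"]][1],
      tukey = as_tibble(tk, rownames = "contrast"),
      letters = letters,
      alpha = alpha,
      value = value, group = group
    ),
    class = "group_comparison"
  )
}

# compact letter display: maximal cliques of the graph whose edges join
# groups NOT significantly different under Tukey HSD
.tukey_letters <- function(df, tk, alpha) {
  lev <- levels(df$g)
  adj <- matrix(TRUE, length(lev), length(lev), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]
    b <- pairs[[i]][2]
    ns <- tk[i, "p adj"] >= alpha
    adj[a, b] <- ns
    adj[b, a] <- ns
  }
  gr <- igraph::graph_from_adjacency_matrix(adj,
    mode = "undirected", diag = FALSE
  )
  cliques <- igraph::max_cliques(gr)
  means <- tapply(df$y, df$g, mean)
  # order cliques by the largest member mean so "a" marks the top group
  clique_rank <- vapply(
    cliques, function(cl) max(means[lev[as.integer(cl)]]), numeric(1)
  )
  cliques <- cliques[order(-clique_rank)]
  lab <- setNames(rep("", length(lev)), lev)
  for (i in seq_along(cliques)) {
    members <- lev[as.integer(cliques[[i]])]
    lab[members] <- paste0(lab[members], letters[i])
  }
  tibble(
    group = lev,
    mean = as.numeric(means[lev]),
    sd = as.numeric(tapply(df$y, df$g, stats::sd)[lev]),
    n = as.integer(table(df$g)[lev]),
    letters = unname(lab)
  ) %>% arrange(dplyr::desc(.data$mean))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA on %s by %s: F = %.4g, p = %.4g (alpha = %g)\n",
    x$value, x$group, x$f_statistic, x$p_value, x$alpha
  ))
  print(x$letters, ...)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  x$letters
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    f_statistic = x$f_statistic,
    p_value = x$p_value,
    n_groups = nrow(x$letters),
    alpha = x$alpha
  )
}
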