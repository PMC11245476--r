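# ggplot2 figures for each result type.

#' Plot normalized DNA-SIP gradient profiles
#'
#' Relative abundance against buoyant density, one line per isotope,
#' faceted by gene and sample. Mirrors the standard SIP figure in which
#' the 13C profile of a labeled population sits to the right (heavier)
#' of its 12C control.
#'
#' @param data Gradient table; normalized on the fly if needed.
#' @return A ggplot object.
#' @export
plot_gradient <- function(data) {
  if (!"rel_abundance" %in% names(data)) data <- normalize_profile(data)
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$density_g_per_mL, y = .data$rel_abundance,
    colour = .data$isotope, group = .data$isotope
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$gene),
      cols = ggplot2::vars(.data$sample_id)
    ) +
    ggplot2::labs(
      x = expression(paste("Buoyant density (g ", mL^-1, ")")),
      y = "Relative gene abundance",
      colour = "Isotope"
    ) +
    ggplot2::theme_bw()
}

#' Plot per-group pathway contributions
#'
#' Stacked bars of the NH2OH-oxidation and nitrifier-denitrification
#' shares of N2O per group, from [group_partition_summary()] output.
#'
#' @param data Per-group summary with `f_a_mean_pct` and `f_n_mean_pct`.
#' @return A ggplot object.
#' @export
plot_partition_summary <- function(data) {
  long <- data %>%
    select("group", "f_a_mean_pct", "f_n_mean_pct") %>%
    tidyr::pivot_longer(-"group",
      names_to = "pathway", values_to = "pct"
    ) %>%
    mutate(pathway = ifelse(
      .data$pathway == "f_a_mean_pct", "NH2OH oxidation",
      "nitrifier denitrification"
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$group, y = .data$pct, fill = .data$pathway
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Share of N2O emission (%)", fill = NULL) +
    ggplot2::theme_bw()
}

#' Plot per-cell nitrification rates by group
#'
#' @param data Output of [estimate_rates()].
#' @return A ggplot object.
#' @export
plot_rates <- function(data) {
  check_columns(data, c("group", "analyte", "rate_fmol_per_cell_h"),
    "rate table"
  )
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$group, y = .data$rate_fmol_per_cell_h, fill = .data$analyte
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL,
      y = expression(paste("Rate (fmol N ", cell^-1, " ", h^-1, ")")),
      fill = "Analyte"
    ) +
    ggplot2::theme_bw()
}

#' Plot Monte Carlo partition summaries
#'
#' Posterior-style interval plot of the nitrifier-denitrification fraction
#' per sample: mean with the 2.5-97.5 percentile band of the Monte Carlo
#' draws.
#'
#' @param object An `mc_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_partition <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$sample_id, y = .data$f_n_mean, colour = .data$group
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$f_n_q025, ymax = .data$f_n_q975
    )) +
    ggplot2::labs(
      x = NULL,
      y = expression(F[N] ~ "(nitrifier denitrification fraction)"),
      colour = "Group"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a group comparison with Tukey letters
#'
#' @param object A `group_comparison` object from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  lt <- tidy(object)
  ggplot2::ggplot(lt, ggplot2::aes(x = stats::reorder(
    .data$group, -.data$mean
  ), y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
    ), width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      label = .data$letters, y = .data$mean + .data$sd
    ), vjust = -0.5) +
    ggplot2::labs(x = NULL, y = object$value) +
    ggplot2::theme_bw()
}
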