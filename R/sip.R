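# DNA-SIP CsCl gradient analysis: per-fraction qPCR normalization, peak
# buoyant density location, 12C -> 13C density shifts, labeling calls and
# heavy-fraction selection.

.GRADIENT_KEYS <- c("sample_id", "gene", "isotope")

.validate_gradient <- function(data) {
  check_columns(
    data,
    c(.GRADIENT_KEYS, "fraction_index", "density_g_per_mL", "copies"),
    "gradient table"
  )
  if (any(data$copies < 0)) validation_error("qPCR copies must be non-negative")
  if (any(data$density_g_per_mL < 1.60 | data$density_g_per_mL > 1.80)) {
    validation_error("buoyant densities outside the plausible CsCl range [1.60, 1.80]")
  }
  if (!all(data$isotope %in% c("12C", "13C"))) {
    validation_error("isotope must be '12C' or '13C'")
  }
  counts <- data %>%
    group_by(dplyr::across(dplyr::all_of(.GRADIENT_KEYS))) %>%
    summarise(k = dplyr::n(), .groups = "drop")
  if (any(counts$k != 13)) {
    warn("some gradient profiles do not have the expected 13 fractions")
  }
  invisible(data)
}

#' Normalize per-fraction qPCR profiles
#'
#' Each fraction's copy number is divided by the summed copies of all
#' fractions of the same sample/gene/isotope profile, giving relative
#' abundances that sum to 1. Normalization is idempotent and invariant to
#' rescaling all copies of a profile.
#'
#' @param data Gradient table: `sample_id`, `gene`, `isotope` (`12C` or
#'   `13C`), `fraction_index` (1-13), `density_g_per_mL`, `copies`.
#' @return `data` with a `rel_abundance` column.
#' @export
normalize_profile <- function(data) {
  .validate_gradient(data)
  out <- data %>%
    as_tibble() %>%
    group_by(dplyr::across(dplyr::all_of(.GRADIENT_KEYS))) %>%
    mutate(.total = sum(.data$copies)) %>%
    ungroup()
  if (any(out$.total <= 0)) {
    abort("a profile has zero total copies; cannot normalize an empty gradient",
      class = "nitrisphere_empty_gradient"
    )
  }
  out %>%
    mutate(rel_abundance = .data$copies / .data$.total) %>%
    select(-".total")
}

#' Peak buoyant density of each gradient profile
#'
#' `method = "argmax"` returns the density of the maximal-abundance
#' fraction (ties break to the lowest fraction index, with a message);
#' `method = "centroid"` returns the abundance-weighted mean density of the
#' `k` highest fractions, which is robust to qPCR noise.
#'
#' @param data Gradient table; normalized on the fly if `rel_abundance`
#'   is absent.
#' @param method Peak statistic.
#' @param k Number of top fractions for the centroid (default 3).
#' @return One row per profile: keys plus `peak_density` and `method`.
#' @export
peak_density <- function(data, method = c("argmax", "centroid"), k = 3) {
  method <- match.arg(method)
  if (!"rel_abundance" %in% names(data)) data <- normalize_profile(data)
  if (nrow(data) == 0) validation_error("empty gradient profile")
  out <- data %>%
    group_by(dplyr::across(dplyr::all_of(.GRADIENT_KEYS))) %>%
    summarise(
      peak_density = .peak_one(
        .data$density_g_per_mL, .data$rel_abundance, .data$fraction_index,
        method, k
      ),
      .tied = method == "argmax" &&
        sum(.data$rel_abundance == max(.data$rel_abundance)) > 1,
      .groups = "drop"
    )
  if (any(out$.tied)) {
    inform("tied maxima in some profiles; lowest fraction index used")
  }
  out %>%
    mutate(method = method) %>%
    select(-".tied")
}

.peak_one <- function(density, abund, index, method, k) {
  if (method == "argmax") {
    top <- which(abund == max(abund))
    density[top[which.min(index[top])]]
  } else {
    o <- order(abund, decreasing = TRUE)[seq_len(min(k, length(abund)))]
    sum(density[o] * abund[o]) / sum(abund[o])
  }
}

#' Buoyant-density shift between a light and a heavy profile
#'
#' The 12C -> 13C shift of the peak buoyant density for one sample/gene
#' lineage: `shift = peak(heavy) - peak(light)`. Isotope incorporation by
#' an active population moves its DNA to heavier CsCl densities.
#'
#' @param light,heavy Single gradient profiles (12C and 13C) for the same
#'   gene.
#' @inheritParams peak_density
#' @param threshold Labeling threshold passed to [classify_labeled()].
#' @return A one-row tibble: `gene`, `peak_density_light`,
#'   `peak_density_heavy`, `shift`, `labeled`, `threshold`, `method`.
#' @export
density_shift <- function(light, heavy, method = c("argmax", "centroid"),
                          k = 3, threshold = 0.015) {
  method <- match.arg(method)
  g_light <- unique(light$gene)
  g_heavy <- unique(heavy$gene)
  if (length(g_light) != 1 || length(g_heavy) != 1 || g_light != g_heavy) {
    validation_error("light and heavy profiles must target the same single gene")
  }
  pl <- peak_density(light, method, k)$peak_density
  ph <- peak_density(heavy, method, k)$peak_density
  if (length(pl) != 1 || length(ph) != 1) {
    validation_error("density_shift expects exactly one profile per isotope; use sip_shift() for grouped tables")
  }
  tibble(
    gene = g_light,
    peak_density_light = pl,
    peak_density_heavy = ph,
    shift = ph - pl,
    labeled = classify_labeled(ph - pl, threshold),
    threshold = threshold,
    method = method
  )
}

#' Density shifts and labeling calls across a gradient table
#'
#' Grouped version of [density_shift()]: for every sample/gene lineage
#' with both a 12C and a 13C profile, computes the peak-density shift and
#' calls labeling.
#'
#' @inheritParams peak_density
#' @param threshold Labeling threshold in g mL\eqn{^{-1}} (default 0.015).
#' @return One row per sample/gene: peak densities, `shift`, `labeled`,
#'   `threshold`, `method`.
#' @export
sip_shift <- function(data, method = c("argmax", "centroid"), k = 3,
                      threshold = 0.015) {
  method <- match.arg(method)
  peaks <- peak_density(data, method, k)
  wide <- peaks %>%
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(c("sample_id", "gene")),
      names_from = "isotope", values_from = "peak_density"
    )
  if (!all(c("12C", "13C") %in% names(wide)) || anyNA(wide[["12C"]]) ||
    anyNA(wide[["13C"]])) {
    validation_error("every sample/gene lineage needs both a 12C and a 13C profile")
  }
  wide %>%
    rename(peak_density_light = "12C", peak_density_heavy = "13C") %>%
    mutate(
      shift = .data$peak_density_heavy - .data$peak_density_light,
      labeled = classify_labeled(.data$shift, threshold),
      threshold = threshold,
      method = method
    )
}

#' Call isotopic labeling from a density shift
#'
#' A lineage is called labeled when its 12C -> 13C peak-density shift is at
#' least `threshold` g mL\eqn{^{-1}}. The 0.015 default separates the
#' clearly shifted AOB profiles (0.016-0.022) from the poorly fractionated
#' AOA profiles (0.008-0.012).
#'
#' @param shift Density shift(s), g mL\eqn{^{-1}}.
#' @param threshold Non-negative threshold, g mL\eqn{^{-1}}.
#' @return Logical vector.
#' @export
classify_labeled <- function(shift, threshold = 0.015) {
  if (any(threshold < 0)) validation_error("labeling threshold must be non-negative")
  shift >= threshold
}

#' Define the heavy-fraction selection window
#'
#' Either explicit fraction indices (default 9 and 10, the fractions taken
#' for sequencing) or a closed buoyant-density interval (e.g.
#' `c(1.699, 1.702)` g mL\eqn{^{-1}}).
#'
#' @param indices Integer fraction indices in 1..13, or `NULL`.
#' @param densities Length-2 density interval in g mL\eqn{^{-1}}, or
#'   `NULL`. Exactly one of `indices`/`densities` must be given.
#' @return An object of class `heavy_window`.
#' @export
heavy_window <- function(indices = c(9L, 10L), densities = NULL) {
  if (!is.null(densities)) {
    indices <- NULL
    if (length(densities) != 2 || densities[1] >= densities[2]) {
      validation_error("density window must be an increasing length-2 interval")
    }
  } else {
    if (is.null(indices) || any(indices < 1 | indices > 13)) {
      validation_error("fraction indices must lie in 1..13")
    }
  }
  structure(list(indices = indices, densities = densities),
    class = "heavy_window"
  )
}

#' Select heavy fractions from a gradient table
#'
#' Keeps fractions whose index is in the window's index set, or whose
#' density lies in its closed density interval. An empty selection is a
#' warning, not an error.
#'
#' @param data Gradient table.
#' @param window A [heavy_window()].
#' @return The selected rows of `data`.
#' @export
select_heavy_fractions <- function(data, window = heavy_window()) {
  stopifnot(inherits(window, "heavy_window"))
  check_columns(data, c("fraction_index", "density_g_per_mL"), "gradient table")
  out <- if (!is.null(window$indices)) {
    data %>% filter(.data$fraction_index %in% window$indices)
  } else {
    data %>% filter(
      .data$density_g_per_mL >= window$densities[1],
      .data$density_g_per_mL <= window$densities[2]
    )
  }
  if (nrow(out) == 0) warn("heavy-fraction window selected no fractions")
  out
}

#' Read a gradient CSV
#'
#' Expects columns `sample_id`, `gene`, `isotope` (12C|13C),
#' `fraction_index`, `density_g_per_mL`, `copies`.
#'
#' @param path Path to the CSV file.
#' @return A validated gradient tibble.
#' @export
read_gradient <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  .validate_gradient(data)
  as_tibble(data)
}
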