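# N2O isotopocule arithmetic: delta notation, site preference (SP),
# NO+ fragment scrambling correction and two-point SP calibration.

# 15N/14N of atmospheric N2, the reference for all per-mil values here.
R15_AIR_N2 <- 0.0036765

#' Convert raw isotope ratios to delta notation
#'
#' Expresses a sample's \eqn{^{15}N/^{14}N} ratio relative to a reference
#' ratio (atmospheric \eqn{^{15}N}-N\eqn{_2} by convention) in per mil:
#' \eqn{\delta = 1000 (R_{sample} - R_{standard}) / R_{standard}}.
#'
#' @param r_sample Dimensionless \eqn{^{15}N/^{14}N} ratio(s) of the sample
#'   (per N position, or bulk).
#' @param r_standard Dimensionless ratio of the reference; defaults to
#'   atmospheric N\eqn{_2} (0.0036765).
#' @return Numeric vector of delta values in per mil.
#' @examples
#' delta_from_ratios(0.0037, 0.0036765)
#' @export
delta_from_ratios <- function(r_sample, r_standard = R15_AIR_N2) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard))) {
    validation_error("isotope ratios must be finite")
  }
  if (any(r_standard <= 0)) {
    validation_error("reference isotope ratio must be strictly positive")
  }
  if (any(r_sample <= 0)) {
    validation_error("sample isotope ratio must be strictly positive")
  }
  if (any(r_sample >= 0.1) || any(r_standard >= 0.1)) {
    validation_error("isotope ratios must be << 1 (plausibility bound 0.1)")
  }
  1000 * (r_sample - r_standard) / r_standard
}

#' Bulk delta and site preference from site-specific deltas
#'
#' The bulk \eqn{\delta^{15}N} of N\eqn{_2}O is the mean of the central
#' (alpha) and terminal (beta) position deltas; the site preference is their
#' difference \eqn{SP = \delta^{15}N^\alpha - \delta^{15}N^\beta}.
#'
#' @param delta_alpha,delta_beta Position-specific deltas in per mil.
#' @return Per-mil value(s).
#' @export
bulk_from_site_deltas <- function(delta_alpha, delta_beta) {
  (delta_alpha + delta_beta) / 2
}

#' @rdname bulk_from_site_deltas
#' @export
sp_from_site_deltas <- function(delta_alpha, delta_beta) {
  delta_alpha - delta_beta
}

#' Recover site-specific deltas from bulk delta and site preference
#'
#' Algebraic inverse of [bulk_from_site_deltas()] and
#' [sp_from_site_deltas()]: \eqn{\delta^\alpha = \delta^{bulk} + SP/2},
#' \eqn{\delta^\beta = \delta^{bulk} - SP/2}.
#'
#' @param delta_bulk Bulk delta in per mil.
#' @param sp Site preference in per mil.
#' @return A tibble with columns `delta_alpha` and `delta_beta` (per mil).
#' @export
site_deltas_from_bulk_sp <- function(delta_bulk, sp) {
  tibble(
    delta_alpha = delta_bulk + sp / 2,
    delta_beta  = delta_bulk - sp / 2
  )
}

#' Correct NO+ fragment-ion ratios for scrambling
#'
#' In the ion source a fraction `gamma` of NO+ fragment ions carry the
#' terminal (beta) rather than central (alpha) nitrogen, so the measured
#' m/z 31/30 ratio mixes the two positions:
#' \eqn{r_{31} = (1-\gamma) r^\alpha + \gamma r^\beta}. Together with the
#' bulk constraint \eqn{r^\alpha + r^\beta = 2 r_{bulk}} this is solved for
#' the position-specific ratios.
#'
#' @param r31 Measured m/z 31/30 ion-current ratio of the NO+ fragment.
#' @param r_bulk Bulk \eqn{^{15}N/^{14}N} ratio of the parent N\eqn{_2}O.
#' @param gamma Scrambling factor in `[0, 0.5]`; default 0.085.
#' @return A tibble with columns `r15_alpha`, `r15_beta`.
#' @export
correct_scrambling <- function(r31, r_bulk, gamma = 0.085) {
  if (any(gamma < 0) || any(gamma > 0.5)) {
    validation_error("scrambling factor gamma must lie in [0, 0.5]")
  }
  if (any(r31 <= 0) || any(r_bulk <= 0)) {
    validation_error("fragment and bulk ratios must be strictly positive")
  }
  if (any(abs(gamma - 0.5) < 1e-12 & abs(r31 - r_bulk) > 1e-12)) {
    abort(
      "gamma = 0.5 scrambles the positions completely; alpha and beta cannot be resolved unless r31 = r_bulk",
      class = "nitrisphere_unresolvable_positions"
    )
  }
  r15_alpha <- ifelse(
    abs(gamma - 0.5) < 1e-12,
    r_bulk,
    (r31 - 2 * gamma * r_bulk) / (1 - 2 * gamma)
  )
  tibble(r15_alpha = r15_alpha, r15_beta = 2 * r_bulk - r15_alpha)
}

#' Define a pair of SP calibration standards
#'
#' Two reference gases with known and measured position-specific deltas,
#' used for the two-point affine calibration of site preference.
#'
#' @param known_alpha,known_beta Length-2 vectors of the certified
#'   position-specific deltas (per mil) of the two standards.
#' @param measured_alpha,measured_beta Length-2 vectors of the deltas
#'   measured on the instrument for the same standards.
#' @return An object of class `calibration_standards`.
#' @export
calibration_standards <- function(known_alpha, known_beta,
                                  measured_alpha, measured_beta) {
  lens <- lengths(list(known_alpha, known_beta, measured_alpha, measured_beta))
  if (any(lens != 2)) {
    validation_error("each argument must give values for exactly 2 standards")
  }
  known_sp <- sp_from_site_deltas(known_alpha, known_beta)
  measured_sp <- sp_from_site_deltas(measured_alpha, measured_beta)
  if (abs(known_sp[1] - known_sp[2]) < 1e-12) {
    abort("the two standards' known SP values must be distinct",
      class = "nitrisphere_degenerate_calibration"
    )
  }
  structure(
    list(
      known_sp = known_sp, measured_sp = measured_sp,
      known_alpha = known_alpha, known_beta = known_beta
    ),
    class = "calibration_standards"
  )
}

#' Two-point SP calibration of an isotopocule table
#'
#' Fits the affine map carrying the two measured SP values of the reference
#' gases onto their certified values and applies it to the `sp_permil`
#' column. Bulk \eqn{\delta^{15}N} is preserved; position-specific deltas are
#' recentered about it via [site_deltas_from_bulk_sp()]. The map is exact at
#' both standards.
#'
#' @param data Isotopocule table, as built by [as_isotopocule_table()].
#' @param standards A [calibration_standards()] object.
#' @return `data` with calibrated `sp_permil`, `delta_alpha_permil`,
#'   `delta_beta_permil` (bulk unchanged).
#' @export
two_point_calibrate <- function(data, standards) {
  stopifnot(inherits(standards, "calibration_standards"))
  check_columns(data, c("delta_bulk_permil", "sp_permil"), "isotopocule table")
  msp <- standards$measured_sp
  ksp <- standards$known_sp
  if (abs(msp[1] - msp[2]) < 1e-12) {
    abort("measured SP values of the two standards coincide; calibration is degenerate",
      class = "nitrisphere_degenerate_calibration"
    )
  }
  slope <- (ksp[2] - ksp[1]) / (msp[2] - msp[1])
  offset <- ksp[1] - slope * msp[1]
  sp_cal <- slope * data$sp_permil + offset
  ab <- site_deltas_from_bulk_sp(data$delta_bulk_permil, sp_cal)
  data %>%
    mutate(
      sp_permil = sp_cal,
      delta_alpha_permil = ab$delta_alpha,
      delta_beta_permil = ab$delta_beta
    )
}

#' Build a validated isotopocule record table
#'
#' Takes per-sample position-specific deltas (or raw fragment-ion ratios)
#' and derives bulk delta and site preference. In raw mode the m/z 31/30
#' and bulk ratios are first scrambling-corrected with
#' [correct_scrambling()] and converted to deltas against atmospheric
#' N\eqn{_2}.
#'
#' @param data A data frame with `sample_id`, `group` and either
#'   `delta_alpha_permil`/`delta_beta_permil` (default) or `r31`/`r_bulk`
#'   (`raw = TRUE`).
#' @param raw Set `TRUE` when `data` carries fragment-ion ratios.
#' @param gamma Scrambling factor used in raw mode.
#' @param r15_standard Reference ratio used in raw mode.
#' @return A tibble with `sample_id`, `group`, `delta_alpha_permil`,
#'   `delta_beta_permil`, `delta_bulk_permil`, `sp_permil`.
#' @export
as_isotopocule_table <- function(data, raw = FALSE, gamma = 0.085,
                                 r15_standard = R15_AIR_N2) {
  check_columns(data, c("sample_id", "group"), "isotopocule table")
  data <- as_tibble(data)
  if (nrow(data) == 0) validation_error("isotopocule table is empty")
  if (raw) {
    check_columns(data, c("r31", "r_bulk"), "raw isotopocule table")
    pos <- correct_scrambling(data$r31, data$r_bulk, gamma)
    data <- data %>% mutate(
      delta_alpha_permil = delta_from_ratios(pos$r15_alpha, r15_standard),
      delta_beta_permil = delta_from_ratios(pos$r15_beta, r15_standard)
    )
  }
  check_columns(data, c("delta_alpha_permil", "delta_beta_permil"),
    "isotopocule table"
  )
  data %>% mutate(
    delta_bulk_permil = bulk_from_site_deltas(
      .data$delta_alpha_permil, .data$delta_beta_permil
    ),
    sp_permil = sp_from_site_deltas(
      .data$delta_alpha_permil, .data$delta_beta_permil
    )
  )
}

#' Read an isotopocule CSV
#'
#' Expects columns `sample_id`, `group` and `delta_alpha_permil`,
#' `delta_beta_permil` (or `r31`, `r_bulk` with `raw = TRUE`).
#'
#' @inheritParams as_isotopocule_table
#' @param path Path to the CSV file.
#' @return The derived isotopocule table (see [as_isotopocule_table()]).
#' @export
read_isotopocules <- function(path, raw = FALSE, gamma = 0.085,
                              r15_standard = R15_AIR_N2) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  as_isotopocule_table(data, raw = raw, gamma = gamma,
    r15_standard = r15_standard
  )
}

#' Write a derived isotopocule table as CSV
#'
#' @param data Isotopocule table.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_isotopocules <- function(data, path) {
  check_columns(
    data,
    c("sample_id", "group", "delta_alpha_permil", "delta_beta_permil",
      "delta_bulk_permil", "sp_permil"),
    "isotopocule table"
  )
  readr::write_csv(data, path)
  invisible(data)
}
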