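#' Expected log2(H/M) under partial proteasomal inhibition
#'
#' For a protein degraded as a first-order process with half-life `t_half_h`,
#' slowing its degradation time constant by a factor `alpha` makes the
#' residual treated/control pool ratio grow as
#' log2(H/M) = t * (alpha - 1) / (alpha * t_half). `expected_log2_hm_limit()`
#' is the strong-inhibition limit t / t_half (alpha >> 1); the two differ by
#' at most t / (alpha * t_half).
#'
#' @param t_h Time(s) since inhibitor addition, hours.
#' @param t_half_h Protein half-life, hours.
#' @param alpha Inhibition factor, >= 1.
#' @return Nonnegative numeric vector of expected log2 ratios.
#' @examples
#' expected_log2_hm(24, 5 * 24, 10) # 0.18
#' expected_log2_hm_limit(24, 5 * 24) # 0.2
#' @export
expected_log2_hm <- function(t_h, t_half_h, alpha = 10) {
  if (any(t_h < 0) || any(t_half_h <= 0) || any(alpha < 1)) {
    rlang::abort("need t_h >= 0, t_half_h > 0, alpha >= 1")
  }
  t_h * (alpha - 1) / (alpha * t_half_h)
}

#' @rdname expected_log2_hm
#' @export
expected_log2_hm_limit <- function(t_h, t_half_h) {
  if (any(t_h < 0) || any(t_half_h <= 0)) {
    rlang::abort("need t_h >= 0, t_half_h > 0")
  }
  t_h / t_half_h
}

#' Expected log2(H/M) time course for a set of half-lives
#'
#' @param times_h Time grid in hours.
#' @param t_half_d Half-lives in days (one curve per value).
#' @param alpha Inhibition factor.
#' @return A tibble `t_half_d, alpha, time_h, expected_log2_hm`, one row per
#'   half-life x time.
#' @export
expected_profile <- function(times_h = seq(0, 24, by = 0.5),
                             t_half_d = 1:10, alpha = 10) {
  tidyr::expand_grid(t_half_d = t_half_d, time_h = times_h) |>
    dplyr::mutate(
      alpha = alpha,
      expected_log2_hm = expected_log2_hm(.data$time_h, .data$t_half_d * 24,
                                          alpha)
    ) |>
    dplyr::select("t_half_d", "alpha", "time_h", "expected_log2_hm")
}

#' Longest half-life whose inhibition effect is still resolvable
#'
#' Inverts the expected-ratio model at a detection threshold: the half-life at
#' which the expected log2(H/M) at time `t_h` equals `threshold_log2` is
#' t_half* = t * (alpha - 1) / (alpha * threshold). Proteins longer-lived than
#' this produce expected ratios below the threshold and elude detection.
#'
#' @inheritParams expected_log2_hm
#' @param threshold_log2 Positive detection threshold in log2 units
#'   (typically 3 x the t = 0 SD).
#' @return Half-life in hours.
#' @examples
#' detection_limit_half_life(24, 10, 0.18) / 24 # 5 days
#' @export
detection_limit_half_life <- function(t_h, alpha, threshold_log2) {
  if (any(threshold_log2 <= 0)) {
    rlang::abort("threshold_log2 must be positive")
  }
  if (any(t_h < 0) || any(alpha < 1)) {
    rlang::abort("need t_h >= 0, alpha >= 1")
  }
  t_h * (alpha - 1) / (alpha * threshold_log2)
}

#' Correlate measured log2(H/M) values with model expectations
#'
#' Restricts to proteins with half-life at most `max_half_life_d` (expected
#' effects of longer-lived proteins are below measurement certainty), drops
#' any listed outliers, optionally subtracts the population-mean measured
#' value at that time point (residual normalization offsets shift all
#' measurements together), and reports the Pearson correlation between
#' measured values and `expected_log2_hm()` predictions.
#'
#' @param measured Tibble with columns `protein_id` and `mean_log2` (measured
#'   log2 H/M at time `t_h`).
#' @param half_lives Tibble with columns `protein_id`, `half_life_h`.
#' @param alpha Inhibition factor used for predictions.
#' @param t_h Time point of the measurements, hours.
#' @param max_half_life_d Half-life cap in days (default 5).
#' @param exclude_ids Protein ids to drop (extreme outliers).
#' @param subtract_population_mean Subtract the mean measured value before
#'   correlating (default TRUE).
#' @return A one-row tibble with `r` and `n`.
#' @export
correlate_measured_expected <- function(measured, half_lives, alpha = 10,
                                        t_h = 24, max_half_life_d = 5,
                                        exclude_ids = character(),
                                        subtract_population_mean = TRUE) {
  df <- measured |>
    dplyr::inner_join(half_lives, by = "protein_id") |>
    dplyr::filter(.data$half_life_h <= max_half_life_d * 24,
                  !.data$protein_id %in% exclude_ids)
  if (nrow(df) < 3) {
    rlang::abort("fewer than 3 proteins after filtering; cannot correlate")
  }
  y <- df$mean_log2
  if (subtract_population_mean) {
    y <- y - mean(measured$mean_log2)
  }
  pred <- expected_log2_hm(t_h, df$half_life_h, alpha)
  tibble::tibble(r = stats::cor(y, pred), n = nrow(df))
}

#' Write expected-ratio prediction curves to CSV
#'
#' @param curves Tibble from [expected_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}
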