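#' Plot expected log2(H/M) time courses for a grid of half-lives
#'
#' @param t_half_d Half-lives in days, one curve each.
#' @param alpha Inhibition factor.
#' @param times_h Time grid, hours.
#' @return A ggplot object.
#' @export
plot_expected_curves <- function(t_half_d = 1:10, alpha = 10,
                                 times_h = seq(0, 24, by = 0.5)) {
  expected_profile(times_h, t_half_d, alpha) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$time_h, y = .data$expected_log2_hm,
      group = .data$t_half_d, colour = factor(.data$t_half_d)
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time after inhibitor addition (h)",
      y = expression(expected ~ log[2] * "(H/M)"),
      colour = expression(t[1 / 2] ~ "(d)"),
      title = sprintf("Expected residual-pool ratios, alpha = %g", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Rank plot of apparent half-life fold changes (pulsed design)
#'
#' Proteins sorted from the strongest H/L reduction to the strongest increase;
#' an optional highlight set (e.g. known synthesis-suppressed proteins) is
#' overdrawn in red.
#'
#' @param pulsed A [run_pulsed_pipeline()] bundle or its `fold_changes` tibble.
#' @param highlight_ids Protein ids to mark.
#' @return A ggplot object.
#' @export
plot_fold_change_rank <- function(pulsed, highlight_ids = character()) {
  fc <- if (inherits(pulsed, "pulsed_bundle")) pulsed$fold_changes else pulsed
  p <- ggplot2::ggplot(fc, ggplot2::aes(x = .data$rank,
                                        y = .data$delta_log2_hl)) +
    ggplot2::geom_point(size = 0.5, colour = "grey40") +
    ggplot2::labs(
      x = "protein rank",
      y = expression(log[2] * "(H/L)"["treated"] - log[2] * "(H/L)"["control"])
    ) +
    ggplot2::theme_minimal()
  if (length(highlight_ids) > 0) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(fc, .data$protein_id %in% highlight_ids),
      colour = "red", size = 1
    )
  }
  p
}

#' Measured vs expected log2(H/M) as a function of half-life
#'
#' Scatter of measured per-protein values at one time point against half-life,
#' with the model expectation overlaid and significant proteins colored.
#'
#' @param bundle A [run_multiplexed_pipeline()] bundle.
#' @param t_h Time point, hours.
#' @param alpha Inhibition factor for the expectation curve.
#' @param max_half_life_d Half-life axis limit, days.
#' @return A ggplot object.
#' @export
plot_measured_vs_expected <- function(bundle, t_h = 24, alpha = 10,
                                      max_half_life_d = 10) {
  df <- bundle$merged[abs(bundle$merged$time_h - t_h) <= 0.5, ] |>
    dplyr::inner_join(
      dplyr::select(bundle$truth, "protein_id", "half_life_h"),
      by = "protein_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(bundle$classification, "protein_id", "p_value"),
      by = "protein_id"
    ) |>
    dplyr::filter(.data$half_life_h <= max_half_life_d * 24) |>
    dplyr::mutate(significant = .data$p_value <= 0.05)
  grid_d <- seq(0.25, max_half_life_d, by = 0.05)
  curve <- tibble::tibble(
    half_life_d = grid_d,
    expected = expected_log2_hm(t_h, grid_d * 24, alpha)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$half_life_h / 24,
                                   y = .data$mean_log2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.6) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$half_life_d, y = .data$expected),
                       colour = "steelblue") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "half-life (d)",
                  y = expression(log[2] * "(H/M)"),
                  colour = "p <= 0.05") +
    ggplot2::theme_minimal()
}
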