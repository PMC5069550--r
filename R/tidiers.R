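#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a t = 0 variability estimate
#'
#' @param x A [estimate_t0_variability()] result.
#' @param ... Unused.
#' @return A one-row tibble with the SD, protein count, 3-SD threshold and
#'   the corresponding H/M ratio bounds.
#' @method tidy t0_variability
#' @export
tidy.t0_variability <- function(x, ...) {
  tibble::tibble(
    sd_log2_t0 = x$sd_log2_t0,
    n_proteins = x$n_proteins,
    threshold_log2 = x$threshold_log2,
    ratio_lower = x$ratio_bounds[["lower"]],
    ratio_upper = x$ratio_bounds[["upper"]]
  )
}

#' Tidy / summarize half-life fits
#'
#' `tidy()` returns the per-protein estimates with day-unit half-lives;
#' `glance()` returns one row with fit counts and the median half-life.
#'
#' @param x A `half_life_fit` from [estimate_half_life()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy half_life_fit
#' @export
tidy.half_life_fit <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(half_life_d = .data$half_life_h / 24)
}

#' @rdname tidy.half_life_fit
#' @method glance half_life_fit
#' @export
glance.half_life_fit <- function(x, ...) {
  ok <- x$status == "ok"
  tibble::tibble(
    n = nrow(x),
    n_ok = sum(ok),
    n_saturated = sum(x$status == "saturated"),
    n_infinite = sum(x$status == "infinite"),
    median_half_life_h = stats::median(x$half_life_h[ok])
  )
}

#' Glance at a multiplexed pipeline bundle
#'
#' @param x A `multiplexed_bundle`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities of the run.
#' @method glance multiplexed_bundle
#' @export
glance.multiplexed_bundle <- function(x, ...) {
  cls <- x$classification$class
  tibble::tibble(
    n_proteins = nrow(x$classification),
    sd_log2_t0 = x$variability$sd_log2_t0,
    threshold_log2 = x$variability$threshold_log2,
    n_significant = sum(x$classification$p_value <= 0.05),
    n_slowed_3sd = sum(cls == "slowed_significant_3sd"),
    r_measured_expected = x$correlation$r
  )
}
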