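#' Fractional saturation of an isotope-pair ratio
#'
#' Converts a labeled/unlabeled ratio R into the labeled fraction
#' R / (R + 1), a value in \[0, 1).
#'
#' @param R Nonnegative ratio(s), e.g. heavy/light.
#' @return Numeric vector of saturations.
#' @examples
#' fractional_saturation(11.195) # ~0.918
#' @export
fractional_saturation <- function(R) {
  if (any(R < 0, na.rm = TRUE)) {
    rlang::abort("ratios must be nonnegative")
  }
  R / (R + 1)
}

#' Fractional incorporation corrected for the maximal attainable labeled
#' fraction
#'
#' With heavy amino acids supplied in finite excess, complete turnover yields
#' a labeled fraction of only `f_max` (5/6 for a 5:1 excess), so the raw
#' saturation is rescaled: F_t = (1 / f_max) * R / (R + 1). Values at or above
#' 1 (within `tol`) mean the measurement is saturated and no turnover time can
#' be estimated.
#'
#' @inheritParams fractional_saturation
#' @param f_max Maximal expected labeled fraction, in (0, 1].
#' @param tol Values above `1 - tol` are treated as saturated downstream.
#' @return Numeric vector of corrected incorporations (may exceed 1 when
#'   saturated; see [estimate_half_life()] for flagging).
#' @examples
#' fractional_incorporation(1, f_max = 5 / 6) # 0.6
#' @export
fractional_incorporation <- function(R, f_max = 5 / 6) {
  stopifnot(f_max > 0, f_max <= 1)
  fractional_saturation(R) / f_max
}

#' Estimate first-order turnover from a single-time-point label ratio
#'
#' Inverts the first-order incorporation model F_t = 1 - exp(-t / tau): the
#' turnover time constant is tau = -t / ln(1 - F_t) and the half-life
#' t_half = ln(2) * tau. Vectorized; returns one row per input ratio with a
#' `status` column: `"ok"`, `"saturated"` (F_t within `tol` of 1 or above —
#' turnover too fast to resolve) or `"infinite"` (F_t = 0 — no detectable
#' turnover over the labeling window).
#'
#' @inheritParams fractional_incorporation
#' @param t_h Labeling duration in hours (default the single 24-h point).
#' @param protein_id Optional id vector carried through to the output.
#' @param tol Saturation guard: F_t >= 1 - tol is flagged rather than passed
#'   to the logarithm.
#' @return A tibble of class `half_life_fit` with columns `protein_id`
#'   (if given), `f_t`, `tau_h`, `half_life_h`, `t_h`, `status`.
#' @examples
#' estimate_half_life(1, t_h = 24) # tau ~26.19 h, t_half ~18.16 h
#' @export
estimate_half_life <- function(R, t_h = 24, f_max = 5 / 6,
                               protein_id = NULL, tol = 1e-9) {
  stopifnot(all(t_h > 0))
  f_t <- fractional_incorporation(R, f_max = f_max)
  status <- dplyr::case_when(
    f_t >= 1 - tol ~ "saturated",
    f_t == 0 ~ "infinite",
    TRUE ~ "ok"
  )
  t_full <- rep_len(t_h, length(f_t))
  tau <- rep(NA_real_, length(f_t))
  ok <- status == "ok"
  tau[ok] <- -t_full[ok] / log(1 - f_t[ok])
  tau[status == "infinite"] <- Inf
  out <- tibble::tibble(
    f_t = f_t,
    tau_h = tau,
    half_life_h = log(2) * tau,
    t_h = rep_len(t_h, length(f_t)),
    status = status
  )
  if (!is.null(protein_id)) {
    out <- dplyr::bind_cols(tibble::tibble(protein_id = protein_id), out)
  }
  class(out) <- c("half_life_fit", class(out))
  out
}

#' Apparent fold change in half-life between two conditions
#'
#' The ratio of estimated turnover time constants, treated over control.
#' Because tau is estimated from label incorporation, suppressed synthesis
#' inflates this ratio even when degradation is untouched — the central
#' confound of inhibitor + pulsed-label designs.
#'
#' @param tau_treated_h,tau_control_h Positive time constants (hours);
#'   vectorized.
#' @return Numeric vector of fold changes.
#' @export
apparent_fold_change <- function(tau_treated_h, tau_control_h) {
  if (any(tau_treated_h <= 0, na.rm = TRUE) ||
        any(tau_control_h <= 0, na.rm = TRUE)) {
    rlang::abort("time constants must be positive")
  }
  tau_treated_h / tau_control_h
}

#' Write half-life estimates to CSV
#'
#' Columns: `protein_id,f_t,tau_h,half_life_h,half_life_d`.
#'
#' @param fit A `half_life_fit` tibble with a `protein_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_half_lives <- function(fit, path) {
  fit |>
    dplyr::select("protein_id", "f_t", "tau_h", "half_life_h") |>
    dplyr::mutate(half_life_d = .data$half_life_h / 24) |>
    readr::write_csv(path)
  invisible(path)
}
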