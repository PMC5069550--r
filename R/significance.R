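#' Estimate measurement variability from t = 0 ratios
#'
#' At t = 0 the treated and control pools are identical, so the spread of
#' per-protein mean log2(H/M) values measures the method's uncertainty. The
#' detection threshold is 3 SD; the corresponding H/M ratio bounds are
#' 2^(+-threshold).
#'
#' @param mean_log2_t0 Numeric vector of per-protein mean log2 values at t = 0.
#' @return An object of class `t0_variability` with fields `sd_log2_t0`,
#'   `n_proteins`, `threshold_log2`, `ratio_bounds`.
#' @examples
#' v <- estimate_t0_variability(rnorm(100, 0, 0.07))
#' v$threshold_log2
#' @export
estimate_t0_variability <- function(mean_log2_t0) {
  mean_log2_t0 <- mean_log2_t0[!is.na(mean_log2_t0)]
  if (length(mean_log2_t0) < 10) {
    rlang::abort("need at least 10 proteins to estimate t = 0 variability")
  }
  s <- stats::sd(mean_log2_t0)
  structure(
    list(
      sd_log2_t0 = s,
      n_proteins = length(mean_log2_t0),
      threshold_log2 = 3 * s,
      ratio_bounds = c(lower = 2^(-3 * s), upper = 2^(3 * s))
    ),
    class = "t0_variability"
  )
}

#' @export
print.t0_variability <- function(x, ...) {
  cat(sprintf(
    "<t0_variability> sd = %.4f log2 units (n = %d); 3-SD threshold %.4f, H/M bounds %.3f-%.3f\n",
    x$sd_log2_t0, x$n_proteins, x$threshold_log2,
    x$ratio_bounds[["lower"]], x$ratio_bounds[["upper"]]
  ))
  invisible(x)
}

#' Two-tailed Welch test between two small replicate groups
#'
#' Wraps [stats::t.test()] (unequal variances, Satterthwaite df) with the
#' degenerate cases made explicit: when both groups have zero variance the
#' test statistic is undefined, and the p-value is 1 for equal means and 0
#' (flagged `degenerate`) for unequal means.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @return A one-row tibble with `t`, `df`, `p_value`, `degenerate`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("need at least 2 values per group")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(
      t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = NA_real_,
      p_value = if (same) 1 else 0,
      degenerate = TRUE
    ))
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    degenerate = FALSE
  )
}

#' Classify proteins by inhibition response
#'
#' For each protein the per-experiment log2(H/M) values at `t_test_h` are
#' compared with those at `t_ref_h` (two-tailed Welch test), and the protein
#' is assigned to exactly one class:
#' * `slowed_significant_3sd` — p <= `p_sig`, positive mean exceeding the
#'   3-SD threshold (confident substrate);
#' * `slowed_significant` — p <= `p_sig`, positive mean below the threshold;
#' * `accelerated_significant` — p <= `p_sig`, negative mean;
#' * `trend` — `p_sig` < p <= `p_trend`, positive mean;
#' * `unaffected` — everything else.
#'
#' @param merged Per-protein per-time tibble from [merge_replicates()].
#' @param variability A [estimate_t0_variability()] result.
#' @param p_sig,p_trend Significance and trend p-value cutoffs.
#' @param t_test_h,t_ref_h Time points compared (default 24 vs 0 h).
#' @param time_tol_h Tolerance when matching time points, hours.
#' @return A tibble of class `protein_classification` with columns
#'   `protein_id`, `mean_log2_hm_24h`, `p_value`, `class`.
#' @export
classify_proteins <- function(merged, variability, p_sig = 0.05,
                              p_trend = 0.10, t_test_h = 24, t_ref_h = 0,
                              time_tol_h = 0.5) {
  at <- function(t) merged[abs(merged$time_h - t) <= time_tol_h, ]
  test_df <- at(t_test_h)
  ref_df <- at(t_ref_h)
  if (nrow(test_df) == 0 || nrow(ref_df) == 0) {
    rlang::abort("merged profiles lack the requested time point(s)")
  }
  df <- dplyr::inner_join(
    dplyr::select(test_df, "protein_id", mean_24 = "mean_log2",
                  values_24 = "values"),
    dplyr::select(ref_df, "protein_id", values_0 = "values"),
    by = "protein_id"
  )
  thr <- variability$threshold_log2
  tests <- purrr::map2(df$values_24, df$values_0, welch_test) |>
    purrr::list_rbind()
  out <- tibble::tibble(
    protein_id = df$protein_id,
    mean_log2_hm_24h = df$mean_24,
    p_value = tests$p_value
  ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$p_value <= p_sig & .data$mean_log2_hm_24h > 0 &
        .data$mean_log2_hm_24h > thr ~ "slowed_significant_3sd",
      .data$p_value <= p_sig & .data$mean_log2_hm_24h > 0 ~
        "slowed_significant",
      .data$p_value <= p_sig & .data$mean_log2_hm_24h < 0 ~
        "accelerated_significant",
      .data$p_value > p_sig & .data$p_value <= p_trend &
        .data$mean_log2_hm_24h > 0 ~ "trend",
      TRUE ~ "unaffected"
    ))
  class(out) <- c("protein_classification", class(out))
  out
}

#' Infer synthesis suppression by combining pulsed and multiplexed results
#'
#' A protein whose pulsed H/L ratio dropped by more than 3 control SDs under
#' inhibitor, yet whose degradation the multiplexed design shows to be
#' unaffected, must owe the drop to suppressed synthesis rather than slowed
#' degradation.
#'
#' @param pulsed Tibble with columns `protein_id` and `delta_log2_hl`
#'   (log2 H/L treated minus control).
#' @param classification A [classify_proteins()] result.
#' @param control_sd_log2hl SD of log2 H/L differences between control
#'   replicates.
#' @return Character vector of synthesis-suppressed protein ids (sorted).
#'   Warns and returns empty when the id sets do not intersect.
#' @export
infer_synthesis_suppression <- function(pulsed, classification,
                                        control_sd_log2hl) {
  common <- intersect(pulsed$protein_id, classification$protein_id)
  if (length(common) == 0) {
    rlang::warn("no shared protein ids between pulsed and multiplexed results")
    return(character())
  }
  df <- pulsed |>
    dplyr::inner_join(
      dplyr::select(classification, "protein_id", "class"),
      by = "protein_id"
    ) |>
    dplyr::filter(
      .data$delta_log2_hl < -3 * control_sd_log2hl,
      !stringr::str_starts(.data$class, "slowed_significant")
    )
  sort(df$protein_id)
}

#' Inspect the most strongly affected fraction of proteins at a time point
#'
#' Selects the top `fraction` of proteins by measured log2(H/M) at time `t_h`
#' and summarizes them: mean molecular weight vs the cohort mean, and the
#' Pearson correlation of their measured values with model expectations from
#' their half-lives (early-time outliers whose size, not half-life, drives
#' the effect show a poor correlation and a high mean weight).
#'
#' @param merged Per-protein per-time tibble from [merge_replicates()].
#' @param metadata Tibble with `protein_id`, `molecular_weight_kda` and
#'   (for the correlation) `half_life_h`.
#' @param fraction Fraction selected, in (0, 1).
#' @param t_h Time point, hours.
#' @param alpha Inhibition factor for expectations.
#' @param exclude_ids Outlier ids dropped from the correlation only.
#' @param time_tol_h Time-matching tolerance, hours.
#' @return A list with `selected` (tibble of selected proteins),
#'   `mean_mw_selected`, `mean_mw_cohort`, `r_expected`, `n`.
#' @export
top_fraction_analysis <- function(merged, metadata, fraction = 0.05, t_h = 4,
                                  alpha = 10, exclude_ids = character(),
                                  time_tol_h = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  at_t <- merged[abs(merged$time_h - t_h) <= time_tol_h, ] |>
    dplyr::inner_join(metadata, by = "protein_id")
  if (nrow(at_t) == 0) {
    rlang::abort("no proteins at the requested time point")
  }
  n_top <- max(1L, floor(fraction * nrow(at_t)))
  sel <- at_t |>
    dplyr::slice_max(.data$mean_log2, n = n_top, with_ties = FALSE)
  r <- NA_real_
  if ("half_life_h" %in% names(sel)) {
    keep <- !sel$protein_id %in% exclude_ids & !is.na(sel$half_life_h)
    if (sum(keep) >= 3) {
      r <- stats::cor(
        sel$mean_log2[keep] - mean(at_t$mean_log2),
        expected_log2_hm(t_h, sel$half_life_h[keep], alpha)
      )
    }
  }
  list(
    selected = sel,
    mean_mw_selected = mean(sel$molecular_weight_kda),
    mean_mw_cohort = mean(at_t$molecular_weight_kda),
    r_expected = r,
    n = n_top
  )
}

#' Tabulate classification counts and percentages
#'
#' @param classification A [classify_proteins()] result.
#' @param annotated_ids Optional character vector of annotated (e.g. synaptic)
#'   protein ids; per-class counts within that subset are reported alongside
#'   the overall counts.
#' @return A tibble with `class`, `n`, `pct` and, when `annotated_ids` is
#'   given, `n_annotated`, `pct_annotated`.
#' @export
summarize_counts <- function(classification, annotated_ids = NULL) {
  if (nrow(classification) == 0) {
    rlang::abort("classification is empty")
  }
  lv <- c("slowed_significant_3sd", "slowed_significant", "trend",
          "unaffected", "accelerated_significant")
  out <- classification |>
    dplyr::count(class = factor(.data$class, levels = lv), .drop = FALSE,
                 name = "n") |>
    dplyr::mutate(class = as.character(.data$class),
                  pct = 100 * .data$n / nrow(classification))
  if (!is.null(annotated_ids)) {
    sub <- classification |>
      dplyr::filter(.data$protein_id %in% annotated_ids)
    ann <- sub |>
      dplyr::count(class = factor(.data$class, levels = lv), .drop = FALSE,
                   name = "n_annotated") |>
      dplyr::mutate(class = as.character(.data$class))
    out <- dplyr::left_join(out, ann, by = "class") |>
      dplyr::mutate(pct_annotated = if (nrow(sub) > 0) {
        100 * .data$n_annotated / nrow(sub)
      } else {
        0
      })
  }
  out
}
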