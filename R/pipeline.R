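#' Default completeness rule for a multiplexed design
#'
#' Splits the replicate experiments into two inhibitor groups (the first three
#' experiments vs the rest, mirroring a 3 + 2 lactacystin/epoxomicin design)
#' and requires a qualifying profile in all but one sample of each group.
#'
#' @param config A [sim_config()].
#' @return A list with elements `design` (experiment-to-group tibble) and
#'   `rule` (per-group `n_samples` / `min_present`).
#' @export
default_completeness_rule <- function(config) {
  experiments <- sprintf("mux%d", seq_len(config$n_replicates))
  n_lacta <- min(3L, length(experiments))
  group <- rep(c("lacta", "epox"),
               c(n_lacta, length(experiments) - n_lacta))
  design <- tibble::tibble(experiment_id = experiments, group = group)
  n_times <- length(config$time_points_h)
  rule <- lapply(split(design$experiment_id, design$group), function(e) {
    n_samples <- length(e) * n_times
    list(n_samples = n_samples, min_present = n_samples - 1L)
  })
  list(design = design, rule = rule)
}

pipeline_stamp <- function(config) {
  sprintf("# silacturn seed=%d config=%s", config$seed, rlang::hash(config))
}

write_stamped_csv <- function(df, path, stamp) {
  readr::write_lines(stamp, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full multiplexed-SILAC degradation pipeline on synthetic data
#'
#' Simulate -> orient -> aggregate -> completeness-filter -> normalize to the
#' reference proteins -> merge replicates -> estimate t = 0 variability ->
#' classify -> correlate with model expectations -> tabulate. Per-stage record
#' counts are logged via [message()].
#'
#' @param config A [sim_config()].
#' @param alpha Inhibition factor used for expectations (default 10).
#' @param p_sig,p_trend Classification p-value cutoffs.
#' @param min_peptides Minimum peptides per protein profile.
#' @param annotated_ids Optional annotation id set for count summaries.
#' @param out_dir Optional directory; when given, every artifact is written as
#'   CSV with a seed/config-hash header comment.
#' @param treated_channels Treated-label assignment passed to
#'   [simulate_multiplexed()].
#' @return A list of class `multiplexed_bundle`: `profiles` (normalized),
#'   `merged`, `variability`, `classification`, `correlation`, `curves`,
#'   `counts`, `truth`, `config`.
#' @export
run_multiplexed_pipeline <- function(config, alpha = 10, p_sig = 0.05,
                                     p_trend = 0.10, min_peptides = 2,
                                     annotated_ids = NULL, out_dir = NULL,
                                     treated_channels = "H") {
  log_stage <- function(stage, n) {
    message(sprintf("[multiplexed] %-22s %d", stage, n))
  }
  truth <- generate_proteome(config)
  sim <- simulate_multiplexed(truth, config, treated_channels)
  log_stage("peptide records", nrow(sim$peptides))
  records <- orient_to_experiment_control(sim$peptides)
  profiles <- aggregate_protein_ratios(records, min_peptides)
  log_stage("protein profiles", nrow(profiles))
  cr <- default_completeness_rule(config)
  keep_ids <- filter_complete(profiles, cr$design, cr$rule)
  profiles <- dplyr::filter(profiles, .data$protein_id %in% keep_ids)
  log_stage("after completeness", length(keep_ids))
  ref_ids <- truth$protein_id[truth$is_reference]
  profiles <- normalize_to_reference(profiles, ref_ids)
  merged <- merge_replicates(profiles)
  t0 <- merged[merged$time_h == 0, ]
  variability <- estimate_t0_variability(t0$mean_log2)
  classification <- classify_proteins(merged, variability, p_sig = p_sig,
                                      p_trend = p_trend)
  log_stage("classified proteins", nrow(classification))
  t24 <- merged[abs(merged$time_h - 24) <= 0.5, ]
  correlation <- correlate_measured_expected(
    t24, dplyr::select(truth, "protein_id", "half_life_h"), alpha = alpha
  )
  curves <- expected_profile(alpha = alpha)
  counts <- summarize_counts(classification, annotated_ids)
  bundle <- structure(
    list(profiles = profiles, merged = merged, variability = variability,
         classification = classification, correlation = correlation,
         curves = curves, counts = counts, truth = truth, config = config),
    class = "multiplexed_bundle"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- pipeline_stamp(config)
    write_stamped_csv(profiles, file.path(out_dir, "profiles.csv"), stamp)
    write_stamped_csv(
      tibble::tibble(sd_log2_t0 = variability$sd_log2_t0,
                     n_proteins = variability$n_proteins,
                     threshold_log2 = variability$threshold_log2,
                     ratio_lower = variability$ratio_bounds[["lower"]],
                     ratio_upper = variability$ratio_bounds[["upper"]]),
      file.path(out_dir, "variability.csv"), stamp
    )
    write_stamped_csv(classification,
                      file.path(out_dir, "classification.csv"), stamp)
    write_stamped_csv(correlation, file.path(out_dir, "correlation.csv"), stamp)
    write_stamped_csv(curves, file.path(out_dir, "prediction_curves.csv"),
                      stamp)
    write_stamped_csv(counts, file.path(out_dir, "counts.csv"), stamp)
  }
  bundle
}

#' Run the pulsed-SILAC apparent-half-life pipeline on synthetic data
#'
#' Simulates heavy-pulse experiments in treated and control conditions,
#' aggregates peptide H/L ratios, averages replicates, estimates per-protein
#' half-lives in each condition from the final time point, and reports
#' apparent half-life fold changes sorted from the strongest H/L reduction to
#' the strongest increase. Saturated proteins are excluded and listed.
#'
#' @inheritParams run_multiplexed_pipeline
#' @param t_h Time point used for half-life estimation (default the last
#'   configured time point).
#' @return A list of class `pulsed_bundle`: `half_lives` (per condition),
#'   `fold_changes` (sorted tibble with `delta_log2_hl`, `tau_control_h`,
#'   `tau_treated_h`, `fold_change`, `rank`), `excluded` (saturated ids),
#'   `control_sd_log2hl`, `truth`, `config`.
#' @export
run_pulsed_pipeline <- function(config, min_peptides = 2,
                                t_h = max(config$time_points_h),
                                out_dir = NULL) {
  log_stage <- function(stage, n) {
    message(sprintf("[pulsed] %-22s %d", stage, n))
  }
  truth <- generate_proteome(config)
  sim <- simulate_pulsed(truth, config)
  log_stage("peptide records", nrow(sim$peptides))
  profiles <- aggregate_protein_ratios(sim$peptides, min_peptides) |>
    tidyr::separate_wider_delim("experiment_id", delim = ".",
                                names = c("rep", "condition"))
  log_stage("protein profiles", nrow(profiles))
  at_t <- profiles[abs(profiles$time_h - t_h) <= 0.5, ]

  # control replicate-to-replicate variability of log2(H/L); the 3-SD band of
  # these differences is the null band for treated-vs-control changes
  ctrl <- at_t |>
    dplyr::filter(.data$condition == "control") |>
    dplyr::select("protein_id", "rep", "log2_ratio") |>
    tidyr::pivot_wider(names_from = "rep", values_from = "log2_ratio")
  rep_cols <- setdiff(names(ctrl), "protein_id")
  control_sd <- if (length(rep_cols) >= 2) {
    stats::sd(ctrl[[rep_cols[1]]] - ctrl[[rep_cols[2]]], na.rm = TRUE)
  } else {
    NA_real_
  }

  avg <- at_t |>
    dplyr::group_by(.data$protein_id, .data$condition) |>
    dplyr::summarise(mean_log2_hl = mean(.data$log2_ratio),
                     n_rep = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean_log2_hl", "n_rep")) |>
    dplyr::filter(!is.na(.data$mean_log2_hl_control),
                  !is.na(.data$mean_log2_hl_treated))
  f_max <- config$heavy_excess / (config$heavy_excess + 1)
  fit_c <- estimate_half_life(2^avg$mean_log2_hl_control, t_h = t_h,
                              f_max = f_max, protein_id = avg$protein_id)
  fit_t <- estimate_half_life(2^avg$mean_log2_hl_treated, t_h = t_h,
                              f_max = f_max, protein_id = avg$protein_id)
  half_lives <- dplyr::bind_rows(
    dplyr::mutate(fit_c, condition = "control"),
    dplyr::mutate(fit_t, condition = "treated")
  )
  ok <- fit_c$status == "ok" & fit_t$status == "ok"
  excluded <- avg$protein_id[!ok]
  log_stage("estimable proteins", sum(ok))
  fold_changes <- tibble::tibble(
    protein_id = avg$protein_id[ok],
    delta_log2_hl = (avg$mean_log2_hl_treated - avg$mean_log2_hl_control)[ok],
    tau_control_h = fit_c$tau_h[ok],
    tau_treated_h = fit_t$tau_h[ok],
    fold_change = apparent_fold_change(fit_t$tau_h[ok], fit_c$tau_h[ok])
  ) |>
    dplyr::arrange(.data$delta_log2_hl) |>
    dplyr::mutate(rank = dplyr::row_number())
  bundle <- structure(
    list(half_lives = half_lives, fold_changes = fold_changes,
         excluded = excluded, control_sd_log2hl = control_sd,
         truth = truth, config = config),
    class = "pulsed_bundle"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- pipeline_stamp(config)
    write_stamped_csv(half_lives, file.path(out_dir, "half_lives.csv"), stamp)
    write_stamped_csv(fold_changes, file.path(out_dir, "fold_changes.csv"),
                      stamp)
    write_stamped_csv(tibble::tibble(protein_id = excluded),
                      file.path(out_dir, "excluded_saturated.csv"), stamp)
  }
  bundle
}

#' Joint inference of synthesis suppression from both designs
#'
#' Combines a pulsed bundle (apparent H/L changes) with a multiplexed bundle
#' (degradation classification): proteins with H/L reductions beyond 3 control
#' SDs whose degradation is not significantly slowed are attributed to
#' synthesis suppression.
#'
#' @param multiplexed A [run_multiplexed_pipeline()] bundle.
#' @param pulsed A [run_pulsed_pipeline()] bundle.
#' @param out_dir Optional output directory.
#' @return A list of class `joint_bundle`: `suppressed_ids`, `n_candidates`
#'   (proteins beyond the 3-SD reduction with a degradation call),
#'   `n_degradation_affected` (candidates whose degradation was slowed),
#'   `fraction_degradation` and the `control_sd_log2hl` used.
#' @export
run_joint_inference <- function(multiplexed, pulsed, out_dir = NULL) {
  sd0 <- pulsed$control_sd_log2hl
  if (is.na(sd0)) {
    rlang::abort("pulsed bundle lacks a control replicate SD (need >= 2 control replicates)")
  }
  suppressed <- infer_synthesis_suppression(
    pulsed$fold_changes, multiplexed$classification, sd0
  )
  candidates <- pulsed$fold_changes |>
    dplyr::filter(.data$delta_log2_hl < -3 * sd0) |>
    dplyr::inner_join(
      dplyr::select(multiplexed$classification, "protein_id", "class"),
      by = "protein_id"
    )
  n_deg <- sum(stringr::str_starts(candidates$class, "slowed_significant"))
  bundle <- structure(
    list(
      suppressed_ids = suppressed,
      n_candidates = nrow(candidates),
      n_degradation_affected = n_deg,
      fraction_degradation = if (nrow(candidates) > 0) {
        n_deg / nrow(candidates)
      } else {
        NA_real_
      },
      control_sd_log2hl = sd0
    ),
    class = "joint_bundle"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- pipeline_stamp(pulsed$config)
    write_stamped_csv(tibble::tibble(protein_id = suppressed),
                      file.path(out_dir, "synthesis_suppressed.csv"), stamp)
  }
  bundle
}

#' @export
print.multiplexed_bundle <- function(x, ...) {
  cat(sprintf(
    "<multiplexed_bundle> %d proteins classified; t0 SD %.4f; r(measured, expected) = %.3f (n = %d)\n",
    nrow(x$classification), x$variability$sd_log2_t0,
    x$correlation$r, x$correlation$n
  ))
  invisible(x)
}

#' @export
print.pulsed_bundle <- function(x, ...) {
  cat(sprintf(
    "<pulsed_bundle> %d proteins with fold changes (%d saturated excluded); median fold change %.2f\n",
    nrow(x$fold_changes), length(x$excluded),
    stats::median(x$fold_changes$fold_change)
  ))
  invisible(x)
}

#' @export
print.joint_bundle <- function(x, ...) {
  cat(sprintf(
    "<joint_bundle> %d candidates with >3-SD H/L reduction; %d degradation-affected (%.0f%%); %d attributed to synthesis suppression\n",
    x$n_candidates, x$n_degradation_affected,
    100 * x$fraction_degradation, length(x$suppressed_ids)
  ))
  invisible(x)
}
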