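test_that("t = 0 variability estimates SD, threshold and ratio bounds", {
  v0 <- estimate_t0_variability(rep(0, 20))
  expect_equal(v0$sd_log2_t0, 0)
  expect_equal(unname(v0$ratio_bounds), c(1, 1))

  set.seed(4)
  x <- rnorm(500)
  x <- (x - mean(x)) / sd(x) * 0.083 # sample SD exactly 0.083
  v <- estimate_t0_variability(x)
  expect_equal(v$sd_log2_t0, 0.083, tolerance = 1e-12)
  expect_equal(v$threshold_log2, 0.249, tolerance = 1e-12)
  expect_equal(unname(v$ratio_bounds), c(0.841, 1.188), tolerance = 1e-3)
  expect_equal(round(unname(v$ratio_bounds), 2), c(0.84, 1.19))
  expect_equal(prod(v$ratio_bounds), 1, tolerance = 1e-12)

  td <- tidy(v)
  expect_equal(td$threshold_log2, v$threshold_log2)
  expect_error(estimate_t0_variability(rep(0, 5)), "at least 10")
})

test_that("replicate averaging shrinks the t = 0 spread as sampling theory predicts", {
  set.seed(99)
  n_prot <- 1500
  reps <- 5
  per_rep <- matrix(rnorm(n_prot * reps, 0, 0.07), n_prot, reps)
  v <- estimate_t0_variability(rowMeans(per_rep))
  expect_equal(v$sd_log2_t0, 0.07 / sqrt(5), tolerance = 0.1)
})

test_that("welch test matches the closed-form statistic and handles degeneracy", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  res <- welch_test(c(2.1, 2.0, 1.9), c(1.0, 1.1, 0.9))
  expect_lt(res$p_value, 0.001)

  # independent oracle: Welch statistic and Satterthwaite df by hand
  set.seed(2)
  x <- rnorm(5, 1)
  y <- rnorm(4)
  got <- welch_test(x, y)
  se2 <- var(x) / 5 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, df_hand, tolerance = 1e-12)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)

  # swapping groups negates t, preserves p
  swapped <- welch_test(y, x)
  expect_equal(swapped$t, -got$t, tolerance = 1e-12)
  expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)

  # degenerate variances
  both_const_eq <- welch_test(c(1, 1), c(1, 1))
  expect_equal(both_const_eq$p_value, 1)
  both_const_ne <- welch_test(c(2, 2), c(1, 1))
  expect_equal(both_const_ne$p_value, 0)
  expect_true(both_const_ne$degenerate)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("classification applies the rule table and partitions the set", {
  # hand-built proteins hitting each rule branch (threshold 0.2)
  x0 <- c(rep(-1, 5), rep(1, 5))
  v <- estimate_t0_variability(x0 / sd(x0) * 0.2 / 3)
  expect_equal(v$threshold_log2, 0.2, tolerance = 1e-12)
  mk <- function(id, v24, v0 = c(-0.01, 0, 0.01)) {
    tibble::tibble(protein_id = id, time_h = c(0, 24),
                   mean_log2 = c(mean(v0), mean(v24)), n = 3,
                   values = list(v0, v24))
  }
  merged <- dplyr::bind_rows(
    mk("strong", c(0.49, 0.50, 0.51)),   # p small, mean > threshold
    mk("weak", c(0.14, 0.15, 0.16)),     # p small, 0 < mean < threshold
    mk("down", c(-0.49, -0.50, -0.51)),  # p small, mean < 0
    mk("flat", c(-0.01, 0, 0.01))        # no change
  )
  cls <- classify_proteins(merged, v)
  got <- setNames(cls$class, cls$protein_id)
  expect_equal(unname(got["strong"]), "slowed_significant_3sd")
  expect_equal(unname(got["weak"]), "slowed_significant")
  expect_equal(unname(got["down"]), "accelerated_significant")
  expect_equal(unname(got["flat"]), "unaffected")
  expect_equal(nrow(cls), 4) # partition: one class per protein
})

test_that("classification agrees with a brute-force rule reimplementation", {
  cfg <- sim_config(n_proteins = 300, substrate_fraction = 0.1,
                    alpha_substrate = 10, seed = 17)
  prot <- generate_proteome(cfg)
  sim <- simulate_multiplexed(prot, cfg)
  merged <- aggregate_protein_ratios(orient_to_experiment_control(sim$peptides)) |>
    normalize_to_reference(prot$protein_id[prot$is_reference]) |>
    merge_replicates()
  v <- estimate_t0_variability(merged$mean_log2[merged$time_h == 0])
  got <- classify_proteins(merged, v)
  want <- brute_force_classify(merged, v$threshold_log2)
  m <- match(want$protein_id, got$protein_id)
  expect_equal(got$class[m], want$class)
  expect_equal(got$p_value[m], want$p, tolerance = 1e-12)
  expect_equal(got$mean_log2_hm_24h[m], want$mean24, tolerance = 1e-12)
})

test_that("synthesis suppression rule combines both designs", {
  classification <- tibble::tibble(
    protein_id = c("A", "B", "C", "D"),
    mean_log2_hm_24h = c(0.01, 0.5, 0.02, -0.1),
    p_value = c(0.9, 0.001, 0.8, 0.2),
    class = c("unaffected", "slowed_significant_3sd", "trend", "unaffected")
  )
  pulsed <- tibble::tibble(
    protein_id = c("A", "B", "C", "D"),
    delta_log2_hl = c(-1.5, -1.5, -0.1, -2.0)
  )
  got <- infer_synthesis_suppression(pulsed, classification,
                                     control_sd_log2hl = 0.2)
  expect_equal(got, c("A", "D")) # B excluded (degradation), C (small drop)

  expect_warning(
    empty <- infer_synthesis_suppression(
      dplyr::mutate(pulsed, protein_id = paste0("X", protein_id)),
      classification, 0.2
    ),
    "no shared"
  )
  expect_length(empty, 0)
})

test_that("top-fraction selection surfaces large early-responding proteins", {
  set.seed(6)
  n <- 100
  merged <- tibble::tibble(
    protein_id = paste0("P", 1:n),
    time_h = 4,
    mean_log2 = c(rnorm(95, 0, 0.05), rnorm(5, 1, 0.05)),
    n = 5,
    values = replicate(100, numeric(0), simplify = FALSE)
  )
  meta <- tibble::tibble(
    protein_id = paste0("P", 1:n),
    molecular_weight_kda = c(rep(70, 95), rep(280, 5)),
    half_life_h = runif(n, 24, 240)
  )
  res <- top_fraction_analysis(merged, meta, fraction = 0.05, t_h = 4)
  expect_equal(res$n, 5)
  expect_setequal(res$selected$protein_id, paste0("P", 96:100))
  expect_gt(res$mean_mw_selected, res$mean_mw_cohort)

  flat <- dplyr::mutate(meta, molecular_weight_kda = 50)
  res2 <- top_fraction_analysis(merged, flat, fraction = 0.05, t_h = 4)
  expect_equal(res2$mean_mw_selected, res2$mean_mw_cohort)
})

test_that("count summaries tally classes overall and within an annotation", {
  classification <- tibble::tibble(
    protein_id = paste0("P", 1:10),
    mean_log2_hm_24h = 0,
    p_value = 1,
    class = c("slowed_significant", rep("unaffected", 9))
  )
  counts <- summarize_counts(classification)
  expect_equal(counts$n[counts$class == "slowed_significant"], 1)
  expect_equal(counts$pct[counts$class == "slowed_significant"], 10)
  expect_equal(sum(counts$n), 10)

  ann <- summarize_counts(classification, annotated_ids = c("P1", "P2"))
  expect_equal(ann$n_annotated[ann$class == "slowed_significant"], 1)
  expect_equal(ann$pct_annotated[ann$class == "slowed_significant"], 50)

  none <- summarize_counts(classification, annotated_ids = character())
  expect_true(all(none$n_annotated == 0))

  # brute-force tally on a synthetic classification
  set.seed(13)
  cls2 <- tibble::tibble(
    protein_id = paste0("Q", 1:200),
    mean_log2_hm_24h = 0, p_value = 1,
    class = sample(c("slowed_significant_3sd", "slowed_significant", "trend",
                     "unaffected", "accelerated_significant"), 200, TRUE)
  )
  counts2 <- summarize_counts(cls2)
  for (cl in unique(cls2$class)) {
    expect_equal(counts2$n[counts2$class == cl], sum(cls2$class == cl))
  }
})
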