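# Small in-code fixtures shared across test files.

# A peptide record tibble built directly (native columns).
make_records <- function(protein_id, ratios, experiment_id = "exp1",
                         time_h = 24, ratio_type = "H/M",
                         treated_channel = "H") {
  tibble::tibble(
    experiment_id = experiment_id,
    time_h = time_h,
    protein_id = protein_id,
    peptide_id = paste0(protein_id, "_pep", seq_along(ratios)),
    ratio_type = ratio_type,
    ratio = ratios,
    treated_channel = treated_channel
  )
}

# Protein profile rows built directly.
make_profiles <- function(protein_id, log2_ratio, experiment_id = "exp1",
                          time_h = 0, n_peptides = 2, ratio_type = "H/M") {
  tibble::tibble(
    protein_id = protein_id,
    experiment_id = experiment_id,
    time_h = time_h,
    ratio_type = ratio_type,
    log2_ratio = log2_ratio,
    n_peptides = n_peptides
  )
}

# A noiseless, offset-free config for exact-kinetics checks.
noiseless_config <- function(n_proteins = 30, seed = 101, ...) {
  sim_config(
    n_proteins = n_proteins,
    peptide_noise_sd_log2 = 0,
    channel_offset_sd_log2 = 0,
    seed = seed,
    ...
  )
}

# Independent brute-force reimplementation of the classification rules,
# used as the oracle for classify_proteins().
brute_force_classify <- function(merged, threshold_log2, p_sig = 0.05,
                                 p_trend = 0.10) {
  ids <- intersect(
    merged$protein_id[merged$time_h == 0],
    merged$protein_id[merged$time_h == 24]
  )
  out <- data.frame(protein_id = ids, mean24 = NA_real_, p = NA_real_,
                    class = NA_character_)
  for (i in seq_along(ids)) {
    v0 <- merged$values[merged$protein_id == ids[i] & merged$time_h == 0][[1]]
    v24 <- merged$values[merged$protein_id == ids[i] & merged$time_h == 24][[1]]
    m <- mean(v24)
    p <- if (stats::var(v0) == 0 && stats::var(v24) == 0) {
      if (isTRUE(all.equal(mean(v0), mean(v24)))) 1 else 0
    } else {
      stats::t.test(v24, v0)$p.value
    }
    cls <- if (p <= p_sig && m > 0 && m > threshold_log2) {
      "slowed_significant_3sd"
    } else if (p <= p_sig && m > 0) {
      "slowed_significant"
    } else if (p <= p_sig && m < 0) {
      "accelerated_significant"
    } else if (p > p_sig && p <= p_trend && m > 0) {
      "trend"
    } else {
      "unaffected"
    }
    out$mean24[i] <- m
    out$p[i] <- p
    out$class[i] <- cls
  }
  out
}
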