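#' Draw a synthetic proteome with known turnover ground truth
#'
#' Samples `n_proteins` proteins: per-protein half-lives from a lognormal
#' distribution (median and log-sigma from the config), peptide multiplicities,
#' abundances and molecular weights, and designates a substrate subset
#' (degradation slowed by `alpha_substrate` under inhibitor) and an
#' independently drawn suppressed subset (synthesis scaled by
#' `beta_suppressed`). The first `n_reference` proteins are the designated
#' long-lived normalization references (`REF1`, `REF2`, ...): abundant,
#' half-lives uniform between 9 and 20 days, alpha = beta = 1.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per protein and columns `protein_id`,
#'   `half_life_h`, `alpha`, `beta`, `abundance`, `n_peptides`,
#'   `molecular_weight_kda`, `is_reference`.
#' @examples
#' truth <- generate_proteome(sim_config(n_proteins = 20, seed = 1))
#' truth
#' @export
generate_proteome <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_proteins
  if (n == 0) {
    return(tibble::tibble(
      protein_id = character(), half_life_h = numeric(), alpha = numeric(),
      beta = numeric(), abundance = numeric(), n_peptides = integer(),
      molecular_weight_kda = numeric(), is_reference = logical()
    ))
  }
  n_ref <- min(config$n_reference, n)
  n_bio <- n - n_ref
  withr::with_seed(config$seed, {
    ref <- tibble::tibble(
      protein_id = paste0("REF", seq_len(n_ref)),
      half_life_h = stats::runif(n_ref, 9, 20) * 24,
      alpha = 1,
      beta = 1,
      abundance = stats::rlnorm(n_ref, meanlog = log(5e4), sdlog = 0.3),
      n_peptides = 6L + stats::rpois(n_ref, 4),
      molecular_weight_kda = stats::rlnorm(n_ref, log(90), 0.5),
      is_reference = TRUE
    )
    bio <- tibble::tibble(
      protein_id = sprintf("P%05d", seq_len(n_bio)),
      half_life_h = stats::rlnorm(
        n_bio,
        meanlog = log(config$half_life_lognormal_median_d * 24),
        sdlog = config$half_life_lognormal_sigma
      ),
      alpha = 1,
      beta = 1,
      abundance = stats::rlnorm(n_bio, meanlog = log(1e4), sdlog = 1),
      n_peptides = 1L + stats::rpois(n_bio, 2.5),
      molecular_weight_kda = stats::rlnorm(n_bio, log(60), 0.6),
      is_reference = FALSE
    )
    # substrate and suppressed sets are independent draws over non-reference rows
    n_sub <- round(config$substrate_fraction * n_bio)
    n_sup <- round(config$suppressed_fraction * n_bio)
    sub_idx <- sample.int(n_bio, n_sub)
    sup_idx <- sample.int(n_bio, n_sup)
    bio$alpha[sub_idx] <- config$alpha_substrate
    bio$beta[sup_idx] <- config$beta_suppressed
    dplyr::bind_rows(ref, bio)
  })
}

#' Noiseless expected ratios under the two labeling designs
#'
#' `multiplexed_true_log2()` gives the log2(H/M) ratio of the residual
#' pre-labeled pools when the treated channel's degradation time constant is
#' increased by `alpha`: both channels decay exponentially, so
#' log2(H/M) = t(alpha - 1) / (alpha * t_half) — the pre-label saturation
#' cancels. `pulsed_true_ratio()` gives the heavy/light ratio in the pulsed
#' design, where newly synthesized protein incorporates heavy amino acids with
#' probability `f_heavy` while synthesis runs at `beta` times the baseline rate
#' (baseline = steady state, synthesis balancing first-order degradation) and
#' degradation is slowed by `alpha`.
#'
#' @param t_h Time since inhibitor addition / label switch, hours.
#' @param half_life_h Baseline protein half-life, hours.
#' @param alpha Degradation-slowing factor (>= 1).
#' @param beta Synthesis-rate multiplier in \[0, 1\].
#' @param f_heavy Fraction of free lysine/arginine that is heavy during the
#'   pulse (5:1 excess gives 5/6).
#' @return A numeric vector (vectorized over all arguments).
#' @examples
#' multiplexed_true_log2(24, 5 * 24, alpha = 10) # 0.18
#' pulsed_true_ratio(24, 24, f_heavy = 5 / 6)    # 5/7
#' @export
multiplexed_true_log2 <- function(t_h, half_life_h, alpha) {
  stopifnot(all(t_h >= 0), all(half_life_h > 0), all(alpha >= 1))
  t_h * (alpha - 1) / (alpha * half_life_h)
}

#' @rdname multiplexed_true_log2
#' @export
pulsed_true_ratio <- function(t_h, half_life_h, alpha = 1, beta = 1,
                              f_heavy = 5 / 6) {
  stopifnot(all(t_h >= 0), all(half_life_h > 0), all(alpha >= 1),
            all(beta >= 0), all(beta <= 1), all(f_heavy > 0), all(f_heavy <= 1))
  k <- log(2) / half_life_h       # baseline degradation rate
  kp <- k / alpha                 # effective rate under treatment
  x <- exp(-kp * t_h)
  # synthesis s = L0 * k at baseline steady state; amounts below are per L0
  gain <- alpha * beta * (1 - x)  # s * beta / kp * (1 - x), per L0
  heavy <- f_heavy * gain
  light <- x + (1 - f_heavy) * gain
  heavy / light
}

#' Simulate a multiplexed dynamic SILAC experiment
#'
#' Two pre-labeled pools (heavy = treated, medium = control) are chased with
#' light media; the residual labeled pools decay exponentially, the treated
#' channel `alpha`-fold slower for substrate proteins. Emits one peptide-level
#' H/M ratio per protein, peptide, experiment and time point, carrying a
#' shared per-experiment-and-time mixing offset plus independent peptide noise
#' (both additive in log2). With zero noise and offset the log2 ratio equals
#' `multiplexed_true_log2()` exactly.
#'
#' @param proteome Tibble from [generate_proteome()].
#' @param config The [sim_config()] used to generate it.
#' @param treated_channels Character vector (recycled to `n_replicates`) giving
#'   the inhibitor-treated label per experiment, `"H"` or `"M"`; label swaps
#'   exercise the orientation step.
#' @return A list of class `silac_sim` with elements `peptides` (native
#'   peptide-table tibble) and `truth` (the proteome).
#' @export
simulate_multiplexed <- function(proteome, config, treated_channels = "H") {
  config <- validate_sim_config(config)
  if (nrow(proteome) == 0) {
    rlang::abort("proteome is empty")
  }
  treated <- rep_len(treated_channels, config$n_replicates)
  stopifnot(all(treated %in% c("H", "M")))
  experiments <- sprintf("mux%d", seq_len(config$n_replicates))

  grid <- tidyr::expand_grid(
    experiment_id = experiments,
    time_h = config$time_points_h
  )
  peptides <- withr::with_seed(config$seed + 1L, {
    grid$offset <- stats::rnorm(nrow(grid), 0, config$channel_offset_sd_log2)
    per_prot <- proteome |>
      dplyr::select("protein_id", "half_life_h", "alpha", "n_peptides") |>
      tidyr::uncount(weights = .data$n_peptides, .id = "pep") |>
      dplyr::mutate(peptide_id = sprintf("%s_pep%d", .data$protein_id, .data$pep))
    out <- tidyr::expand_grid(grid, pep_row = seq_len(nrow(per_prot)))
    out <- dplyr::bind_cols(out, per_prot[out$pep_row, ])
    true_log2 <- multiplexed_true_log2(out$time_h, out$half_life_h, out$alpha)
    sgn <- ifelse(treated[match(out$experiment_id, experiments)] == "H", 1, -1)
    obs <- sgn * true_log2 + out$offset +
      stats::rnorm(nrow(out), 0, config$peptide_noise_sd_log2)
    out$ratio <- 2^obs
    out$treated_channel <- treated[match(out$experiment_id, experiments)]
    if (config$detection_prob < 1) {
      out <- out[stats::runif(nrow(out)) < config$detection_prob, ]
    }
    out |>
      dplyr::transmute(
        experiment_id = .data$experiment_id,
        time_h = .data$time_h,
        protein_id = .data$protein_id,
        peptide_id = .data$peptide_id,
        ratio_type = "H/M",
        ratio = .data$ratio,
        treated_channel = .data$treated_channel
      )
  })
  structure(list(peptides = peptides, truth = proteome), class = "silac_sim")
}

#' Simulate a pulsed SILAC experiment (heavy pulse, treated vs control)
#'
#' Heavy amino acids are added in `heavy_excess`-fold excess at t = 0; newly
#' synthesized protein is heavy with probability `f_heavy =
#' heavy_excess / (heavy_excess + 1)`. In the treated condition degradation is
#' slowed `alpha`-fold and synthesis scaled by `beta`; the control has
#' alpha = beta = 1. Emits peptide-level H/L ratios with multiplicative noise
#' for each condition, experiment and positive time point. Proteins whose true
#' heavy signal is zero (beta = 0) are emitted as absent rows, mirroring
#' undetectable heavy peptides.
#'
#' @inheritParams simulate_multiplexed
#' @return A list of class `silac_sim` with elements `peptides` and `truth`.
#'   Condition is encoded in `experiment_id` as `pulse<i>.control` /
#'   `pulse<i>.treated`; `ratio_type` is `"H/L"`.
#' @export
simulate_pulsed <- function(proteome, config) {
  config <- validate_sim_config(config)
  if (nrow(proteome) == 0) {
    rlang::abort("proteome is empty")
  }
  f_heavy <- config$heavy_excess / (config$heavy_excess + 1)
  times <- config$time_points_h[config$time_points_h > 0]
  if (length(times) == 0) {
    rlang::abort("pulsed design needs at least one positive time point")
  }
  peptides <- withr::with_seed(config$seed + 2L, {
    per_prot <- proteome |>
      dplyr::select("protein_id", "half_life_h", "alpha", "beta", "n_peptides") |>
      tidyr::uncount(weights = .data$n_peptides, .id = "pep") |>
      dplyr::mutate(peptide_id = sprintf("%s_pep%d", .data$protein_id, .data$pep))
    out <- tidyr::expand_grid(
      rep = seq_len(config$n_replicates_pulsed),
      condition = c("control", "treated"),
      time_h = times,
      pep_row = seq_len(nrow(per_prot))
    )
    out <- dplyr::bind_cols(out, per_prot[out$pep_row, ])
    trt <- out$condition == "treated"
    true_ratio <- pulsed_true_ratio(
      out$time_h, out$half_life_h,
      alpha = ifelse(trt, out$alpha, 1),
      beta = ifelse(trt, out$beta, 1),
      f_heavy = f_heavy
    )
    noise <- stats::rnorm(nrow(out), 0, config$peptide_noise_sd_log2)
    out$ratio <- true_ratio * 2^noise
    if (config$detection_prob < 1) {
      out <- out[stats::runif(nrow(out)) < config$detection_prob, ]
    }
    out <- out[out$ratio > 0, ] # beta = 0 proteins have no heavy peptides
    out |>
      dplyr::transmute(
        experiment_id = sprintf("pulse%d.%s", .data$rep, .data$condition),
        time_h = .data$time_h,
        protein_id = .data$protein_id,
        peptide_id = .data$peptide_id,
        ratio_type = "H/L",
        ratio = .data$ratio,
        treated_channel = "H"
      )
  })
  structure(list(peptides = peptides, truth = proteome), class = "silac_sim")
}

#' Write the ground-truth table of a simulation to CSV
#'
#' @param truth Proteome tibble from [generate_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  if (nrow(truth) == 0) {
    rlang::abort("ground truth is empty; nothing to write")
  }
  truth |>
    dplyr::select("protein_id", "half_life_h", "alpha", "beta", "abundance",
                  "n_peptides", "molecular_weight_kda") |>
    readr::write_csv(path)
  invisible(path)
}

#' @export
print.silac_sim <- function(x, ...) {
  cat(sprintf("<silac_sim> %d peptide-level measurements, %d proteins\n",
              nrow(x$peptides), nrow(x$truth)))
  invisible(x)
}
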