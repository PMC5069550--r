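test_that("native tables read back validated records and drop bad ratios", {
  recs <- make_records("P1", c(1.5, 2, 0.8, 1.1, 0.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(recs, path)
  back <- read_peptide_table(path, "native")
  expect_equal(nrow(back), 5)
  expect_equal(back$ratio, recs$ratio)

  recs$ratio[2] <- 0
  write_peptide_table(recs, path)
  expect_message(back <- read_peptide_table(path, "native"), "dropped 1")
  expect_equal(nrow(back), 4)
  expect_equal(attr(back, "n_dropped"), 1)

  raw <- readLines(path)
  raw[3] <- sub("\t0\t", "\tnot_a_number\t", raw[3], fixed = TRUE)
  writeLines(raw, path)
  expect_error(read_peptide_table(path, "native"), "line\\(s\\): 3")

  expect_error(read_peptide_table(path, "maxquant"), "must be one of")
})

test_that("proteingroups dialect maps columns and takes first accession", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Protein IDs\tRatio H/M\tRatio H/M count",
    "P10;P11\t1.25\t4",
    "P20\t0.8\t2",
    "P30\t2.0\t3"
  ), path)
  recs <- read_peptide_table(path, "proteingroups", time_h = 10)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$protein_id, c("P10", "P20", "P30"))
  expect_equal(recs$ratio, c(1.25, 0.8, 2.0))
  expect_true(all(recs$ratio_type == "H/M"))
  expect_true(all(recs$time_h == 10))

  expect_error(
    read_peptide_table(path, "proteingroups",
                       column_map = c(ratio = "Ratio M/L")),
    "absent"
  )
})

test_that("orientation maps every record to treated/control", {
  recs <- make_records("P1", c(1.5, 2.0), treated_channel = c("H", "M"))
  out <- orient_to_experiment_control(recs)
  expect_equal(out$ratio, c(1.5, 0.5))
  expect_true(all(out$treated_channel == "H"))

  recs$treated_channel[1] <- NA
  expect_error(orient_to_experiment_control(recs), "treated_channel")
})

test_that("label-swap experiments recover the same effect after orientation", {
  cfg <- noiseless_config(n_proteins = 12, n_reference = 0,
                          substrate_fraction = 1, alpha_substrate = 10,
                          n_replicates = 2)
  prot <- generate_proteome(cfg)
  sim <- simulate_multiplexed(prot, cfg, treated_channels = c("H", "M"))
  oriented <- orient_to_experiment_control(sim$peptides)
  prof <- aggregate_protein_ratios(oriented, min_peptides = 1)
  at24 <- dplyr::inner_join(prof[prof$time_h == 24, ], prot, by = "protein_id")
  expected <- multiplexed_true_log2(24, at24$half_life_h, 10)
  expect_equal(at24$log2_ratio, expected, tolerance = 1e-12)
  # both orientations agree protein by protein
  wide <- tidyr::pivot_wider(at24[, c("protein_id", "experiment_id", "log2_ratio")],
                             names_from = "experiment_id",
                             values_from = "log2_ratio")
  expect_equal(wide$mux1, wide$mux2, tolerance = 1e-12)
})

test_that("aggregation pools peptides as a geometric mean with a floor", {
  prof <- aggregate_protein_ratios(make_records("P1", c(2, 2)))
  expect_equal(prof$log2_ratio, 1)
  expect_equal(prof$n_peptides, 2)

  prof2 <- aggregate_protein_ratios(make_records("P1", c(1, 4)))
  expect_equal(prof2$log2_ratio, 1) # geometric mean 2

  expect_equal(nrow(aggregate_protein_ratios(make_records("P1", 3))), 0)
  expect_equal(aggregate_protein_ratios(make_records("P1", 3),
                                        min_peptides = 1)$n_peptides, 1)

  # permutation invariance, and commuting with orientation
  recs <- make_records("P1", c(0.5, 1.2, 3.1), treated_channel = "M")
  shuffled <- recs[c(3, 1, 2), ]
  expect_equal(
    aggregate_protein_ratios(recs, 1)$log2_ratio,
    aggregate_protein_ratios(shuffled, 1)$log2_ratio
  )
  a_then_o <- aggregate_protein_ratios(orient_to_experiment_control(recs), 1)
  o_then_a <- aggregate_protein_ratios(recs, 1)
  expect_equal(a_then_o$log2_ratio, -o_then_a$log2_ratio, tolerance = 1e-12)
})

test_that("completeness filter matches a brute-force scan", {
  design <- tibble::tibble(
    experiment_id = c("mux1", "mux2", "mux3", "mux4", "mux5"),
    group = c("lacta", "lacta", "lacta", "epox", "epox")
  )
  rule <- list(lacta = list(n_samples = 12, min_present = 11),
               epox = list(n_samples = 8, min_present = 7))
  times <- c(0, 4, 10, 24)

  # protein fully present; protein missing 2 lacta samples; protein missing
  # 1 lacta + 1 epox sample (still passes); random patterns
  set.seed(71)
  samples <- tidyr::expand_grid(experiment_id = design$experiment_id,
                                time_h = times)
  build <- function(id, present) {
    make_profiles(id, 0, experiment_id = samples$experiment_id[present],
                  time_h = samples$time_h[present])
  }
  profs <- dplyr::bind_rows(lapply(1:30, function(i) {
    n_absent <- sample(0:4, 1)
    present <- !seq_len(20) %in% sample(20, n_absent)
    build(sprintf("P%02d", i), present)
  }))
  got <- filter_complete(profs, design, rule)

  # brute force: count qualifying samples per group, protein by protein
  want <- character()
  for (id in unique(profs$protein_id)) {
    sub <- profs[profs$protein_id == id, ]
    ok <- TRUE
    for (g in names(rule)) {
      exps <- design$experiment_id[design$group == g]
      n <- nrow(unique(sub[sub$experiment_id %in% exps,
                           c("experiment_id", "time_h")]))
      if (n < rule[[g]]$min_present) ok <- FALSE
    }
    if (ok) want <- c(want, id)
  }
  expect_setequal(got, sort(want))

  # rule boundary: 10/12 lactacystin samples is excluded
  ten <- build("PX", c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 8)))
  expect_false("PX" %in% filter_complete(ten, design, rule))
  eleven <- build("PY", c(rep(TRUE, 11), FALSE, rep(TRUE, 8)))
  expect_true("PY" %in% filter_complete(eleven, design, rule))

  expect_error(filter_complete(profs, design, list(mg132 = list(min_present = 1))),
               "unknown experiment group")
})

test_that("reference normalization removes offsets and is idempotent", {
  refs <- paste0("REF", 1:4)
  profs <- dplyr::bind_rows(
    make_profiles(refs, c(0.05, -0.03, 0.02, 0.01)),
    make_profiles(c("P1", "P2"), c(0.4, -0.2))
  )
  shifted <- dplyr::mutate(profs, log2_ratio = log2_ratio + 0.3)
  norm <- normalize_to_reference(shifted, refs)
  ref_mean <- mean(norm$log2_ratio[norm$protein_id %in% refs])
  expect_lt(abs(ref_mean), 1e-12)
  # the injected +0.3 offset is gone: non-reference values match the
  # unshifted normalization
  base <- normalize_to_reference(profs, refs)
  expect_equal(norm$log2_ratio, base$log2_ratio, tolerance = 1e-12)
  # idempotent
  again <- normalize_to_reference(norm, refs)
  expect_equal(again$log2_ratio, norm$log2_ratio, tolerance = 1e-12)

  expect_error(normalize_to_reference(profs, refs, min_ref_detected = 5),
               "exp1@0h")
})

test_that("replicate merging preserves values and means", {
  profs <- make_profiles("P1", c(0.1, 0.2, 0.3),
                         experiment_id = c("e1", "e2", "e3"))
  merged <- merge_replicates(profs)
  expect_equal(merged$mean_log2, 0.2)
  expect_equal(merged$n, 3)
  expect_equal(sort(merged$values[[1]]), c(0.1, 0.2, 0.3))

  single <- merge_replicates(make_profiles("P1", 0.7))
  expect_equal(single$mean_log2, 0.7)
  expect_equal(single$n, 1)

  # five-replicate fixture equals brute-force recomputation
  set.seed(8)
  vals <- rnorm(5)
  five <- merge_replicates(make_profiles("P9", vals,
                                         experiment_id = paste0("e", 1:5)))
  expect_equal(five$mean_log2, mean(vals))
})

test_that("t = 0 population mean is near zero after normalization", {
  cfg <- sim_config(n_proteins = 400, channel_offset_sd_log2 = 0.2, seed = 31)
  prot <- generate_proteome(cfg)
  sim <- simulate_multiplexed(prot, cfg)
  prof <- aggregate_protein_ratios(orient_to_experiment_control(sim$peptides)) |>
    normalize_to_reference(prot$protein_id[prot$is_reference])
  merged <- merge_replicates(prof)
  t0 <- merged$mean_log2[merged$time_h == 0]
  se <- sd(t0) / sqrt(length(t0))
  expect_lt(abs(mean(t0)), 3 * se)
})
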