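#' Read a peptide-level SILAC ratio table
#'
#' Two dialects are supported. `"native"` is a TSV with header
#' `experiment_id time_h protein_id peptide_id ratio_type ratio
#' treated_channel`. `"proteingroups"` reads a MaxQuant-proteinGroups-style
#' TSV through a configurable column map; protein groups separated by `;` are
#' reduced to their first accession and the software's own ratio is taken as
#' given (one pseudo-peptide per row). Rows with missing or nonpositive ratios
#' are dropped with a message giving the count; malformed numeric fields abort
#' with their line numbers.
#'
#' @param path Path to the TSV file.
#' @param dialect `"native"` or `"proteingroups"`.
#' @param column_map Named character vector mapping record fields to file
#'   columns (proteingroups dialect only). Defaults:
#'   `protein_id = "Protein IDs"`, `ratio = "Ratio H/M"`,
#'   `n_peptides = "Ratio H/M count"`.
#' @param experiment_id,time_h,ratio_type,treated_channel Values to stamp on
#'   proteingroups rows, which do not carry them.
#' @return A tibble of peptide ratio records (native columns), with attribute
#'   `n_dropped` = number of rows removed for missing/nonpositive ratios.
#' @export
read_peptide_table <- function(path, dialect = c("native", "proteingroups"),
                               column_map = NULL,
                               experiment_id = "exp1", time_h = 24,
                               ratio_type = "H/M", treated_channel = "H") {
  dialect <- rlang::arg_match(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  if (dialect == "native") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
    needed <- c("experiment_id", "time_h", "protein_id", "peptide_id",
                "ratio_type", "ratio", "treated_channel")
    missing <- setdiff(needed, names(raw))
    if (length(missing) > 0) {
      rlang::abort(sprintf("native table lacks column(s): %s",
                           paste(missing, collapse = ", ")))
    }
    num <- suppressWarnings(list(
      time_h = as.numeric(raw$time_h),
      ratio = as.numeric(raw$ratio)
    ))
    bad <- which((is.na(num$time_h) & !is.na(raw$time_h)) |
                   (is.na(num$ratio) & !is.na(raw$ratio) & raw$ratio != "NA"))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "malformed numeric value(s) at data line(s): %s",
        paste(utils::head(bad + 1L, 20), collapse = ", ")
      ))
    }
    rec <- tibble::tibble(
      experiment_id = raw$experiment_id,
      time_h = num$time_h,
      protein_id = raw$protein_id,
      peptide_id = raw$peptide_id,
      ratio_type = raw$ratio_type,
      ratio = num$ratio,
      treated_channel = raw$treated_channel
    )
  } else {
    map <- c(protein_id = "Protein IDs", ratio = "Ratio H/M",
             n_peptides = "Ratio H/M count")
    if (!is.null(column_map)) {
      map[names(column_map)] <- column_map
    }
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
    missing <- setdiff(unname(map[c("protein_id", "ratio")]), names(raw))
    if (length(missing) > 0) {
      rlang::abort(sprintf("mapped column(s) absent from file: %s",
                           paste(missing, collapse = ", ")))
    }
    ratio_raw <- raw[[map[["ratio"]]]]
    ratio <- suppressWarnings(as.numeric(ratio_raw))
    bad <- which(is.na(ratio) & !is.na(ratio_raw) & ratio_raw != "NA" &
                   nzchar(ratio_raw))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "malformed numeric value(s) at data line(s): %s",
        paste(utils::head(bad + 1L, 20), collapse = ", ")
      ))
    }
    rec <- tibble::tibble(
      experiment_id = experiment_id,
      time_h = time_h,
      protein_id = stringr::str_split_i(raw[[map[["protein_id"]]]], ";", 1),
      peptide_id = sprintf("pg_row%d", seq_len(nrow(raw))),
      ratio_type = ratio_type,
      ratio = ratio,
      treated_channel = treated_channel
    )
  }
  keep <- !is.na(rec$ratio) & rec$ratio > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    rlang::inform(sprintf("dropped %d row(s) with missing or nonpositive ratios",
                          n_dropped))
  }
  rec <- rec[keep, ]
  bad_type <- setdiff(unique(rec$ratio_type), c("H/L", "M/L", "H/M"))
  if (length(bad_type) > 0) {
    rlang::abort(sprintf("unknown ratio_type value(s): %s",
                         paste(bad_type, collapse = ", ")))
  }
  attr(rec, "n_dropped") <- n_dropped
  rec
}

#' Write a peptide table in the native TSV dialect
#'
#' @param records Peptide record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Orient H/M ratios to a uniform treated/control convention
#'
#' In label-swap experiments the inhibitor-treated pool may carry the medium
#' label, in which case the measured H/M ratio is control/treated. Inverting
#' those ratios makes every emitted ratio treated/control, after which all
#' records are relabeled `"H/M"` with `treated_channel = "H"`.
#'
#' @param records Peptide record tibble.
#' @return The oriented tibble.
#' @export
orient_to_experiment_control <- function(records) {
  hm <- records$ratio_type == "H/M"
  if (any(hm & (is.na(records$treated_channel) |
                  !records$treated_channel %in% c("H", "M")))) {
    rlang::abort("H/M record(s) lack a valid treated_channel")
  }
  flip <- hm & records$treated_channel == "M"
  records$ratio[flip] <- 1 / records$ratio[flip]
  records$treated_channel[hm] <- "H"
  records
}

#' Aggregate peptide ratios to protein-level log2 profiles
#'
#' Within each protein x experiment x time x ratio-type group the protein
#' log2 ratio is the arithmetic mean of the peptide log2 ratios (the geometric
#' mean of the ratios); groups with fewer than `min_peptides` distinct
#' peptides emit no profile.
#'
#' @param records Peptide record tibble.
#' @param min_peptides Minimum distinct peptides per group (default 2).
#' @return A tibble with columns `protein_id`, `experiment_id`, `time_h`,
#'   `ratio_type`, `log2_ratio`, `n_peptides`.
#' @export
aggregate_protein_ratios <- function(records, min_peptides = 2) {
  stopifnot(min_peptides >= 1)
  records |>
    dplyr::group_by(.data$protein_id, .data$experiment_id, .data$time_h,
                    .data$ratio_type) |>
    dplyr::summarise(
      log2_ratio = mean(log2(.data$ratio)),
      n_peptides = dplyr::n_distinct(.data$peptide_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_peptides >= min_peptides)
}

#' Filter proteins by per-group sample completeness
#'
#' Reproduces stringent-list selection: a protein is retained only if, within
#' every experiment group, it has a qualifying profile (i.e. one that survived
#' peptide-count aggregation) in at least `min_present` of that group's
#' experiment x time samples.
#'
#' @param profiles Protein profile tibble from [aggregate_protein_ratios()].
#' @param design Tibble with columns `experiment_id`, `group` assigning each
#'   experiment to an inhibitor group.
#' @param rule Named list, one entry per group, each a list/vector with
#'   elements `n_samples` (expected samples in the group) and `min_present`.
#' @return Character vector of retained protein ids (sorted).
#' @export
filter_complete <- function(profiles, design, rule) {
  unknown <- setdiff(names(rule), unique(design$group))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("rule references unknown experiment group(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  counts <- profiles |>
    dplyr::inner_join(design, by = "experiment_id") |>
    dplyr::distinct(.data$protein_id, .data$group, .data$experiment_id,
                    .data$time_h) |>
    dplyr::count(.data$protein_id, .data$group, name = "n_present")
  grid <- tidyr::expand_grid(
    protein_id = unique(counts$protein_id),
    group = names(rule)
  )
  keep <- grid |>
    dplyr::left_join(counts, by = c("protein_id", "group")) |>
    dplyr::mutate(
      n_present = dplyr::coalesce(.data$n_present, 0L),
      min_present = purrr::map_dbl(
        .data$group, function(g) as.numeric(rule[[g]][["min_present"]])
      )
    ) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(ok = all(.data$n_present >= .data$min_present)) |>
    dplyr::filter(.data$ok)
  sort(keep$protein_id)
}

#' Normalize profiles to a long-lived reference protein set
#'
#' Within each experiment x time point, the mean log2 ratio of the detected
#' reference proteins is subtracted from every profile, removing channel
#' mixing offsets. Errors if fewer than `min_ref_detected` reference proteins
#' are present in any sample. Idempotent: the reference mean is exactly 0
#' afterwards.
#'
#' @param profiles Protein profile tibble.
#' @param reference Character vector of reference protein ids, or a tibble
#'   with a `protein_id` column.
#' @param min_ref_detected Minimum reference proteins required per sample.
#' @return The normalized profile tibble.
#' @export
normalize_to_reference <- function(profiles, reference, min_ref_detected = 4) {
  ref_ids <- if (is.data.frame(reference)) reference$protein_id else reference
  if (length(ref_ids) == 0) {
    rlang::abort("reference set is empty")
  }
  out <- profiles |>
    dplyr::group_by(.data$experiment_id, .data$time_h) |>
    dplyr::mutate(
      .n_ref = sum(.data$protein_id %in% ref_ids),
      .ref_mean = mean(.data$log2_ratio[.data$protein_id %in% ref_ids])
    ) |>
    dplyr::ungroup()
  short <- out |>
    dplyr::distinct(.data$experiment_id, .data$time_h, .data$.n_ref) |>
    dplyr::filter(.data$.n_ref < min_ref_detected)
  if (nrow(short) > 0) {
    rlang::abort(sprintf(
      "fewer than %d reference proteins detected in sample(s): %s",
      min_ref_detected,
      paste(sprintf("%s@%gh (%d)", short$experiment_id, short$time_h,
                    short$.n_ref), collapse = ", ")
    ))
  }
  out |>
    dplyr::mutate(log2_ratio = .data$log2_ratio - .data$.ref_mean) |>
    dplyr::select(-".n_ref", -".ref_mean")
}

#' Merge replicate experiments into per-protein per-time summaries
#'
#' @param profiles Normalized profile tibble.
#' @return A tibble with one row per protein x time point: `mean_log2`
#'   (mean across experiments), `n` (number of experiments), and `values`
#'   (list-column of the per-experiment log2 values, kept for Welch testing).
#' @export
merge_replicates <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$protein_id, .data$time_h) |>
    dplyr::summarise(
      mean_log2 = mean(.data$log2_ratio),
      n = dplyr::n(),
      values = list(.data$log2_ratio),
      .groups = "drop"
    )
}
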