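# Candidate screening cascade: CSF-detected circRNAs, minus the normal-brain
# exclusion list, intersected with circRNAs recurring in tumor tissue of at
# least min_patients distinct patients; then per-patient detection burden
# over the candidates, dichotomized at the top-quantile nearest-rank cutoff
# (deficient: burden <= cutoff, abundant: burden > cutoff).

#' Remove junctions on a normal-brain exclusion list
#'
#' Matching is by exact junction ID by default; `tolerance_nt` enables a
#' coordinate-tolerance mode (same chromosome and strand, both boundaries
#' within the tolerance) for lists produced by other pipelines whose
#' boundaries may jitter.
#'
#' @param junction_ids Character vector of junction IDs.
#' @param exclusion Character vector of junction IDs to exclude.
#' @param tolerance_nt Maximum boundary offset for a match (default 0,
#'   exact ID matching).
#' @return Set difference (order preserved); idempotent.
#' @export
exclude_brain_list <- function(junction_ids, exclusion, tolerance_nt = 0L) {
  if (!length(exclusion)) return(junction_ids)
  ex <- parse_junction_id(exclusion)   # validates IDs
  if (tolerance_nt == 0L) {
    return(junction_ids[!(junction_ids %in% exclusion)])
  }
  jx <- parse_junction_id(junction_ids)
  hit <- vapply(seq_len(nrow(jx)), function(i) {
    any(ex$chrom == jx$chrom[i] & ex$strand == jx$strand[i] &
          abs(ex$start - jx$start[i]) <= tolerance_nt &
          abs(ex$end - jx$end[i]) <= tolerance_nt)
  }, logical(1))
  junction_ids[!hit]
}

#' Read an exclusion list from TSV (first column junction_id)
#'
#' @param path File path.
#' @return Character vector of junction IDs (validated).
#' @export
read_exclusion_list <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  ok <- grepl("^[^:]+:[0-9]+\\|[0-9]+:[+-]$", ids)
  if (!all(ok)) {
    stop("malformed junction ID at line ", which(!ok)[1] + 1L, ": ",
         ids[!ok][1])
  }
  ids
}

#' Keep circRNAs detected in tumor tissue of enough distinct patients
#'
#' Patients with several tissue samples count once.
#'
#' @param counts Junctions x samples count matrix.
#' @param samples Sample sheet (`sample_id`, `patient_id`, `compartment`).
#' @param min_patients Minimum number of distinct tissue-positive patients.
#' @return Character vector of junction IDs passing the filter.
#' @export
tumor_recurrence_filter <- function(counts, samples, min_patients = 2L) {
  tissue <- samples[samples$compartment == "tissue", , drop = FALSE]
  if (nrow(tissue) == 0L) stop("no tissue samples in cohort")
  det <- counts[, tissue$sample_id, drop = FALSE] > 0
  n_pat <- apply(det, 1L, function(d) length(unique(tissue$patient_id[d])))
  rownames(counts)[n_pat >= min_patients]
}

#' Run the full candidate screening cascade
#'
#' @param csf_counts Junctions x CSF-sample count matrix.
#' @param tissue_counts Junctions x tissue-sample count matrix.
#' @param samples Sample sheet covering both matrices.
#' @param exclusion Character vector of normal-brain junction IDs.
#' @param min_patients Tumor-recurrence threshold (default 2).
#' @param quantile Top fraction defining the abundant group (default 0.25).
#' @param cutoff Optional integer overriding the quantile-derived cutoff.
#' @return A `screen_report` list: stage counts (`n_csf_total`,
#'   `n_after_brain_exclusion`, `n_after_tumor_recurrence`), `candidates`
#'   (lexicographic), `per_patient_burden`, `cutoff`, `groups`, `degenerate`.
#' @export
run_cascade <- function(csf_counts, tissue_counts, samples, exclusion,
                        min_patients = 2L, quantile = 0.25, cutoff = NULL) {
  csf_detected <- rownames(csf_counts)[rowSums(csf_counts > 0) > 0]
  after_excl <- exclude_brain_list(csf_detected, exclusion)
  recurrent <- tumor_recurrence_filter(tissue_counts, samples,
                                       min_patients = min_patients)
  candidates <- sort(intersect(after_excl, recurrent))

  csf_samples <- samples[samples$compartment == "csf" &
                           samples$sample_id %in% colnames(csf_counts), ,
                         drop = FALSE]
  burden <- species_count(csf_counts[, csf_samples$sample_id, drop = FALSE],
                          subset = candidates)
  names(burden) <- csf_samples$patient_id[
    match(names(burden), csf_samples$sample_id)]

  dich <- if (length(burden) >= 2L) {
    dichotomize_burden(burden, quantile = quantile, cutoff = cutoff)
  } else {
    list(cutoff = NA_integer_, groups = setNames(character(0), character(0)),
         degenerate = TRUE)
  }
  structure(list(
    n_csf_total = length(csf_detected),
    n_after_brain_exclusion = length(after_excl),
    n_after_tumor_recurrence = length(candidates),
    candidates = candidates,
    per_patient_burden = burden,
    cutoff = dich$cutoff,
    groups = dich$groups,
    degenerate = dich$degenerate
  ), class = "screen_report")
}

#' Dichotomize per-patient candidate burden at a top-quantile cutoff
#'
#' The cutoff is the nearest-rank `(1 - quantile)` empirical quantile of the
#' burdens (the `ceiling((1 - quantile) * n)`-th order statistic); patients
#' with burden at or below the cutoff are "deficient", above it "abundant".
#'
#' @param burden Named integer vector (patient -> detected candidates).
#' @param quantile Top fraction in (0, 1) (default 0.25).
#' @param cutoff Optional integer overriding the quantile rule.
#' @return List with `cutoff`, `groups` (named character vector), and
#'   `degenerate` (TRUE when a single group results).
#' @export
dichotomize_burden <- function(burden, quantile = 0.25, cutoff = NULL) {
  stopifnot(length(burden) >= 2L, quantile > 0, quantile < 1)
  if (is.null(cutoff)) {
    k <- ceiling((1 - quantile) * length(burden))
    cutoff <- sort(burden)[k]
  }
  groups <- ifelse(burden <= cutoff, "deficient", "abundant")
  names(groups) <- names(burden)
  degenerate <- length(unique(groups)) < 2L
  list(cutoff = as.integer(cutoff), groups = groups, degenerate = degenerate)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screening cascade report\n")
  cat("  CSF-detected circRNAs:      ", x$n_csf_total, "\n")
  cat("  after brain-list exclusion: ", x$n_after_brain_exclusion, "\n")
  cat("  after tumor recurrence:     ", x$n_after_tumor_recurrence, "\n")
  cat("  burden cutoff:              ", x$cutoff,
      if (isTRUE(x$degenerate)) " (degenerate split)" else "", "\n", sep = "")
  tab <- table(x$groups)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
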