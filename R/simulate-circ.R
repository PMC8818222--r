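# Planted circRNA universe. Each circ is an exon-boundary pair inside one
# gene; circs are stratified so the downstream screening cascade has an exact,
# known answer:
#   brain_listed  -- on the normal-brain exclusion list
#   candidate     -- in >= 1 CSF, in tumor tissue of >= 2 patients, not listed
#   csf_absent    -- never expressed in CSF (fails the CSF-detection stage)
#   low_recurrence-- CSF-present but in tumor tissue of <= 1 patient
#                    (negative control for the recurrence filter)

#' Plant a circRNA universe with screening ground truth
#'
#' @param config A [cohort_config()].
#' @param gene_models Result of [generate_gene_models()].
#' @return A list with `circs` (data.frame: `junction_id`, `chrom`, `start`,
#'   `end`, `strand`, `gene_id`, `stratum`) and `truth` (list:
#'   `true_candidates`, `exclusion_list`, `planted_sites`, `true_hr`,
#'   `ctdna_rho`; group assignment is added by [simulate_clinical()]).
#' @export
simulate_circ_truth <- function(config, gene_models) {
  validate_cohort_config(config)
  if (config$n_circ_total < config$n_candidates_true) {
    stop("invalid config: n_circ_total < n_candidates_true")
  }
  set.seed(config$seed + 202L)
  genes <- gene_models$genes
  gene_ids <- unique(genes$gene_id)
  n <- config$n_circ_total

  seen <- character(0)
  rows <- vector("list", n)
  k <- 0L
  while (k < n) {
    gid <- sample(gene_ids, 1L)
    gx <- genes[genes$gene_id == gid, , drop = FALSE]
    i <- sample(nrow(gx), 1L)
    jj <- i:nrow(gx)                 # sample() misbehaves on scalars
    j <- jj[sample.int(length(jj), 1L)]
    jid <- junction_id(gx$chrom[1], gx$start[i], gx$end[j], gx$strand[1])
    if (jid %in% seen) next
    seen <- c(seen, jid)
    k <- k + 1L
    rows[[k]] <- data.frame(
      junction_id = jid, chrom = gx$chrom[1],
      start = gx$start[i], end = gx$end[j], strand = gx$strand[1],
      gene_id = gid, stringsAsFactors = FALSE
    )
  }
  circs <- do.call(rbind, rows)

  n_cand <- config$n_candidates_true
  n_listed <- min(config$n_brain_listed, n - n_cand)
  n_rest <- n - n_cand - n_listed
  n_absent <- n_rest %/% 2L
  n_lowrec <- n_rest - n_absent
  stratum <- c(rep("candidate", n_cand), rep("brain_listed", n_listed),
               rep("csf_absent", n_absent), rep("low_recurrence", n_lowrec))
  circs$stratum <- sample(stratum)

  cand_ids <- sort(circs$junction_id[circs$stratum == "candidate"])
  planted <- data.frame(
    circ_id = cand_ids,
    mirna_id = sprintf("sim-miR-%03d", seq_along(cand_ids)),
    stringsAsFactors = FALSE
  )
  truth <- list(
    true_candidates = cand_ids,
    exclusion_list = sort(circs$junction_id[circs$stratum == "brain_listed"]),
    planted_sites = planted,
    true_hr = config$hazard_ratio_abundant,
    ctdna_rho = config$ctdna_rho
  )
  list(circs = circs, truth = truth)
}
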