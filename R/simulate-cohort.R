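# End-to-end synthetic cohort generation. Everything is derived from the
# config seed, so a fixed seed yields byte-identical output files.

#' Simulate a complete synthetic cohort
#'
#' Runs the whole generator: toy genome and gene models, planted circRNA
#' universe with screening ground truth, count matrices, chimeric junction
#' records, miRNAs/3'UTRs with planted binding sites, and a clinical table
#' whose hazard follows the realized candidate-detection burden (dichotomized
#' with [dichotomize_burden()]).
#'
#' @param config A [cohort_config()].
#' @param outdir Optional directory; when given, all standard files are
#'   written (genome FASTA, genes BED12, per-sample chimeric TSVs, miRNA and
#'   3'UTR FASTA, count TSVs, exclusion TSV, sample sheet CSV, clinical CSV,
#'   truth JSON).
#' @param n_decoys Decoy chimeric records per sample (default 0).
#' @param quantile Top-burden fraction used to assign the true survival
#'   groups (default 0.25).
#' @return List with `config`, `gene_models`, `circs`, `truth`, `expr`
#'   (from [simulate_expression()]), `chimeric`, `mirna` (from
#'   [simulate_mirnas()]), `clinical`, and `files` (named paths, when
#'   `outdir` is given).
#' @export
simulate_cohort <- function(config = cohort_config(), outdir = NULL,
                            n_decoys = 0L, quantile = 0.25) {
  validate_cohort_config(config)
  gm <- generate_gene_models(config)
  ct <- simulate_circ_truth(config, gm)
  expr <- simulate_expression(config, ct, gm)
  chim <- simulate_chimeric_records(ct$circs, expr$circ_counts, config,
                                    n_decoys = n_decoys)
  mir <- simulate_mirnas(config, ct, gm, gm$genome)

  samples <- expr$samples
  csf <- samples[samples$compartment == "csf", , drop = FALSE]
  burden <- species_count(
    expr$circ_counts[, csf$sample_id, drop = FALSE],
    subset = ct$truth$true_candidates
  )
  names(burden) <- csf$patient_id[match(names(burden), csf$sample_id)]
  all_pats <- sprintf("P%02d", seq_len(config$n_patients))
  # patients without a CSF sample cannot be graded by burden; they default to
  # the deficient (baseline-hazard) group
  dich <- dichotomize_burden(burden, quantile = quantile)
  groups <- setNames(rep("deficient", length(all_pats)), all_pats)
  groups[names(dich$groups)] <- dich$groups
  csf_abundance <- colSums(expr$circ_counts[, csf$sample_id, drop = FALSE])
  names(csf_abundance) <- csf$patient_id[
    match(names(csf_abundance), csf$sample_id)]

  truth <- ct$truth
  truth$group_assignment <- groups
  truth$burden_cutoff <- dich$cutoff
  clinical <- simulate_clinical(config, groups,
                                csf_abundance = csf_abundance)

  out <- list(config = config, gene_models = gm, circs = ct$circs,
              truth = truth, expr = expr, chimeric = chim, mirna = mir,
              clinical = clinical)
  if (!is.null(outdir)) out$files <- write_cohort(out, outdir)
  out
}

write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  files <- c(
    genome = p("genome.fa"), genes = p("genes.bed"),
    mirna = p("mirna.fa"), utr = p("utr3.fa"),
    circ_counts = p("circ_counts.tsv"), linear_counts = p("linear_counts.tsv"),
    exclusion = p("normal_brain_exclusion.tsv"),
    samples = p("samples.csv"), clinical = p("clinical.csv"),
    truth = p("truth.json")
  )
  Biostrings::writeXStringSet(cohort$gene_models$genome, files["genome"])
  write_bed12(cohort$gene_models$genes, files["genes"])
  write_fasta(cohort$mirna$mirnas, files["mirna"], rna = TRUE)
  write_fasta(cohort$mirna$utrs, files["utr"], rna = TRUE)
  write_count_matrix(cohort$expr$circ_counts, files["circ_counts"])
  write_count_matrix(cohort$expr$linear_counts, files["linear_counts"])
  writeLines(c("junction_id", cohort$truth$exclusion_list),
             files["exclusion"])
  write.csv(cohort$expr$samples, files["samples"], row.names = FALSE)
  write.csv(cohort$clinical, files["clinical"], row.names = FALSE)
  jsonlite::write_json(
    list(true_candidates = cohort$truth$true_candidates,
         exclusion_list = cohort$truth$exclusion_list,
         planted_sites = cohort$truth$planted_sites,
         group_assignment = as.list(cohort$truth$group_assignment),
         burden_cutoff = cohort$truth$burden_cutoff,
         true_hr = cohort$truth$true_hr,
         ctdna_rho = cohort$truth$ctdna_rho),
    files["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  chim_files <- write_chimeric_files(cohort$chimeric, file.path(outdir, "chimeric"))
  c(files, chim_files)
}

#' Write a feature x sample matrix as TSV with a feature_id column
#'
#' @param mat Matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature x sample TSV written by [write_count_matrix()]
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
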