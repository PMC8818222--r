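# Count simulation. Negative-binomial counts with per-circ lognormal means;
# the CSF compartment draws from a per-patient Bernoulli species subset
# (inter-patient heterogeneity) with means boosted by csf_abundance_factor.
# Candidate circs get a correlated partner mRNA via a Gaussian copula so the
# co-expression edge rule (|PCC| >= 0.70 & p < 0.01) is recoverable.

#' Simulate linear and circRNA count matrices for the cohort
#'
#' @param config A [cohort_config()].
#' @param circ_truth Result of [simulate_circ_truth()].
#' @param gene_models Result of [generate_gene_models()].
#' @return List with `circ_counts` (junctions x samples integer matrix),
#'   `linear_counts` (genes x samples), `lib_size` (per-sample linear totals),
#'   `samples` (the sample sheet), and `coexpr_partners` (data.frame
#'   `circ_id`, `gene_id`, one partner mRNA per planted candidate).
#' @export
simulate_expression <- function(config, circ_truth, gene_models) {
  validate_cohort_config(config)
  set.seed(config$seed + 303L)
  circs <- circ_truth$circs
  samples <- sample_sheet(config)
  n_c <- nrow(circs)
  n_s <- nrow(samples)
  size <- 1 / config$dispersion

  mu_circ <- exp(rnorm(n_c, log(30), 0.7))
  # compartment mean multipliers, CSF boosted
  comp_fac <- c(csf = config$csf_abundance_factor, plasma = 1, tissue = 1)
  fac <- comp_fac[samples$compartment]
  fac[is.na(fac)] <- 1

  # eligibility masks -------------------------------------------------------
  eligible <- matrix(TRUE, n_c, n_s,
                     dimnames = list(circs$junction_id, samples$sample_id))
  is_csf <- samples$compartment == "csf"
  is_tissue <- samples$compartment == "tissue"

  # CSF: per-patient Bernoulli species subset; csf_absent stratum never in CSF
  for (s in which(is_csf)) {
    eligible[, s] <- runif(n_c) < config$csf_species_fraction
  }
  eligible[circs$stratum == "csf_absent", is_csf] <- FALSE

  # low-recurrence stratum: at most one designated tissue patient
  tissue_pat <- unique(samples$patient_id[is_tissue])
  low_idx <- which(circs$stratum == "low_recurrence")
  designated <- sample(tissue_pat, length(low_idx), replace = TRUE)
  eligible[low_idx, is_tissue] <- FALSE
  for (i in seq_along(low_idx)) {
    s <- which(is_tissue & samples$patient_id == designated[i])
    eligible[low_idx[i], s] <- TRUE
  }

  # forced-present cells make cascade ground truth exact by construction
  forced <- matrix(FALSE, n_c, n_s,
                   dimnames = dimnames(eligible))
  csf_pat <- unique(samples$patient_id[is_csf])
  cand_idx <- which(circs$stratum == "candidate")
  for (i in cand_idx) {
    pc <- sample(csf_pat, min(3L, length(csf_pat)))
    forced[i, is_csf & samples$patient_id %in% pc] <- TRUE
    pt <- sample(tissue_pat, min(2L, length(tissue_pat)))
    forced[i, is_tissue & samples$patient_id %in% pt] <- TRUE
  }
  for (i in seq_along(low_idx)) {
    s <- which(is_tissue & samples$patient_id == designated[i])
    forced[low_idx[i], s] <- TRUE
  }
  eligible[forced] <- TRUE

  # counts -------------------------------------------------------------------
  mu_mat <- outer(mu_circ, fac)
  latent_circ <- matrix(rnorm(n_c * n_s), n_c, n_s)
  circ_counts <- matrix(0L, n_c, n_s, dimnames = dimnames(eligible))
  circ_counts[eligible] <- qnbinom(pnorm(latent_circ[eligible]),
                                   size = size, mu = mu_mat[eligible])
  circ_counts[forced] <- pmax(circ_counts[forced], 1L)
  storage.mode(circ_counts) <- "integer"

  # linear genes -------------------------------------------------------------
  gene_ids <- unique(gene_models$genes$gene_id)
  n_g <- length(gene_ids)
  mu_gene <- exp(rnorm(n_g, log(200), 0.8))
  latent_gene <- matrix(rnorm(n_g * n_s), n_g, n_s)

  cand_ids <- circ_truth$truth$true_candidates
  cand_row <- match(cand_ids, circs$junction_id)
  partner_gene <- sample(gene_ids, length(cand_ids))
  rho <- config$coexpr_rho
  for (i in seq_along(cand_ids)) {
    gi <- match(partner_gene[i], gene_ids)
    latent_gene[gi, ] <- rho * latent_circ[cand_row[i], ] +
      sqrt(1 - rho^2) * rnorm(n_s)
  }
  linear_counts <- matrix(
    qnbinom(pnorm(latent_gene), size = size, mu = rep(mu_gene, n_s)),
    n_g, n_s, dimnames = list(gene_ids, samples$sample_id)
  )
  storage.mode(linear_counts) <- "integer"

  list(
    circ_counts = circ_counts,
    linear_counts = linear_counts,
    lib_size = colSums(linear_counts),
    samples = samples,
    coexpr_partners = data.frame(circ_id = cand_ids, gene_id = partner_gene,
                                 stringsAsFactors = FALSE)
  )
}
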