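#' Cohort simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults encode the
#' study conditions the toolkit targets: 21 brain-metastasis patients sampled
#' in three compartments with the observed missingness pattern (15 tumor
#' tissues, 19 CSFs, 21 plasmas), CSF carrying fewer circRNA species than
#' tissue (`csf_species_fraction < 1`) but at higher abundance
#' (`csf_abundance_factor > 1`), and survival hazard tied to candidate-circRNA
#' detection burden.
#'
#' @param n_patients Number of patients.
#' @param compartments Compartment labels; the cascade expects `"csf"` and
#'   `"tissue"` to be present.
#' @param missing_samples Data frame with columns `patient` (integer index)
#'   and `compartment`, listing absent samples. The default reproduces the
#'   target design: CSF missing for patients 1 and 20, tumor tissue missing
#'   for patients 4, 7, 9, 11, 18 and 19.
#' @param read_length,anchor_size Sequencing read length and junction anchor
#'   size in nt; the circRNA effective length is `2 * (read_length -
#'   anchor_size)`.
#' @param n_genes Number of multi-exon gene models on the toy genome.
#' @param n_circ_total Total number of simulated back-splice junctions.
#' @param n_candidates_true Number of planted true candidates (in >= 1 CSF,
#'   in tumor tissue of >= 2 patients, not on the exclusion list).
#' @param n_brain_listed Size of the normal-brain exclusion stratum.
#' @param csf_species_fraction Fraction in (0, 1) of circ species eligible for
#'   expression in a given patient's CSF relative to tissue.
#' @param csf_abundance_factor Multiplicative mean-abundance boost in CSF
#'   (must be > 1).
#' @param hazard_ratio_abundant True hazard ratio of the circRNA-abundant
#'   group versus the deficient group (> 0).
#' @param ctdna_rho Target (negative) correlation between CSF candidate
#'   circRNA abundance and ctDNA concentration.
#' @param coexpr_rho Latent correlation planted between each candidate circ
#'   and its partner mRNA.
#' @param dispersion Negative-binomial dispersion (1/size) of simulated counts.
#' @param baseline_median_os Baseline (deficient-group) median overall
#'   survival in months.
#' @param max_followup Upper bound of the uniform censoring distribution in
#'   months.
#' @param seed Integer RNG seed; a fixed seed makes every generated artifact
#'   byte-identical.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 21L,
                          compartments = c("csf", "plasma", "tissue"),
                          missing_samples = NULL,
                          read_length = 150L,
                          anchor_size = 20L,
                          n_genes = 80L,
                          n_circ_total = 150L,
                          n_candidates_true = 12L,
                          n_brain_listed = 40L,
                          csf_species_fraction = 0.4,
                          csf_abundance_factor = 5,
                          hazard_ratio_abundant = 3,
                          ctdna_rho = -0.76,
                          coexpr_rho = 0.9,
                          dispersion = 0.3,
                          baseline_median_os = 17,
                          max_followup = 68.2,
                          seed = 1L) {
  if (is.null(missing_samples) && n_patients == 21L &&
      all(c("csf", "tissue") %in% compartments)) {
    missing_samples <- data.frame(
      patient = c(1L, 20L, 4L, 7L, 9L, 11L, 18L, 19L),
      compartment = c("csf", "csf", rep("tissue", 6L)),
      stringsAsFactors = FALSE
    )
  } else if (is.null(missing_samples)) {
    missing_samples <- data.frame(patient = integer(), compartment = character(),
                                  stringsAsFactors = FALSE)
  }
  cfg <- list(
    n_patients = as.integer(n_patients), compartments = compartments,
    missing_samples = missing_samples,
    read_length = as.integer(read_length), anchor_size = as.integer(anchor_size),
    n_genes = as.integer(n_genes), n_circ_total = as.integer(n_circ_total),
    n_candidates_true = as.integer(n_candidates_true),
    n_brain_listed = as.integer(n_brain_listed),
    csf_species_fraction = csf_species_fraction,
    csf_abundance_factor = csf_abundance_factor,
    hazard_ratio_abundant = hazard_ratio_abundant,
    ctdna_rho = ctdna_rho, coexpr_rho = coexpr_rho,
    dispersion = dispersion,
    baseline_median_os = baseline_median_os, max_followup = max_followup,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("invalid config: n_patients must be >= 1")
  if (cfg$n_genes < 1L) stop("invalid config: n_genes must be >= 1")
  if (cfg$n_circ_total < 1L) stop("invalid config: n_circ_total must be >= 1")
  if (cfg$n_circ_total < cfg$n_candidates_true) {
    stop("invalid config: n_circ_total < n_candidates_true")
  }
  if (!(cfg$csf_species_fraction > 0 && cfg$csf_species_fraction < 1)) {
    stop("invalid config: csf_species_fraction must lie in (0, 1)")
  }
  if (cfg$csf_abundance_factor <= 1) {
    stop("invalid config: csf_abundance_factor must be > 1")
  }
  if (cfg$hazard_ratio_abundant <= 0) {
    stop("invalid config: hazard_ratio_abundant must be > 0")
  }
  if (cfg$read_length <= cfg$anchor_size) {
    stop("invalid config: read_length must exceed anchor_size")
  }
  invisible(cfg)
}

#' Sample sheet implied by a cohort configuration
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `sample_id`, `patient_id`, `compartment`,
#'   `batch`; one row per non-missing patient x compartment combination.
#' @export
sample_sheet <- function(config) {
  pats <- sprintf("P%02d", seq_len(config$n_patients))
  grid <- expand.grid(patient = seq_len(config$n_patients),
                      compartment = config$compartments,
                      stringsAsFactors = FALSE)
  miss <- config$missing_samples
  if (nrow(miss)) {
    drop <- paste(grid$patient, grid$compartment) %in%
      paste(miss$patient, miss$compartment)
    grid <- grid[!drop, , drop = FALSE]
  }
  grid <- grid[order(grid$patient, grid$compartment), , drop = FALSE]
  data.frame(
    sample_id = paste0(pats[grid$patient], "_", grid$compartment),
    patient_id = pats[grid$patient],
    compartment = grid$compartment,
    batch = letters[(grid$patient - 1L) %% 6L + 1L],
    stringsAsFactors = FALSE
  )
}
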