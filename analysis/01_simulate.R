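#!/usr/bin/env Rscript
# Step 1: generate the synthetic 21-patient cohort (CSF / plasma / tumor
# tissue with the study's missingness pattern) with known ground truth.
# Bulky per-sample artifacts go under scratch/; small summaries under
# results/.

suppressMessages(library(csfcirc))

cfg <- cohort_config(seed = 20260301L)
cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

co <- simulate_cohort(cfg, outdir = cohort_dir, n_decoys = 25L)

cat("Simulated cohort:\n")
cat("  patients:", cfg$n_patients, " samples:", nrow(co$expr$samples), "\n")
cat("  circ junctions:", nrow(co$circs),
    " planted candidates:", length(co$truth$true_candidates), "\n")
cat("  exclusion-list entries:", length(co$truth$exclusion_list), "\n")
cat("  genome:", sum(Biostrings::width(co$gene_models$genome)), "nt over",
    length(co$gene_models$genome), "chromosomes\n")
cat("  burden cutoff (top 25%):", co$truth$burden_cutoff, "\n")
cat("  files in", cohort_dir, "\n")

write.csv(data.frame(parameter = names(unlist(cfg[c(
  "n_patients", "read_length", "anchor_size", "n_genes", "n_circ_total",
  "n_candidates_true", "n_brain_listed", "csf_species_fraction",
  "csf_abundance_factor", "hazard_ratio_abundant", "ctdna_rho", "seed")])),
  value = unlist(cfg[c(
    "n_patients", "read_length", "anchor_size", "n_genes", "n_circ_total",
    "n_candidates_true", "n_brain_listed", "csf_species_fraction",
    "csf_abundance_factor", "hazard_ratio_abundant", "ctdna_rho", "seed")])),
  "results/01_simulation_parameters.csv", row.names = FALSE)
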