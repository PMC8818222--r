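#!/usr/bin/env Rscript
# Step 3: compartment profiling -- species counts per compartment,
# abundance and circ/parent ratios, shared-species structure, and the
# circRNA-vs-ctDNA correlation.

suppressMessages(library(csfcirc))

samples <- read.csv("scratch/cohort/samples.csv", stringsAsFactors = FALSE)
clinical <- read.csv("scratch/cohort/clinical.csv", stringsAsFactors = FALSE)
circ_counts <- read_count_matrix("scratch/circ_counts_called.tsv")
cf <- read_count_matrix("scratch/circ_fpkm.tsv")
lf <- read_count_matrix("scratch/linear_fpkm.tsv")
ann <- read.delim("scratch/junction_annotation.tsv",
                  stringsAsFactors = FALSE)

sp <- species_count(circ_counts)
by_comp <- split(sp[samples$sample_id], samples$compartment)
cat("Species per sample (mean):\n")
print(round(vapply(by_comp, mean, numeric(1)), 1))

comp_tests <- do.call(rbind, lapply(
  list(c("csf", "tissue"), c("csf", "plasma"), c("plasma", "tissue")),
  function(pr) {
    wt <- wilcoxon_test(by_comp[[pr[1]]], by_comp[[pr[2]]])
    data.frame(comparison = paste(pr, collapse = "_vs_"),
               statistic = wt$statistic, p = wt$p)
  }
))
cat("Species-count comparisons (rank-sum):\n")
print(comp_tests, row.names = FALSE)

med_nz <- vapply(by_comp, function(ids) {
  v <- cf[, names(ids), drop = FALSE]
  median(v[v > 0])
}, numeric(1))
cat("Median nonzero circ FPKM by compartment:\n")
print(signif(med_nz, 3))

ratios <- suppressWarnings(circ_parent_ratio(cf, lf, ann))
cat("Median circ/parent FPKM ratio by compartment:\n")
print(signif(vapply(by_comp, function(ids) {
  v <- ratios[, names(ids), drop = FALSE]
  median(v[is.finite(v) & v > 0])
}, numeric(1)), 3))

sh <- sharing_table(circ_counts, samples)
sh$same_patient <- sh$patient_a == sh$patient_b
cat("Mean log2 shared species, between-patient, by compartment pair:\n")
bp <- sh[!sh$same_patient & sh$compartment_a == sh$compartment_b, ]
print(round(tapply(bp$log2_shared, bp$compartment_a, mean), 2))

# ctDNA anti-correlation with total candidate CSF abundance
csf <- samples[samples$compartment == "csf", ]
ab <- colSums(cf[, csf$sample_id, drop = FALSE])
cl <- clinical[match(csf$patient_id, clinical$patient_id), ]
ct <- pearson_with_p(log1p(ab), log(cl$ctdna))
cat(sprintf("CSF circ abundance vs ctDNA: r = %.2f, p = %.3f (n = %d)\n",
            ct$r, ct$p, ct$n))

write.table(comp_tests, "results/03_species_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sh, "results/03_sharing_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.csv(data.frame(metric = c("ctdna_r", "ctdna_p", "ctdna_n"),
                     value = c(ct$r, ct$p, ct$n)),
          "results/03_ctdna_correlation.csv", row.names = FALSE)
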