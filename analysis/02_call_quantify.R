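#!/usr/bin/env Rscript
# Step 2: call back-splice junctions from the chimeric files, merge to a
# cohort count matrix, annotate against the gene models, and quantify
# (TMM factors from linear counts; circ FPKM with effective length
# 2 * (read_length - anchor_size) and linear-derived denominators).

suppressMessages(library(csfcirc))

cohort_dir <- "scratch/cohort"
samples <- read.csv(file.path(cohort_dir, "samples.csv"),
                    stringsAsFactors = FALSE)
genes <- read_bed12(file.path(cohort_dir, "genes.bed"))

chim_paths <- list.files(file.path(cohort_dir, "chimeric"),
                         full.names = TRUE)
calls <- lapply(chim_paths, function(p) {
  call_backsplice(parse_chimeric_file(p), min_reads = 1L)
})
names(calls) <- sub("\\.chimeric\\.tsv$", "", basename(chim_paths))
circ_counts <- merge_samples(calls, sample_ids = samples$sample_id)
cat("Called", nrow(circ_counts), "distinct back-splice junctions from",
    length(chim_paths), "samples\n")

ann <- annotate_junctions(parse_junction_id(rownames(circ_counts)), genes)
cat("  annotated to a parental gene:", sum(ann$gene_id != "unannotated"),
    "/", nrow(ann), "\n")

linear_counts <- read_count_matrix(file.path(cohort_dir, "linear_counts.tsv"))
lib_size <- colSums(linear_counts)
nf <- tmm_factors(linear_counts)
lens <- gene_lengths(genes)[rownames(linear_counts)]
lin_fpkm <- linear_fpkm(linear_counts, lens, lib_size, nf)

cfg_tab <- read.csv("results/01_simulation_parameters.csv")
rl <- as.integer(cfg_tab$value[cfg_tab$parameter == "read_length"])
an <- as.integer(cfg_tab$value[cfg_tab$parameter == "anchor_size"])
cat("  circ effective length:", circ_effective_length(rl, an), "nt\n")
cf <- circ_fpkm(circ_counts, rl, an, lib_size, nf)

write_count_matrix(circ_counts, "scratch/circ_counts_called.tsv")
write_count_matrix(cf, "scratch/circ_fpkm.tsv")
write_count_matrix(lin_fpkm, "scratch/linear_fpkm.tsv")
write.table(
  data.frame(sample_id = colnames(linear_counts), lib_size = lib_size,
             norm_factor = nf),
  "results/02_sample_stats.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE
)
write.table(cbind(ann["junction_id"], gene_id = ann$gene_id),
            "scratch/junction_annotation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("  TMM factors span [", round(min(nf), 3), ",", round(max(nf), 3), "]\n")
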