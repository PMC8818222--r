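# Planted miRNA binding sites. For every planted (circ, miRNA) pair the
# miRNA is the perfect antiparallel complement of a 22-nt window spanning the
# circ's back-splice joint on the reverse-joined junction probe, so the site
# cannot occur on the linear transcript. Decoy miRNAs are random sequences.

#' Simulate mature miRNAs and 3'UTRs with planted binding sites
#'
#' @param config A [cohort_config()].
#' @param circ_truth Result of [simulate_circ_truth()].
#' @param gene_models,genome From [generate_gene_models()].
#' @param targets Optional data.frame (`mirna_id`, `gene_id`) of planted
#'   miRNA-to-mRNA seed sites; by default each planted miRNA targets its
#'   candidate circ's co-expression partner position in the gene list.
#' @param n_decoys Number of random decoy miRNAs (default 8).
#' @param flank_nt Probe flank length used for site planting (default 30).
#' @param utr_length Length of simulated 3'UTRs in nt (default 500).
#' @return List: `mirnas` (named RNA character vector), `utrs` (named RNA
#'   character vector keyed by gene), `planted_sites` (circ/miRNA pairs),
#'   `mirna_targets` (miRNA/gene pairs), `probes` (the junction probes used).
#' @export
simulate_mirnas <- function(config, circ_truth, gene_models, genome,
                            targets = NULL, n_decoys = 8L, flank_nt = 30L,
                            utr_length = 500L) {
  set.seed(config$seed + 505L)
  planted <- circ_truth$truth$planted_sites
  circs <- circ_truth$circs
  stopifnot(all(planted$circ_id %in% circs$junction_id))

  probes <- lapply(planted$circ_id, function(id) {
    build_probe(circs[circs$junction_id == id, ], gene_models, genome,
                flank_nt = flank_nt)
  })
  names(probes) <- planted$circ_id

  mirnas <- character(0)
  for (i in seq_len(nrow(planted))) {
    p <- probes[[planted$circ_id[i]]]
    L <- nchar(p$sequence)
    # 22-nt window straddling the joint (falls back to the probe for tiny circs)
    w0 <- max(1L, min(p$junction_offset - 10L, L - 21L))
    window <- substr(p$sequence, w0, min(w0 + 21L, L))
    mirnas[[planted$mirna_id[i]]] <- as.character(
      Biostrings::reverseComplement(Biostrings::RNAString(window))
    )
  }
  for (d in seq_len(n_decoys)) {
    mirnas[[sprintf("decoy-miR-%03d", d)]] <-
      paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE), collapse = "")
  }

  gene_ids <- unique(
    (if (is.data.frame(gene_models)) gene_models else gene_models$genes)$gene_id
  )
  if (is.null(targets)) {
    targets <- data.frame(
      mirna_id = planted$mirna_id,
      gene_id = sample(gene_ids, nrow(planted)),
      stringsAsFactors = FALSE
    )
  }
  utrs <- vapply(gene_ids, function(g) {
    paste(sample(c("A", "C", "G", "U"), utr_length, replace = TRUE),
          collapse = "")
  }, character(1))
  for (i in seq_len(nrow(targets))) {
    seed <- substr(.rna_clean(mirnas[[targets$mirna_id[i]]]), 2L, 8L)
    site <- paste0(as.character(Biostrings::reverseComplement(
      Biostrings::RNAString(seed))), "A")    # 8mer site
    g <- targets$gene_id[i]
    at <- sample(seq_len(utr_length - nchar(site) - 1L), 1L)
    utrs[[g]] <- paste0(substr(utrs[[g]], 1L, at - 1L), site,
                        substr(utrs[[g]], at + nchar(site), utr_length))
  }
  list(mirnas = mirnas, utrs = utrs, planted_sites = planted,
       mirna_targets = targets, probes = probes)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector (RNA or DNA alphabet).
#' @param path Output path.
#' @param rna Write as RNA (`TRUE`) or back-transcribe to DNA.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, rna = TRUE) {
  x <- if (rna) Biostrings::RNAStringSet(unlist(seqs)) else
    Biostrings::DNAStringSet(chartr("U", "T", unlist(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
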