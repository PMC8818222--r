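# Toy genome + multi-exon gene models for the synthetic cohort.
# Coordinates are 0-based half-open throughout; BED12 serialization keeps that
# convention natively.

#' Generate a toy genome and multi-exon gene models
#'
#' Lays non-overlapping multi-exon genes along three toy chromosomes and draws
#' a random genome sequence. Deterministic under the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list with `genes` (data.frame: `gene_id`, `chrom`, `strand`,
#'   `exon`, `start`, `end`; one row per exon, 0-based half-open), `genome`
#'   (a [Biostrings::DNAStringSet] of chromosomes), and `chrom_sizes`.
#' @export
generate_gene_models <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed + 101L)
  n_genes <- config$n_genes
  chroms <- c("chr1", "chr2", "chr3")
  gene_chrom <- chroms[(seq_len(n_genes) - 1L) %% length(chroms) + 1L]
  rows <- vector("list", n_genes)
  cursor <- setNames(rep(1000L, length(chroms)), chroms)
  for (g in seq_len(n_genes)) {
    chrom <- gene_chrom[g]
    n_exon <- sample(3:8, 1L)
    exon_len <- sample(80:300, n_exon, replace = TRUE)
    intron_len <- sample(100:500, n_exon - 1L, replace = TRUE)
    starts <- integer(n_exon)
    ends <- integer(n_exon)
    pos <- cursor[[chrom]]
    for (e in seq_len(n_exon)) {
      starts[e] <- pos
      ends[e] <- pos + exon_len[e]
      pos <- ends[e] + if (e < n_exon) intron_len[e] else 0L
    }
    cursor[[chrom]] <- pos + sample(8000L:12000L, 1L)
    rows[[g]] <- data.frame(
      gene_id = sprintf("G%03d", g), chrom = chrom,
      strand = sample(c("+", "-"), 1L),
      exon = seq_len(n_exon), start = starts, end = ends,
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, rows)
  chrom_sizes <- setNames(as.integer(cursor + 1000L), chroms)
  genome <- Biostrings::DNAStringSet(vapply(chrom_sizes, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1)))
  names(genome) <- chroms
  list(genes = genes, genome = genome, chrom_sizes = chrom_sizes)
}

#' Write gene models as BED12
#'
#' One line per gene; blocks are the exons. Coordinates stay 0-based
#' half-open per the BED convention.
#'
#' @param genes Exon-level gene model data.frame from
#'   [generate_gene_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  sp <- split(genes, genes$gene_id)
  lines <- vapply(sp, function(gx) {
    gx <- gx[order(gx$start), , drop = FALSE]
    chrom_start <- min(gx$start)
    chrom_end <- max(gx$end)
    sizes <- paste0(paste(gx$end - gx$start, collapse = ","), ",")
    offsets <- paste0(paste(gx$start - chrom_start, collapse = ","), ",")
    paste(gx$chrom[1], chrom_start, chrom_end, gx$gene_id[1], 0L,
          gx$strand[1], chrom_start, chrom_end, "0", nrow(gx),
          sizes, offsets, sep = "\t")
  }, character(1))
  writeLines(lines[order(names(sp))], path)
  invisible(path)
}

#' Read BED12 gene models
#'
#' @param path BED12 file path.
#' @return Exon-level gene model data.frame (`gene_id`, `chrom`, `strand`,
#'   `exon`, `start`, `end`).
#' @export
read_bed12 <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("BED12 requires 12 columns, found ", ncol(tab))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    sizes <- as.integer(strsplit(tab[i, 11], ",")[[1]])
    offsets <- as.integer(strsplit(tab[i, 12], ",")[[1]])
    if (length(sizes) != tab[i, 10] || length(offsets) != tab[i, 10]) {
      stop("BED12 block count mismatch on line ", i)
    }
    data.frame(
      gene_id = tab[i, 4], chrom = tab[i, 1], strand = tab[i, 6],
      exon = seq_along(sizes),
      start = tab[i, 2] + offsets, end = tab[i, 2] + offsets + sizes,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
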