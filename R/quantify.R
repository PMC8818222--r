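# Quantification: TMM normalization factors from the linear count matrix,
# exon-union FPKM for linear genes, and circRNA FPKM with the junction-
# specific effective length 2 * (read_length - anchor_size). circRNA FPKM
# always borrows library size and normalization factor from the SAME sample's
# linear transcripts -- circ totals never enter the denominator.

#' TMM normalization factors
#'
#' Trimmed mean of M-values via edgeR with the method's standard trims
#' (30% on M, 5% on A) and upper-quartile reference selection; factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Genes x samples non-negative count matrix.
#' @param ref_sample Optional reference column (name or index); auto-chosen
#'   otherwise.
#' @param trim_m,trim_a Trim fractions for M- and A-values.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  if (any(counts < 0)) stop("negative counts")
  zero_col <- colSums(counts) == 0
  if (any(zero_col)) {
    stop("sample with all-zero counts: ",
         paste(colnames(counts)[zero_col], collapse = ", "))
  }
  ref <- if (is.null(ref_sample)) NULL else {
    if (is.character(ref_sample)) match(ref_sample, colnames(counts))
    else as.integer(ref_sample)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = trim_m, sumTrim = trim_a)
  setNames(as.numeric(f), colnames(counts))
}

#' Exon-union length of a gene model
#'
#' Length of the union of exon intervals, with overlaps merged once.
#'
#' @param exons Data.frame with `start`, `end` (0-based half-open), one gene.
#' @return Integer length in nt.
#' @export
exon_union_length <- function(exons) {
  stopifnot(nrow(exons) >= 1L, all(exons$end > exons$start))
  ex <- exons[order(exons$start), , drop = FALSE]
  total <- 0L
  cur_s <- ex$start[1]
  cur_e <- ex$end[1]
  for (i in seq_len(nrow(ex))[-1]) {
    if (ex$start[i] <= cur_e) {
      cur_e <- max(cur_e, ex$end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- ex$start[i]
      cur_e <- ex$end[i]
    }
  }
  as.integer(total + (cur_e - cur_s))
}

#' Exon-union lengths for all genes in a model set
#'
#' @param gene_models Gene model list or exon-level `genes` data.frame.
#' @return Named integer vector keyed by gene_id.
#' @export
gene_lengths <- function(gene_models) {
  genes <- if (is.data.frame(gene_models)) gene_models else gene_models$genes
  vapply(split(genes, genes$gene_id), exon_union_length, integer(1))
}

#' FPKM from counts, feature lengths and linear library statistics
#'
#' `FPKM = count * 1e9 / (eff_length * lib_size * norm_factor)`.
#'
#' @param counts Feature x sample matrix.
#' @param eff_length Per-feature effective length in nt (recycled if scalar).
#' @param lib_size Per-sample linear library size.
#' @param norm_factor Per-sample TMM factor (default 1).
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
linear_fpkm <- function(counts, eff_length, lib_size,
                        norm_factor = rep(1, ncol(counts))) {
  if (any(eff_length <= 0)) stop("non-positive effective length")
  if (length(eff_length) == 1L) eff_length <- rep(eff_length, nrow(counts))
  if (!is.null(names(lib_size)) && !is.null(colnames(counts))) {
    missing_stats <- setdiff(colnames(counts), names(lib_size))
    if (length(missing_stats)) {
      stop("missing linear library statistics for sample: ",
           paste(missing_stats, collapse = ", "))
    }
    lib_size <- lib_size[colnames(counts)]
  }
  if (!is.null(names(norm_factor)) && !is.null(colnames(counts))) {
    norm_factor <- norm_factor[colnames(counts)]
  }
  denom <- outer(as.numeric(eff_length),
                 as.numeric(lib_size) * as.numeric(norm_factor))
  counts * 1e9 / denom
}

#' circRNA effective length
#'
#' Only read placements overlapping the back-splice joint by at least the
#' anchor on each side are unbiased circ evidence, giving effective length
#' `2 * (read_length - anchor_size)` for every circ.
#'
#' @param read_length,anchor_size Integers in nt, `read_length > anchor_size`.
#' @return Integer effective length.
#' @export
circ_effective_length <- function(read_length, anchor_size) {
  if (anchor_size >= read_length) {
    stop("anchor_size must be smaller than read_length")
  }
  2L * (as.integer(read_length) - as.integer(anchor_size))
}

#' circRNA FPKM with linear-derived normalization
#'
#' @param circ_counts Junctions x samples count matrix.
#' @param read_length,anchor_size Define the shared circ effective length.
#' @param lib_size,norm_factor Per-sample statistics from the LINEAR
#'   transcripts of the same samples (named by sample).
#' @return circRNA FPKM matrix.
#' @export
circ_fpkm <- function(circ_counts, read_length, anchor_size, lib_size,
                      norm_factor = setNames(rep(1, ncol(circ_counts)),
                                             colnames(circ_counts))) {
  el <- circ_effective_length(read_length, anchor_size)
  missing_stats <- setdiff(colnames(circ_counts), names(lib_size))
  if (length(missing_stats)) {
    stop("missing linear library statistics for sample: ",
         paste(missing_stats, collapse = ", "))
  }
  linear_fpkm(circ_counts, el, lib_size, norm_factor)
}

#' Ratio of circRNA FPKM to parental-gene FPKM
#'
#' @param circ_fpkm Junctions x samples FPKM matrix.
#' @param lin_fpkm Genes x samples FPKM matrix.
#' @param annotation Data.frame (`junction_id`, `gene_id`); unannotated circs
#'   are skipped with a warning.
#' @return Junctions x samples matrix of ratios; `NA` where the parent FPKM
#'   is 0 (undefined, never infinite).
#' @export
circ_parent_ratio <- function(circ_fpkm, lin_fpkm, annotation) {
  ann <- annotation[annotation$junction_id %in% rownames(circ_fpkm), ,
                    drop = FALSE]
  unann <- ann$junction_id[!(ann$gene_id %in% rownames(lin_fpkm)) |
                             ann$gene_id == "unannotated"]
  if (length(unann)) {
    warning("skipping unannotated circ(s): ",
            paste(utils::head(unann, 3), collapse = ", "),
            if (length(unann) > 3) " ...")
  }
  ann <- ann[!(ann$junction_id %in% unann), , drop = FALSE]
  out <- matrix(NA_real_, nrow(ann), ncol(circ_fpkm),
                dimnames = list(ann$junction_id, colnames(circ_fpkm)))
  for (i in seq_len(nrow(ann))) {
    parent <- lin_fpkm[ann$gene_id[i], colnames(circ_fpkm)]
    ratio <- circ_fpkm[ann$junction_id[i], ] / parent
    ratio[parent == 0] <- NA_real_
    out[i, ] <- ratio
  }
  out
}

#' Number of detected species per sample
#'
#' A species is a feature with read count > 0. Optionally restricted to a
#' feature subset (e.g. the candidate list for per-patient burden).
#'
#' @param counts Feature x sample matrix.
#' @param subset Optional character vector of feature IDs.
#' @return Named integer vector per sample.
#' @export
species_count <- function(counts, subset = NULL) {
  if (!is.null(subset)) {
    counts <- counts[intersect(subset, rownames(counts)), , drop = FALSE]
  }
  colSums(counts > 0)
}
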