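# Back-splice junction calling from chimeric read records.
#
# A chimeric record is back-splice evidence iff both segments map to the same
# chromosome and strand and the acceptor lies upstream of the donor in
# transcription order -- coordinate order reversed relative to linear
# splicing. With pos_a = 1-based first base after the donor segment end and
# pos_b = 1-based last base before the acceptor segment start, that is
# pos_b < pos_a - 1 on "+" (junction [pos_b, pos_a - 1) in 0-based half-open
# coordinates) and the mirrored pos_a < pos_b - 1 on "-" (junction
# [pos_a, pos_b - 1)).

#' Parse a chimeric junction file
#'
#' Reads the documented tab-delimited dialect (10 columns, the first seven
#' laid out like STAR's `Chimeric.out.junction`; extra columns ignored).
#' Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Data.frame of chimeric records in input order.
#' @export
parse_chimeric_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_chimeric())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 10L)) {
    stop("parse error at line ", lineno[which(nf < 10L)[1]],
         ": expected >= 10 tab-delimited columns, found ", nf[nf < 10L][1])
  }
  col <- function(k) vapply(fields, `[`, "", k)
  rec <- data.frame(
    chrom_a = col(1), pos_a = suppressWarnings(as.integer(col(2))),
    strand_a = col(3),
    chrom_b = col(4), pos_b = suppressWarnings(as.integer(col(5))),
    strand_b = col(6),
    junction_type = suppressWarnings(as.integer(col(7))),
    read_name = col(8),
    anchor_a = suppressWarnings(as.integer(col(9))),
    anchor_b = suppressWarnings(as.integer(col(10))),
    stringsAsFactors = FALSE
  )
  bad_num <- which(is.na(rec$pos_a) | is.na(rec$pos_b) |
                     is.na(rec$anchor_a) | is.na(rec$anchor_b))
  if (length(bad_num)) {
    stop("parse error at line ", lineno[bad_num[1]], ": non-numeric position")
  }
  bad_strand <- which(!(rec$strand_a %in% c("+", "-")) |
                        !(rec$strand_b %in% c("+", "-")))
  if (length(bad_strand)) {
    stop("parse error at line ", lineno[bad_strand[1]], ": invalid strand")
  }
  bad_pos <- which(rec$pos_a < 1L | rec$pos_b < 1L |
                     rec$anchor_a <= 0L | rec$anchor_b <= 0L)
  if (length(bad_pos)) {
    stop("parse error at line ", lineno[bad_pos[1]],
         ": position or anchor out of range")
  }
  rec
}

#' Call back-splice junctions from chimeric records
#'
#' @param records Data.frame from [parse_chimeric_file()] (or the same
#'   columns built in memory).
#' @param min_reads Minimum supporting reads to emit a junction (default 1,
#'   matching the species definition of read count > 0).
#' @return Data.frame: `junction_id`, `chrom`, `start`, `end`, `strand`,
#'   `count`, sorted by junction_id.
#' @export
call_backsplice <- function(records, min_reads = 1L) {
  stopifnot(min_reads >= 1L)
  if (nrow(records) == 0L) return(empty_junction_calls())
  same <- records$chrom_a == records$chrom_b &
    records$strand_a == records$strand_b
  plus_bs <- same & records$strand_a == "+" &
    records$pos_b < records$pos_a - 1L
  minus_bs <- same & records$strand_a == "-" &
    records$pos_a < records$pos_b - 1L
  bs <- records[plus_bs | minus_bs, , drop = FALSE]
  if (nrow(bs) == 0L) return(empty_junction_calls())
  start <- ifelse(bs$strand_a == "+", bs$pos_b, bs$pos_a)
  end <- ifelse(bs$strand_a == "+", bs$pos_a - 1L, bs$pos_b - 1L)
  jid <- junction_id(bs$chrom_a, start, end, bs$strand_a)
  tab <- table(jid)
  keep <- tab >= min_reads
  ids <- sort(names(tab)[keep])
  if (!length(ids)) return(empty_junction_calls())
  coords <- parse_junction_id(ids)
  coords$count <- as.integer(tab[ids])
  coords
}

empty_junction_calls <- function() {
  data.frame(junction_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             count = integer(), stringsAsFactors = FALSE)
}

#' Annotate junctions against exon boundaries of gene models
#'
#' A junction gets a `gene_id` iff its start matches an exon start and its
#' end an exon end of the same gene, each within `tolerance_nt`; otherwise
#' `"unannotated"`. Distinct junctions from one gene are never merged.
#'
#' @param junctions Data.frame from [call_backsplice()] (or with the same
#'   coordinate columns).
#' @param gene_models Gene model list or exon-level `genes` data.frame.
#' @param tolerance_nt Maximum boundary offset in nt (default 0, exact).
#' @param annotated_only Drop junctions without a gene assignment instead of
#'   keeping them as `"unannotated"`.
#' @return `junctions` with a `gene_id` column appended.
#' @export
annotate_junctions <- function(junctions, gene_models, tolerance_nt = 0L,
                               annotated_only = FALSE) {
  genes <- if (is.data.frame(gene_models)) gene_models else gene_models$genes
  gene_id <- rep("unannotated", nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    jx <- junctions[i, ]
    cand <- genes[genes$chrom == jx$chrom & genes$strand == jx$strand, ,
                  drop = FALSE]
    if (!nrow(cand)) next
    hit_start <- cand$gene_id[abs(cand$start - jx$start) <= tolerance_nt]
    hit_end <- cand$gene_id[abs(cand$end - jx$end) <= tolerance_nt]
    both <- intersect(unique(hit_start), unique(hit_end))
    if (length(both) == 1L) gene_id[i] <- both
    # ends in two different genes (or ambiguous) stay unannotated
  }
  junctions$gene_id <- gene_id
  if (annotated_only) {
    junctions <- junctions[gene_id != "unannotated", , drop = FALSE]
  }
  junctions
}

#' Merge per-sample junction calls into a cohort count matrix
#'
#' @param calls Named list (by sample ID) of data.frames from
#'   [call_backsplice()].
#' @param sample_ids Optional character vector fixing column order (samples
#'   without calls get all-zero columns).
#' @return Integer matrix, rows = union of junction IDs (sorted), columns =
#'   samples; absent combinations are 0.
#' @export
merge_samples <- function(calls, sample_ids = names(calls)) {
  if (anyDuplicated(sample_ids)) stop("duplicate sample ID")
  ids <- sort(unique(unlist(lapply(calls, `[[`, "junction_id"))))
  mat <- matrix(0L, length(ids), length(sample_ids),
                dimnames = list(ids, sample_ids))
  for (s in names(calls)) {
    cs <- calls[[s]]
    if (nrow(cs)) mat[cs$junction_id, s] <- cs$count
  }
  mat
}
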