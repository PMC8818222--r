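# Chimeric junction record simulation. The dialect is tab-delimited with ten
# columns (1-7 laid out like STAR's Chimeric.out.junction):
#   chrom_a  pos_a  strand_a  chrom_b  pos_b  strand_b  junction_type
#   read_name  anchor_a  anchor_b
# pos_a is the 1-based first base after the donor segment end, pos_b the
# 1-based last base before the acceptor segment start. A back-splice read for
# a circ [s, e) (0-based half-open) is encoded as pos_a = e + 1, pos_b = s on
# the "+" strand, and with the segment roles mirrored (pos_a = s,
# pos_b = e + 1) on the "-" strand, where the read traverses the junction in
# transcription order.

#' Simulate per-sample chimeric junction records
#'
#' Each circ with count `k` in a sample yields exactly `k` back-splice
#' records; optional decoys add linear-splice and inter-chromosomal chimeras
#' that a back-splice caller must reject.
#'
#' @param circs Circ table from [simulate_circ_truth()] (`$circs`).
#' @param counts Junctions x samples integer matrix of supporting reads.
#' @param config A [cohort_config()].
#' @param n_decoys Number of decoy records per sample (default 0).
#' @return Named list (by sample) of data.frames in the chimeric dialect.
#' @export
simulate_chimeric_records <- function(circs, counts, config, n_decoys = 0L) {
  stopifnot(all(counts >= 0), nrow(circs) == nrow(counts))
  set.seed(config$seed + 404L)
  rl <- config$read_length
  an <- config$anchor_size
  lapply(setNames(colnames(counts), colnames(counts)), function(s) {
    k <- counts[, s]
    idx <- rep(seq_len(nrow(circs)), k)
    if (length(idx)) {
      cc <- circs[idx, , drop = FALSE]
      plus <- cc$strand == "+"
      pos_a <- ifelse(plus, cc$end + 1L, cc$start)
      pos_b <- ifelse(plus, cc$start, cc$end + 1L)
      anchor_a <- sample(an:(rl - an), length(idx), replace = TRUE)
      rec <- data.frame(
        chrom_a = cc$chrom, pos_a = as.integer(pos_a), strand_a = cc$strand,
        chrom_b = cc$chrom, pos_b = as.integer(pos_b), strand_b = cc$strand,
        junction_type = 1L,
        read_name = sprintf("%s_bs_%06d", s, seq_along(idx)),
        anchor_a = anchor_a, anchor_b = rl - anchor_a,
        stringsAsFactors = FALSE
      )
    } else {
      rec <- empty_chimeric()
    }
    if (n_decoys > 0L) {
      rec <- rbind(rec, simulate_decoy_records(config, n_decoys, s))
    }
    rownames(rec) <- NULL
    rec
  })
}

#' Simulate decoy chimeric records (never back-splice)
#'
#' Half the decoys are linear-splice chimeras (donor upstream of acceptor in
#' transcription order), the rest inter-chromosomal fusions.
#'
#' @param config A [cohort_config()].
#' @param n Number of decoys.
#' @param sample_id Label used in read names.
#' @return Data.frame in the chimeric dialect.
#' @export
simulate_decoy_records <- function(config, n, sample_id = "decoy") {
  rl <- config$read_length
  an <- config$anchor_size
  strand <- sample(c("+", "-"), n, replace = TRUE)
  lo <- sample(1000:5000, n, replace = TRUE)
  hi <- lo + sample(500:5000, n, replace = TRUE)
  inter <- seq_len(n) > n / 2
  # linear splice: on "+", donor end precedes acceptor start (pos_a <= pos_b);
  # on "-" the mirrored layout (pos_b <= pos_a)
  pos_a <- ifelse(strand == "+", lo, hi)
  pos_b <- ifelse(strand == "+", hi, lo)
  chrom_a <- rep("chr1", n)
  chrom_b <- ifelse(inter, "chr2", "chr1")
  anchor_a <- sample(an:(rl - an), n, replace = TRUE)
  data.frame(
    chrom_a = chrom_a, pos_a = as.integer(pos_a), strand_a = strand,
    chrom_b = chrom_b, pos_b = as.integer(pos_b), strand_b = strand,
    junction_type = 0L,
    read_name = sprintf("%s_decoy_%06d", sample_id, seq_len(n)),
    anchor_a = anchor_a, anchor_b = rl - anchor_a,
    stringsAsFactors = FALSE
  )
}

empty_chimeric <- function() {
  data.frame(
    chrom_a = character(), pos_a = integer(), strand_a = character(),
    chrom_b = character(), pos_b = integer(), strand_b = character(),
    junction_type = integer(), read_name = character(),
    anchor_a = integer(), anchor_b = integer(), stringsAsFactors = FALSE
  )
}

#' Write chimeric record tables to per-sample TSV files
#'
#' @param records Named list of chimeric data.frames.
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths.
#' @export
write_chimeric_files <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(names(records), function(s) {
    path <- file.path(dir, paste0(s, ".chimeric.tsv"))
    con <- file(path, "w")
    writeLines(paste0("# ", paste(names(empty_chimeric()), collapse = "\t")),
               con)
    if (nrow(records[[s]])) {
      write.table(records[[s]], con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    close(con)
    path
  }, character(1))
}
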