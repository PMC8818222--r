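# circRNA-miRNA-mRNA sponge network construction.
#
# Binding sites unique to the circular isoform span the back-splice joint, so
# prediction runs on a "junction probe": the last flank_nt of the spliced
# circ's 3' end reverse-joined to the first flank_nt of its 5' end. The
# duplex scorer is a local alignment of the reversed miRNA against the probe
# with miRanda-style parameters (Watson-Crick +5, G:U wobble +1, mismatch -3,
# gap open -9, gap extend -4, seed positions 2-8 weighted x4) and a per-pair
# energy sum (G:C -3, A:U -2, G:U -1 kcal/mol). The default acceptance
# thresholds are score > 170 and energy < -30 with a strict seed filter.

#' Spliced sequence of an annotated circRNA
#'
#' Concatenates the parental gene's exons lying inside the junction interval,
#' reverse-complementing for minus-strand genes, and returns an RNA string
#' (5' to 3' along the circular transcript).
#'
#' @param circ One-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `strand`, `gene_id`.
#' @param gene_models Gene model list from [generate_gene_models()] or a
#'   `genes` data.frame.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return A character scalar over the RNA alphabet.
#' @export
circ_spliced_seq <- function(circ, gene_models, genome) {
  genes <- if (is.data.frame(gene_models)) gene_models else gene_models$genes
  gx <- genes[genes$gene_id == circ$gene_id, , drop = FALSE]
  gx <- gx[gx$start >= circ$start & gx$end <= circ$end, , drop = FALSE]
  if (nrow(gx) == 0L || min(gx$start) != circ$start || max(gx$end) != circ$end) {
    stop("circ ends do not match exon boundaries of gene ", circ$gene_id)
  }
  gx <- gx[order(gx$start), , drop = FALSE]
  chrom_seq <- genome[[circ$chrom]]
  parts <- Biostrings::DNAStringSet(chrom_seq,
                                    start = gx$start + 1L, end = gx$end)
  dna <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (circ$strand == "-") dna <- Biostrings::reverseComplement(dna)
  as.character(Biostrings::RNAString(dna))
}

#' Build the back-splice junction probe for a circRNA
#'
#' @inheritParams circ_spliced_seq
#' @param flank_nt Flank length taken from each side of the joint (default
#'   30). Setting it to at least half the spliced length yields the full
#'   circ sequence rotated so the joint lies inside the probe
#'   (full-sequence scanning mode).
#' @return A list of class `junction_probe`: `circ_id`, `sequence` (RNA),
#'   `junction_offset` (the joint lies between positions `junction_offset`
#'   and `junction_offset + 1`).
#' @export
build_probe <- function(circ, gene_models, genome, flank_nt = 30L) {
  s <- circ_spliced_seq(circ, gene_models, genome)
  L <- nchar(s)
  take3 <- min(flank_nt, ceiling(L / 2))
  take5 <- min(flank_nt, L - take3)
  probe <- paste0(substr(s, L - take3 + 1L, L), substr(s, 1L, take5))
  structure(list(circ_id = circ$junction_id, sequence = probe,
                 junction_offset = take3),
            class = "junction_probe")
}

## ---- duplex scoring ------------------------------------------------------

.rna_clean <- function(x) {
  x <- toupper(gsub("T", "U", toupper(x)))
  if (grepl("[^ACGU]", x)) stop("non-nucleotide character in sequence")
  x
}

.pair_class <- function(a, b) {
  # a, b: single bases; returns "wc", "gu", or "mm"
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, "wc", ifelse(gu, "gu", "mm"))
}

#' Score a miRNA against a junction probe
#'
#' Local alignment (affine gaps) of the reversed miRNA against the probe;
#' pairing is read antiparallel, so a Watson-Crick pair is a complementary
#' base pair between the miRNA and the probe. Substitution scores at miRNA
#' seed positions 2-8 are multiplied by `params$seed_weight`.
#'
#' @param mirna_seq miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param probe A `junction_probe` from [build_probe()], or a plain sequence.
#' @param params Scoring parameters; see [duplex_params()].
#' @param strict Require miRNA positions 2-8 to be contiguously Watson-Crick
#'   paired with no gaps.
#' @return A list (`score`, `energy`, `alignment` data.frame of paired
#'   positions, `spans_junction`, `strict_ok`), or `NULL` if no positive-
#'   scoring alignment exists.
#' @export
duplex_score <- function(mirna_seq, probe, params = duplex_params(),
                         strict = TRUE) {
  probe_seq <- if (inherits(probe, "junction_probe")) probe$sequence else probe
  joint <- if (inherits(probe, "junction_probe")) probe$junction_offset else NA
  if (!nzchar(mirna_seq) || !nzchar(probe_seq)) stop("empty sequence")
  q <- strsplit(.rna_clean(mirna_seq), "")[[1]]
  s <- strsplit(.rna_clean(probe_seq), "")[[1]]
  M <- length(q)
  N <- length(s)
  qr <- rev(q)                       # reversed miRNA (3'->5')
  orig_pos <- rev(seq_len(M))        # original miRNA position of each row

  sub <- matrix(0, M, N)
  for (i in seq_len(M)) {
    cls <- .pair_class(qr[i], s)
    sc <- ifelse(cls == "wc", params$match,
                 ifelse(cls == "gu", params$wobble, params$mismatch))
    if (orig_pos[i] >= 2L && orig_pos[i] <= 8L) sc <- sc * params$seed_weight
    sub[i, ] <- sc
  }

  # affine-gap Smith-Waterman; H best ending in pair, E gap in query (skip
  # probe base), F gap in probe (skip miRNA base)
  H <- matrix(0, M + 1L, N + 1L)
  E <- matrix(-Inf, M + 1L, N + 1L)
  F_ <- matrix(-Inf, M + 1L, N + 1L)
  best <- 0
  bi <- 0L
  bj <- 0L
  for (i in 2L:(M + 1L)) {
    for (j in 2L:(N + 1L)) {
      E[i, j] <- max(H[i, j - 1L] + params$gap_open,
                     E[i, j - 1L] + params$gap_extend)
      F_[i, j] <- max(H[i - 1L, j] + params$gap_open,
                      F_[i - 1L, j] + params$gap_extend)
      diag <- H[i - 1L, j - 1L] + sub[i - 1L, j - 1L]
      h <- max(0, diag, E[i, j], F_[i, j])
      H[i, j] <- h
      if (h > best) {
        best <- h
        bi <- i
        bj <- j
      }
    }
  }
  if (best <= 0) return(NULL)

  # three-state traceback of the paired positions
  pairs <- list()
  i <- bi
  j <- bj
  state <- "H"
  while (i > 1L && j > 1L) {
    if (state == "H") {
      if (H[i, j] <= 0) break
      diag <- H[i - 1L, j - 1L] + sub[i - 1L, j - 1L]
      if (H[i, j] == diag) {
        pairs[[length(pairs) + 1L]] <-
          c(mirna_pos = orig_pos[i - 1L], probe_pos = j - 1L)
        i <- i - 1L
        j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      if (E[i, j] == H[i, j - 1L] + params$gap_open) state <- "H"
      j <- j - 1L
    } else {
      if (F_[i, j] == H[i - 1L, j] + params$gap_open) state <- "H"
      i <- i - 1L
    }
  }
  aln <- as.data.frame(do.call(rbind, rev(pairs)))
  aln$mirna_base <- q[aln$mirna_pos]
  aln$probe_base <- s[aln$probe_pos]
  aln$pair <- .pair_class(aln$mirna_base, aln$probe_base)

  pair_energy <- ifelse(
    aln$pair == "wc",
    ifelse((aln$mirna_base == "G" & aln$probe_base == "C") |
             (aln$mirna_base == "C" & aln$probe_base == "G"),
           params$energy_gc, params$energy_au),
    ifelse(aln$pair == "gu", params$energy_gu, 0)
  )
  energy <- sum(pair_energy)

  # strict seed: all of miRNA positions 2-8 Watson-Crick paired with no gap
  # inside the seed segment (contiguous on both strands)
  seed <- aln[aln$mirna_pos >= 2L & aln$mirna_pos <= 8L, , drop = FALSE]
  strict_ok <- nrow(seed) == 7L && all(seed$pair == "wc") &&
    all(diff(sort(seed$probe_pos)) == 1L)
  spans <- if (is.na(joint)) NA else
    any(aln$probe_pos <= joint) && any(aln$probe_pos > joint)

  res <- list(score = best, energy = energy, alignment = aln,
              spans_junction = spans, strict_ok = strict_ok)
  if (strict && !strict_ok) return(NULL)
  res
}

#' Duplex scoring parameters
#'
#' Defaults follow the miRanda-style parameterization used throughout the
#' package; all are overridable.
#'
#' @param match,wobble,mismatch Substitution scores (Watson-Crick, G:U, other).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param seed_weight Multiplier on substitution scores at miRNA positions
#'   2-8.
#' @param energy_gc,energy_au,energy_gu Per-pair energy terms (kcal/mol).
#' @return Named list of parameters.
#' @export
duplex_params <- function(match = 5, wobble = 1, mismatch = -3,
                          gap_open = -9, gap_extend = -4, seed_weight = 4,
                          energy_gc = -3, energy_au = -2, energy_gu = -1) {
  list(match = match, wobble = wobble, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       seed_weight = seed_weight, energy_gc = energy_gc,
       energy_au = energy_au, energy_gu = energy_gu)
}

#' Predict circRNA-miRNA interactions over all probe/miRNA pairs
#'
#' @param probes List of `junction_probe` objects.
#' @param mirnas Named character vector or [Biostrings::RNAStringSet] of
#'   mature miRNA sequences.
#' @param score_min,energy_max Acceptance thresholds: `score > score_min`
#'   and `energy < energy_max`.
#' @param strict Apply the strict seed filter.
#' @param params Scoring parameters, see [duplex_params()].
#' @return Data.frame of hits (`circ_id`, `mirna_id`, `score`, `energy`,
#'   `spans_junction`), sorted by circ then descending score.
#' @export
predict_circ_mirna <- function(probes, mirnas, score_min = 170,
                               energy_max = -30, strict = TRUE,
                               params = duplex_params()) {
  if (!is.character(mirnas)) mirnas <- as.character(mirnas)
  if (length(mirnas) == 0L) stop("empty miRNA set")
  if (is.null(names(mirnas))) stop("miRNA sequences must be named")
  hits <- list()
  for (p in probes) {
    for (m in names(mirnas)) {
      h <- duplex_score(mirnas[[m]], p, params = params, strict = strict)
      if (!is.null(h) && h$score > score_min && h$energy < energy_max) {
        hits[[length(hits) + 1L]] <- data.frame(
          circ_id = p$circ_id, mirna_id = m, score = h$score,
          energy = h$energy, spans_junction = isTRUE(h$spans_junction),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(circ_id = character(), mirna_id = character(),
                      score = numeric(), energy = numeric(),
                      spans_junction = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$circ_id, -out$score), , drop = FALSE]
}

#' Predict miRNA-mRNA edges by seed matching
#'
#' An edge is called when the reverse complement of miRNA positions 2-8
#' (7mer-m8 site) occurs in the 3'UTR; an adenosine opposite position 1
#' upgrades the class to 8mer.
#'
#' @param mirnas Named character vector (or `RNAStringSet`) of mature miRNAs.
#' @param utrs Named character vector (or `XStringSet`) of 3'UTR sequences,
#'   keyed by gene.
#' @return Data.frame with `mirna_id`, `gene_id`, `site_class`.
#' @export
predict_mirna_mrna <- function(mirnas, utrs) {
  if (!is.character(mirnas)) mirnas <- as.character(mirnas)
  if (!is.character(utrs)) utrs <- as.character(utrs)
  edges <- list()
  for (m in names(mirnas)) {
    seed <- substr(.rna_clean(mirnas[[m]]), 2L, 8L)
    site7 <- as.character(Biostrings::reverseComplement(
      Biostrings::RNAString(seed)))
    site8 <- paste0(site7, "A")
    for (g in names(utrs)) {
      utr <- .rna_clean(utrs[[g]])
      if (grepl(site7, utr, fixed = TRUE)) {
        cls <- if (grepl(site8, utr, fixed = TRUE)) "8mer" else "7mer-m8"
        edges[[length(edges) + 1L]] <- data.frame(
          mirna_id = m, gene_id = g, site_class = cls,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      site_class = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}

#' Co-expression edges between circRNAs and mRNAs
#'
#' Computes Pearson correlation (with its t-test p-value) per circ/mRNA pair
#' over samples where both are quantified, and keeps pairs with
#' `|r| >= r_min` and `p < p_max`. Raw p-values govern the filter;
#' Benjamini-Hochberg q-values are reported alongside.
#'
#' @param circ_fpkm,mrna_fpkm Feature x sample numeric matrices sharing
#'   sample columns.
#' @param r_min,p_max Edge thresholds (defaults 0.70 and 0.01).
#' @param pairs Optional data.frame (`circ_id`, `gene_id`) restricting the
#'   pairs tested; all pairs otherwise.
#' @return Data.frame `circ_id`, `gene_id`, `r`, `p`, `q`, `n` (edges only).
#' @export
coexpression_edges <- function(circ_fpkm, mrna_fpkm, r_min = 0.70,
                               p_max = 0.01, pairs = NULL) {
  shared <- intersect(colnames(circ_fpkm), colnames(mrna_fpkm))
  if (is.null(pairs)) {
    pairs <- expand.grid(circ_id = rownames(circ_fpkm),
                         gene_id = rownames(mrna_fpkm),
                         stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- circ_fpkm[pairs$circ_id[i], shared]
    y <- mrna_fpkm[pairs$gene_id[i], shared]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      warning("pair ", pairs$circ_id[i], " / ", pairs$gene_id[i],
              " skipped: fewer than 3 shared samples")
      return(NULL)
    }
    if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NULL)
    ct <- pearson_with_p(x[ok], y[ok])
    data.frame(circ_id = pairs$circ_id[i], gene_id = pairs$gene_id[i],
               r = ct$r, p = ct$p, n = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(circ_id = character(), gene_id = character(),
                      r = numeric(), p = numeric(), q = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  res$q <- p.adjust(res$p, method = "BH")
  keep <- abs(res$r) >= r_min & res$p < p_max
  res[keep, c("circ_id", "gene_id", "r", "p", "q", "n"), drop = FALSE]
}

#' Assemble the tripartite circRNA-miRNA-mRNA network
#'
#' @param circ_mirna Hits from [predict_circ_mirna()].
#' @param mirna_mrna Edges from [predict_mirna_mrna()].
#' @param coexpr Optional co-expression edges from [coexpression_edges()].
#' @param keep_isolated Keep nodes without any incident edge.
#' @return List with `nodes` (data.frame `node_id`, `node_type`) and `edges`
#'   (data.frame `source`, `target`, `edge_type`, `attr`).
#' @export
assemble_network <- function(circ_mirna, mirna_mrna, coexpr = NULL,
                             keep_isolated = FALSE) {
  e1 <- if (nrow(circ_mirna)) {
    data.frame(source = circ_mirna$circ_id, target = circ_mirna$mirna_id,
               edge_type = "circ-mirna",
               attr = sprintf("score=%g;energy=%g",
                              circ_mirna$score, circ_mirna$energy),
               stringsAsFactors = FALSE)
  }
  e2 <- if (nrow(mirna_mrna)) {
    data.frame(source = mirna_mrna$mirna_id, target = mirna_mrna$gene_id,
               edge_type = "mirna-mrna",
               attr = paste0("site=", mirna_mrna$site_class),
               stringsAsFactors = FALSE)
  }
  e3 <- if (!is.null(coexpr) && nrow(coexpr)) {
    data.frame(source = coexpr$circ_id, target = coexpr$gene_id,
               edge_type = "circ-mrna-coexpr",
               attr = sprintf("r=%.4f;p=%.4g", coexpr$r, coexpr$p),
               stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, Filter(Negate(is.null), list(e1, e2, e3)))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), attr = character(),
                        stringsAsFactors = FALSE)
  }
  node_of <- function(ids, type) {
    if (!length(ids)) return(NULL)
    data.frame(node_id = ids, node_type = type, stringsAsFactors = FALSE)
  }
  nodes <- unique(do.call(rbind, Filter(Negate(is.null), list(
    node_of(circ_mirna$circ_id, "circ"),
    node_of(if (!is.null(coexpr)) coexpr$circ_id else character(), "circ"),
    node_of(c(circ_mirna$mirna_id, mirna_mrna$mirna_id), "mirna"),
    node_of(c(mirna_mrna$gene_id,
              if (!is.null(coexpr)) coexpr$gene_id else character()), "mrna")
  ))))
  if (is.null(nodes)) {
    nodes <- data.frame(node_id = character(), node_type = character(),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("node ID used by more than one node class: ",
         nodes$node_id[duplicated(nodes$node_id)][1])
  }
  if (!keep_isolated && nrow(nodes)) {
    touched <- unique(c(edges$source, edges$target))
    nodes <- nodes[nodes$node_id %in% touched, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value per gene set, with fold enrichment and
#' Benjamini-Hochberg q-values.
#'
#' @param gene_list Character vector of selected genes (subset of universe).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all considered genes.
#' @return Data.frame `set`, `overlap`, `set_size`, `list_size`, `universe`,
#'   `fold_enrichment`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(gene_list, gene_sets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) stop("gene list not contained in universe")
  N <- length(universe)
  k <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set)
    x <- length(intersect(gene_list, set))
    p <- phyper(x - 1L, m, N - m, k, lower.tail = FALSE)
    fe <- if (m == 0L || k == 0L) NA_real_ else (x / k) / (m / N)
    data.frame(set = nm, overlap = x, set_size = m, list_size = k,
               universe = N, fold_enrichment = fe, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
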