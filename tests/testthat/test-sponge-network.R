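rc_rna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

probe_obj <- function(seq, offset, id = "circX") {
  structure(list(circ_id = id, sequence = seq, junction_offset = offset),
            class = "junction_probe")
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

test_that("junction probes are reverse-joined flanks of the spliced circ", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+", exon = 1L,
                      start = 100L, end = 300L, stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), length.out = 600), collapse = "")))
  circ <- data.frame(junction_id = "chr1:100|300:+", chrom = "chr1",
                     start = 100L, end = 300L, strand = "+", gene_id = "G1",
                     stringsAsFactors = FALSE)
  p <- build_probe(circ, genes, genome, flank_nt = 30L)
  expect_equal(nchar(p$sequence), 60L)
  expect_equal(p$junction_offset, 30L)
  s <- circ_spliced_seq(circ, genes, genome)
  expect_equal(p$sequence, paste0(substr(s, 171, 200), substr(s, 1, 30)))

  # short circ: full length, no duplication
  genes40 <- transform(genes, end = 140L)
  circ40 <- transform(circ, end = 140L, junction_id = "chr1:100|140:+")
  p40 <- build_probe(circ40, genes40, genome, flank_nt = 30L)
  expect_equal(nchar(p40$sequence), 40L)

  # minus strand equals the reverse-complement construction
  genes_m <- transform(genes, strand = "-")
  circ_m <- transform(circ, strand = "-")
  s_m <- circ_spliced_seq(circ_m, genes_m, genome)
  expect_equal(s_m, rc_rna(s))

  # junction ends must sit on exon boundaries
  expect_error(circ_spliced_seq(transform(circ, start = 101L), genes, genome),
               "exon boundaries")
})

test_that("duplex scorer reproduces the closed-form perfect-complement case", {
  # 22-nt miRNA with 11 G and 11 A: 11 G:C + 11 A:U pairs when bound to its
  # perfect complement; score 15*5 + 7*5*4 = 215, energy 11*(-3) + 11*(-2)
  set.seed(49)
  mirna <- "GAGAGAGAGAGAGAGAGAGAGA"
  probe <- probe_obj(paste0(rand_rna(19), rc_rna(mirna), rand_rna(19)), 30L)
  h <- duplex_score(mirna, probe, strict = TRUE)
  expect_equal(h$score, 5 * 15 + 5 * 7 * 4)
  expect_equal(h$energy, -3 * 11 - 2 * 11)
  expect_true(h$score > 170 && h$energy < -30)
  expect_true(h$strict_ok)
  # alignment pairs all Watson-Crick, probe positions strictly increasing
  expect_true(all(h$alignment$pair == "wc"))
  expect_true(all(diff(h$alignment$probe_pos) > 0))
})

test_that("strict mode rejects a seed mismatch that non-strict scores", {
  set.seed(50)
  mirna <- "UGAGGUAGUAGGUUGUAUAGUU"   # non-repetitive, so no sliding rescue
  site <- rc_rna(mirna)
  # probe base pairing miRNA position 4 is probe-site position 22 - 4 + 1
  pos <- 19L
  broken <- site
  substr(broken, pos, pos) <- "A"   # opposite G at position 4: mismatch
  probe <- probe_obj(paste0(rand_rna(10), broken, rand_rna(10)), 21L)
  expect_null(duplex_score(mirna, probe, strict = TRUE))
  h <- duplex_score(mirna, probe, strict = FALSE)
  expect_false(is.null(h))
  expect_lt(h$score, 215)
})

test_that("random decoy miRNAs never pass the (170, -30) thresholds", {
  set.seed(51)
  probe <- probe_obj(rand_rna(60), 30L)
  hits <- 0L
  for (i in 1:50) {
    h <- duplex_score(rand_rna(22), probe, strict = TRUE)
    if (!is.null(h) && h$score > 170 && h$energy < -30) hits <- hits + 1L
  }
  expect_equal(hits, 0L)
})

test_that("DP score matches exhaustive ungapped enumeration on short pairs", {
  set.seed(52)
  for (k in 1:40) {
    q <- rand_rna(sample(6:15, 1))
    s <- rand_rna(sample(6:15, 1))
    oracle <- oracle_duplex_ungapped(q, s)
    h <- duplex_score(q, probe_obj(s, 3L), strict = FALSE)
    got <- if (is.null(h)) 0 else h$score
    # gaps can only help, so the DP optimum is bounded below by the
    # enumeration; equality holds when the optimal trace is gap-free
    expect_gte(got, oracle)
    if (!is.null(h)) {
      gap_free <- all(diff(h$alignment$probe_pos) == 1) &&
        all(diff(h$alignment$mirna_pos) == -1)
      if (gap_free) expect_equal(got, oracle)
    }
  }
})

test_that("junction-spanning flag tracks the alignment footprint", {
  set.seed(48)
  mirna <- "UGAGGUAGUAGGUUGUAUAGUU"
  site <- rc_rna(mirna)
  # site entirely inside the first (3') flank: never spans
  p_in <- probe_obj(paste0(site, rand_rna(38)), 40L)
  h_in <- duplex_score(mirna, p_in)
  expect_false(h_in$spans_junction)
  # site crossing the joint: always spans
  p_cross <- probe_obj(paste0(rand_rna(19), site, rand_rna(19)), 30L)
  expect_true(duplex_score(mirna, p_cross)$spans_junction)
})

test_that("circ-miRNA prediction recovers planted pairs and filters
           monotonically", {
  co <- simulate_cohort(tiny_config(seed = 6L))
  hits <- predict_circ_mirna(co$mirna$probes, co$mirna$mirnas)
  planted <- co$truth$planted_sites
  found <- paste(hits$circ_id, hits$mirna_id)
  expect_true(all(paste(planted$circ_id, planted$mirna_id) %in% found))
  expect_true(all(hits$spans_junction[
    paste(hits$circ_id, hits$mirna_id) %in%
      paste(planted$circ_id, planted$mirna_id)]))

  expect_equal(nrow(predict_circ_mirna(co$mirna$probes, co$mirna$mirnas,
                                       score_min = Inf)), 0L)
  loose <- predict_circ_mirna(co$mirna$probes, co$mirna$mirnas, strict = FALSE)
  expect_gte(nrow(loose), nrow(hits))
  # tightening either threshold never adds hits
  tight <- predict_circ_mirna(co$mirna$probes, co$mirna$mirnas,
                              score_min = 200, energy_max = -40)
  expect_true(all(paste(tight$circ_id, tight$mirna_id) %in% found))
  expect_error(predict_circ_mirna(co$mirna$probes, character(0)), "empty")
})

test_that("seed matching finds planted UTR sites with the right class", {
  mirna <- c(m1 = "UGAGGUAGUAGGUUGUAUAGUU")
  seed7 <- rc_rna(substr(mirna[[1]], 2, 8))
  utr_hit <- paste0(rand_rna(40), seed7, rand_rna(40))
  utr_8mer <- paste0(rand_rna(40), seed7, "A", rand_rna(40))
  utr_miss <- gsub(substr(seed7, 1, 1), "", rand_rna(120))
  edges <- predict_mirna_mrna(mirna, c(gA = utr_hit, g8 = utr_8mer))
  expect_setequal(edges$gene_id, c("gA", "g8"))
  expect_equal(edges$site_class[edges$gene_id == "g8"], "8mer")
  expect_equal(edges$site_class[edges$gene_id == "gA"], "7mer-m8")

  # occurrence frequency in random UTRs matches the closed-form estimate
  set.seed(53)
  L <- 500L
  n_trials <- 200L
  hits <- sum(vapply(seq_len(n_trials), function(i) {
    nrow(predict_mirna_mrna(mirna, c(g = rand_rna(L)))) > 0
  }, logical(1)))
  p_closed <- 1 - (1 - 0.25^7)^(L - 6)
  expect_lt(abs(hits / n_trials - p_closed),
            3 * sqrt(p_closed * (1 - p_closed) / n_trials) + 0.01)
})

test_that("co-expression edges apply the joint |r| and p rule inclusively", {
  # engineered exact-boundary pair: the achieved r is used as the threshold
  set.seed(54)
  x <- rnorm(15)
  e <- residuals(lm(rnorm(15) ~ x))
  y <- 0.7 * scale(x)[, 1] + sqrt(1 - 0.49) * scale(e)[, 1]
  cm <- matrix(x, 1, 15, dimnames = list("circ1", paste0("s", 1:15)))
  mm <- matrix(y, 1, 15, dimnames = list("geneA", paste0("s", 1:15)))
  r_exact <- cor(x, y)
  edges <- coexpression_edges(cm, mm, r_min = r_exact, p_max = 0.01)
  expect_equal(nrow(edges), 1L)   # >= is inclusive at the boundary
  expect_equal(edges$r, r_exact)

  # null features: joint rule admits at most ~1% of pairs
  set.seed(55)
  cm0 <- matrix(rnorm(50 * 15), 50, 15,
                dimnames = list(paste0("c", 1:50), paste0("s", 1:15)))
  mm0 <- matrix(rnorm(10 * 15), 10, 15,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:15)))
  e0 <- coexpression_edges(cm0, mm0)
  expect_lte(nrow(e0) / 500, 0.01)

  # fewer than 3 shared samples: pair skipped with a warning
  cm3 <- cm[, 1:2, drop = FALSE]
  mm3 <- mm[, 1:2, drop = FALSE]
  expect_warning(coexpression_edges(cm3, mm3), "fewer than 3")
})

test_that("network assembly joins the tripartite edges and drops isolates", {
  cm <- data.frame(circ_id = "circ1", mirna_id = "miR-1", score = 200,
                   energy = -40, spans_junction = TRUE)
  mm <- data.frame(mirna_id = "miR-1", gene_id = "geneA",
                   site_class = "7mer-m8")
  net <- assemble_network(cm, mm)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)

  # no shared miRNA: two disconnected dyads
  mm2 <- data.frame(mirna_id = "miR-2", gene_id = "geneB",
                    site_class = "8mer")
  net2 <- assemble_network(cm, mm2)
  expect_equal(nrow(net2$edges), 2L)
  expect_setequal(net2$nodes$node_id, c("circ1", "miR-1", "miR-2", "geneB"))

  # conservation: every output edge is present in an input table
  expect_true(all(net2$edges$source %in% c(cm$circ_id, mm2$mirna_id)))

  # an ID used by two node classes is an error
  bad <- data.frame(mirna_id = "circ1", gene_id = "geneA",
                    site_class = "7mer-m8")
  expect_error(assemble_network(cm, bad), "node ID")
})

test_that("hypergeometric enrichment matches closed-form tails", {
  uni <- paste0("g", 1:10)
  # drawing all 3 set members in a 3-gene list: p = 1 / C(10,3)
  res <- hypergeom_enrichment(uni[1:3], list(S = uni[1:3]), uni)
  expect_equal(res$p, 1 / choose(10, 3))

  # list = set = universe: no enrichment possible
  expect_equal(hypergeom_enrichment(uni, list(S = uni), uni)$p, 1)
  # disjoint list and set
  expect_equal(hypergeom_enrichment(uni[1:3], list(S = uni[4:6]), uni)$p, 1)
  expect_error(hypergeom_enrichment("g1", list(S = "g1"), character(0)),
               "empty universe")
  expect_error(hypergeom_enrichment("zz", list(S = "g1"), uni), "universe")
})
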