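toy_counts <- function(det, samples) {
  # det: named list junction -> sample IDs with detection
  ids <- names(det)
  m <- matrix(0L, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in ids) m[j, det[[j]]] <- 1L
  m
}

test_that("brain-list exclusion is a validated set difference", {
  ids <- sprintf("chr1:%d|%d:+", c(10, 20, 30, 40, 50), c(90, 80, 85, 95, 99))
  excl <- ids[c(2, 4)]
  expect_equal(exclude_brain_list(ids, excl), ids[c(1, 3, 5)])
  expect_equal(exclude_brain_list(ids, character(0)), ids)
  expect_equal(exclude_brain_list(ids[1:2], ids), character(0))
  # idempotent
  expect_equal(exclude_brain_list(exclude_brain_list(ids, excl), excl),
               exclude_brain_list(ids, excl))

  path <- tempfile(fileext = ".tsv")
  writeLines(c("junction_id", ids[1], "not-a-junction"), path)
  expect_error(read_exclusion_list(path), "malformed junction ID at line 3")
  writeLines(c("junction_id", ids[1:2]), path)
  expect_equal(read_exclusion_list(path), ids[1:2])

  # coordinate-tolerance mode catches boundary jitter from other pipelines
  jittered <- "chr1:11|91:+"   # one off from ids[1] on both ends
  expect_equal(exclude_brain_list(ids[1], jittered), ids[1])
  expect_equal(exclude_brain_list(ids[1], jittered, tolerance_nt = 2L),
               character(0))
  expect_equal(exclude_brain_list(ids[2], jittered, tolerance_nt = 2L),
               ids[2])
})

test_that("tumor recurrence counts distinct patients only", {
  sam <- data.frame(
    sample_id = c("t1a", "t1b", "t2", "t3", "csf1"),
    patient_id = c("P1", "P1", "P2", "P3", "P1"),
    compartment = c("tissue", "tissue", "tissue", "tissue", "csf"),
    stringsAsFactors = FALSE
  )
  counts <- toy_counts(list(
    "chr1:1|10:+" = c("t1a", "t2"),    # two distinct patients
    "chr1:2|20:+" = c("t1a", "t1b"),   # two samples, one patient
    "chr1:3|30:+" = "t3"
  ), sam$sample_id)
  expect_equal(tumor_recurrence_filter(counts, sam, 2L), "chr1:1|10:+")
  expect_setequal(tumor_recurrence_filter(counts, sam, 1L), rownames(counts))
  expect_error(
    tumor_recurrence_filter(counts, sam[sam$compartment == "csf", ], 2L),
    "no tissue"
  )
})

test_that("cascade stage counts follow the toy fixture by hand", {
  ids <- sprintf("chr1:%d|%d:+", 1:6, 101:106)
  sam <- data.frame(
    sample_id = c("c1", "c2", "t1", "t2", "t3"),
    patient_id = c("P1", "P2", "P1", "P2", "P3"),
    compartment = c("csf", "csf", rep("tissue", 3)),
    stringsAsFactors = FALSE
  )
  csf <- toy_counts(setNames(rep(list("c1"), 6), ids), c("c1", "c2"))
  tissue <- toy_counts(list(
    # the four non-excluded circs: 3 recurrent in >= 2 patients, 1 not
    "chr1:3|103:+" = c("t1", "t2"),
    "chr1:4|104:+" = c("t1", "t3"),
    "chr1:5|105:+" = c("t2", "t3"),
    "chr1:6|106:+" = "t1"
  ), c("t1", "t2", "t3"))
  rep_ <- run_cascade(csf, tissue, sam, exclusion = ids[1:2])
  expect_equal(rep_$n_csf_total, 6L)
  expect_equal(rep_$n_after_brain_exclusion, 4L)
  expect_equal(rep_$n_after_tumor_recurrence, 3L)
  expect_equal(rep_$candidates, sort(ids[3:5]))
  # candidate order is lexicographic
  expect_equal(rep_$candidates, sort(rep_$candidates))

  # empty CSF detection: empty candidates, no error
  rep0 <- run_cascade(csf * 0L, tissue, sam, exclusion = character(0))
  expect_equal(rep0$candidates, character(0))
})

test_that("burden dichotomization uses the nearest-rank quantile", {
  d <- dichotomize_burden(c(P1 = 2, P2 = 4, P3 = 6, P4 = 8), quantile = 0.25)
  expect_equal(d$cutoff, 6L)
  expect_equal(d$groups,
               c(P1 = "deficient", P2 = "deficient", P3 = "deficient",
                 P4 = "abundant"))
  expect_false(d$degenerate)

  # all burdens at or below the cutoff: single group, flagged
  d2 <- dichotomize_burden(c(P1 = 1, P2 = 1, P3 = 1), quantile = 0.25)
  expect_true(d2$degenerate)

  # published convention: explicit cutoff 7 splits <= 7 vs > 7
  b <- c(P1 = 3, P2 = 7, P3 = 8, P4 = 12)
  d3 <- dichotomize_burden(b, cutoff = 7L)
  expect_equal(unname(d3$groups), c("deficient", "deficient", "abundant",
                                    "abundant"))
})

test_that("cascade is monotone in exclusion list, recurrence and samples", {
  co <- simulate_cohort(tiny_config(seed = 5L))
  sam <- co$expr$samples
  counts <- co$expr$circ_counts
  csf <- counts[, sam$sample_id[sam$compartment == "csf"], drop = FALSE]
  tis <- counts[, sam$sample_id[sam$compartment == "tissue"], drop = FALSE]
  base <- run_cascade(csf, tis, sam, co$truth$exclusion_list)

  bigger_excl <- c(co$truth$exclusion_list,
                   setdiff(rownames(counts), co$truth$exclusion_list)[1:5])
  expect_true(all(run_cascade(csf, tis, sam, bigger_excl)$candidates %in%
                    base$candidates))
  expect_true(all(
    run_cascade(csf, tis, sam, co$truth$exclusion_list,
                min_patients = 3L)$candidates %in% base$candidates
  ))
  # dropping one patient's tissue sample never adds candidates
  drop_s <- sam$sample_id[sam$compartment == "tissue"][1]
  expect_true(all(
    run_cascade(csf, tis[, setdiff(colnames(tis), drop_s), drop = FALSE],
                sam[sam$sample_id != drop_s, ],
                co$truth$exclusion_list)$candidates %in% base$candidates
  ))

  # dichotomization partitions all CSF-bearing patients
  expect_setequal(names(base$groups),
                  unique(sam$patient_id[sam$compartment == "csf"]))
  expect_true(all(base$groups %in% c("abundant", "deficient")))
})

test_that("cascade recovers the planted candidate set on simulated cohorts", {
  for (seed in 1:5) {
    co <- simulate_cohort(tiny_config(seed = seed))
    sam <- co$expr$samples
    counts <- co$expr$circ_counts
    rep_ <- run_cascade(
      counts[, sam$sample_id[sam$compartment == "csf"], drop = FALSE],
      counts[, sam$sample_id[sam$compartment == "tissue"], drop = FALSE],
      sam, co$truth$exclusion_list
    )
    expect_identical(rep_$candidates, co$truth$true_candidates)
  }
})
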