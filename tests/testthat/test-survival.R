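rec <- function(t, e) data.frame(os_months = t, event = e)

test_that("Kaplan-Meier product-limit arithmetic and median convention", {
  km <- km_estimate(rec(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  # all censored: flat curve, median not reached
  km0 <- km_estimate(rec(c(4, 6, 9), c(0, 0, 0)))
  expect_equal(length(km0$times), 0L)
  expect_true(is.na(km0$median))

  # single record with an event
  km1 <- km_estimate(rec(5, 1))
  expect_equal(km1$survival, 0)
  expect_equal(km1$median, 5)

  expect_error(km_estimate(rec(-1, 1)), "negative")

  # no censoring: KM equals the empirical survival function (hand oracle)
  set.seed(61)
  t <- round(rexp(20, 0.1), 3)
  km2 <- km_estimate(rec(t, rep(1, 20)))
  o <- oracle_km(t, rep(1, 20))
  expect_equal(km2$times, o$times)
  expect_equal(km2$survival, o$survival)
  expect_true(all(diff(km2$survival) <= 0))
})

test_that("reverse KM is KM with the event indicator flipped", {
  # all events: after flipping everything is censored -> median undefined
  expect_true(is.na(reverse_km_followup(rec(c(1, 2, 3), c(1, 1, 1)))))
  # all censored at 10 -> median follow-up 10
  expect_equal(reverse_km_followup(rec(rep(10, 4), rep(0, 4))), 10)
  # mixed toy: identical to km_estimate on a hand-flipped copy
  r6 <- rec(c(2, 5, 7, 8, 11, 13), c(1, 0, 0, 1, 0, 1))
  flipped <- rec(r6$os_months, 1L - r6$event)
  expect_equal(reverse_km_followup(r6), km_estimate(flipped)$median)
})

test_that("log-rank statistic matches hand computation and symmetries", {
  # two identical groups: statistic 0, p = 1
  r <- rec(c(1, 3, 5, 1, 3, 5), c(1, 1, 0, 1, 1, 0))
  lr <- logrank_test(r, c("A", "A", "A", "B", "B", "B"))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # A events at 1,2; B events at 3,4; no censoring:
  # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chi-square 2.882353
  r2 <- rec(c(1, 2, 3, 4), c(1, 1, 1, 1))
  lr2 <- logrank_test(r2, c("A", "A", "B", "B"))
  expect_equal(lr2$chisq, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-6)
  # label swap invariance
  lr2s <- logrank_test(r2, c("B", "B", "A", "A"))
  expect_equal(lr2s$chisq, lr2$chisq)

  expect_error(logrank_test(r2, rep("A", 4)), "2 non-empty groups")
})

test_that("Cox fit agrees with a partial-likelihood search oracle", {
  # two groups with identical survival: beta ~ 0, HR ~ 1
  r <- rec(c(1, 3, 5, 1, 3, 5), c(1, 1, 0, 1, 1, 0))
  r$grp <- c(0, 0, 0, 1, 1, 1)
  cx <- cox_fit(r, "grp")
  expect_equal(cx$beta, 0, tolerance = 1e-8)
  expect_equal(cx$hr, 1, tolerance = 1e-8)

  # tie-free random instances, n <= 8: maximum of the hand-coded partial
  # likelihood matches coxph to 1e-4
  set.seed(62)
  tested <- 0L
  while (tested < 8L) {
    n <- sample(5:8, 1)
    t <- rexp(n)
    e <- rbinom(n, 1, 0.8)
    x <- rnorm(n)
    if (sum(e) < 2L) next
    b_oracle <- oracle_cox_beta(t, e, x)
    if (abs(b_oracle) > 5) next   # near-separated instance
    d <- data.frame(os_months = t, event = e, x = x)
    cx <- cox_fit(d, "x")
    expect_equal(cx$beta, b_oracle, tolerance = 1e-4)
    tested <- tested + 1L
  }

  expect_error(cox_fit(transform(r, event = 0), "grp"), "no events")
  expect_error(cox_fit(transform(r, grp = 1), "grp"), "constant")

  # univariate mode fits each covariate alone
  set.seed(63)
  d2 <- data.frame(os_months = rexp(40), event = rbinom(40, 1, 0.8),
                   age = rnorm(40, 55, 8), sexm = rbinom(40, 1, 0.5))
  uni <- cox_fit(d2, c("age", "sexm"), univariate = TRUE)
  expect_equal(nrow(uni), 2L)
  expect_equal(uni$beta[1], cox_fit(d2, "age")$beta, tolerance = 1e-10)
  multi <- cox_fit(d2, c("age", "sexm"))
  expect_equal(nrow(multi), 2L)
  expect_true(all(multi$model == "multivariate"))
})

test_that("per-candidate survival scan flags degenerate splits and ranks the
           planted prognostic circ first", {
  set.seed(64)
  n <- 60L
  pats <- sprintf("P%02d", 1:n)
  cands <- sprintf("chr1:%d|%d:+", 1:12, 1001:1012)
  det <- matrix(rbinom(12 * n, 1, 0.5), 12, n,
                dimnames = list(cands, pats))
  det[1, ] <- rbinom(n, 1, 0.5)
  cfg <- cohort_config(n_patients = n, seed = 64L)
  groups <- setNames(ifelse(det[1, ] == 1, "abundant", "deficient"), pats)
  clin <- simulate_clinical(cfg, groups)
  fpkm <- det * 50

  tab <- per_circ_survival_scan(fpkm, clin, cands)
  expect_equal(nrow(tab), 12L)
  expect_false(any(tab$degenerate))
  # detected in every patient: degenerate row, not an error
  fpkm_all <- rbind(fpkm, matrix(10, 1, n,
                                 dimnames = list("chr1:99|199:+", pats)))
  tab2 <- per_circ_survival_scan(fpkm_all, clin,
                                 c(cands, "chr1:99|199:+"))
  expect_true(tab2$degenerate[tab2$junction_id == "chr1:99|199:+"])

  # recovery Monte-Carlo: the prognostic circ has the smallest q in >= 80%
  wins <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    det <- matrix(rbinom(12 * n, 1, 0.5), 12, n,
                  dimnames = list(cands, pats))
    groups <- setNames(ifelse(det[1, ] == 1, "abundant", "deficient"), pats)
    clin <- simulate_clinical(cohort_config(n_patients = n, seed = 1000L + s),
                              groups)
    tab <- per_circ_survival_scan(det * 50, clin, cands)
    ok <- !tab$degenerate
    if (which.min(tab$q[ok]) == which(tab$junction_id[ok] == cands[1])) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins / n_seeds, 0.8)
})
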