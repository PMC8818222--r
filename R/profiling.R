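# Compartment profiling: species sharing between samples, rank-based
# two-group comparisons, Pearson correlation with its t-test p-value, and an
# ordinal trend test across therapy lines.

#' Number of circRNA species shared by two samples
#'
#' @param a,b Count vectors over the same feature universe.
#' @return Integer count of features detected (> 0) in both.
#' @export
shared_species <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a > 0 & b > 0)
}

#' Number of species shared by three samples
#'
#' @param a,b,c Count vectors over the same feature universe.
#' @return Integer count detected in all three.
#' @export
shared_species3 <- function(a, b, c) {
  stopifnot(length(a) == length(b), length(b) == length(c))
  sum(a > 0 & b > 0 & c > 0)
}

#' Pairwise shared-species table across a cohort
#'
#' @param counts Feature x sample count matrix.
#' @param samples Sample sheet with `sample_id`, `patient_id`, `compartment`.
#' @param pseudocount Added before the log2 transform (default 1, so
#'   zero-shared pairs are representable).
#' @return Data.frame with one row per unordered sample pair: the two sample
#'   IDs, patients, compartments, `n_shared` and `log2_shared`.
#' @export
sharing_table <- function(counts, samples, pseudocount = 1) {
  ids <- samples$sample_id
  pairs <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  det <- counts[, ids, drop = FALSE] > 0
  n_shared <- vapply(seq_len(nrow(pairs)), function(k) {
    sum(det[, pairs[k, 1]] & det[, pairs[k, 2]])
  }, integer(1))
  data.frame(
    sample_a = ids[pairs[, 1]], sample_b = ids[pairs[, 2]],
    patient_a = samples$patient_id[pairs[, 1]],
    patient_b = samples$patient_id[pairs[, 2]],
    compartment_a = samples$compartment[pairs[, 1]],
    compartment_b = samples$compartment[pairs[, 2]],
    n_shared = n_shared,
    log2_shared = log2(n_shared + pseudocount),
    stringsAsFactors = FALSE
  )
}

#' Wilcoxon rank test (signed-rank or rank-sum)
#'
#' Exact p-values for small tie-free inputs, normal approximation with tie
#' correction otherwise (base R `wilcox.test` semantics).
#'
#' @param x,y Numeric vectors; equal length required when `paired`.
#' @param paired Signed-rank on paired differences vs two-sample rank-sum.
#' @return List with `statistic`, `p`, `method`.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    if (all(x == y)) stop("degenerate input: all paired differences are zero")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value, method = wt$method)
}

#' Pearson correlation with a t-distribution p-value
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Ordinal trend test across therapy lines
#'
#' Kendall-tau correlation between the values and the ordinal line index
#' (Jonckheere-style monotone-trend alternative), two-sided.
#'
#' @param values Numeric vector.
#' @param lines Ordered factor or integer therapy-line labels.
#' @return List with `tau`, `p`, `degenerate` (TRUE when the values or the
#'   labels carry no variation, in which case `tau`/`p` are `NA`).
#' @export
trend_over_lines <- function(values, lines) {
  ord <- if (is.factor(lines)) as.integer(lines) else as.integer(lines)
  if (length(unique(ord)) < 2L) stop("need at least 2 ordered groups")
  if (length(unique(values)) < 2L) {
    return(list(tau = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(values, ord, method = "kendall",
                                         alternative = "two.sided"))
  list(tau = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Percentages from a cohort characteristics count table
#'
#' Recomputes `100 * count / cohort size` for each characteristic row of a
#' demographic table (e.g. sex, smoking status, mutation carriers).
#'
#' @param tab Data.frame with columns `character` and `count`.
#' @param n Cohort size.
#' @return `tab` with a `pct` column appended.
#' @export
cohort_percentages <- function(tab, n) {
  stopifnot(n >= 1L, all(tab$count >= 0), all(tab$count <= n))
  tab$pct <- 100 * tab$count / n
  tab
}
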