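# Independent oracles used across the suite. Each re-derives a result from
# first principles (enumeration, direct formula, grid search) without calling
# the code path it checks.

# small cohort config for fast end-to-end runs
tiny_config <- function(seed = 1L, n_patients = 8L, ...) {
  cohort_config(n_patients = n_patients, n_genes = 25L, n_circ_total = 36L,
                n_candidates_true = 6L, n_brain_listed = 8L, seed = seed, ...)
}

# brute-force back-splice grouping straight from the definition
brute_backsplice <- function(records, min_reads = 1L) {
  acc <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$chrom_a != r$chrom_b || r$strand_a != r$strand_b) next
    if (r$strand_a == "+") {
      if (!(r$pos_b < r$pos_a - 1L)) next
      key <- paste(r$chrom_a, r$pos_b, r$pos_a - 1L, "+")
    } else {
      if (!(r$pos_a < r$pos_b - 1L)) next
      key <- paste(r$chrom_a, r$pos_a, r$pos_b - 1L, "-")
    }
    acc[[key]] <- (acc[[key]] %||% 0L) + 1L
  }
  acc <- acc[unlist(acc) >= min_reads]
  if (!length(acc)) {
    return(data.frame(junction_id = character(), count = integer()))
  }
  parts <- strsplit(names(acc), " ")
  ids <- vapply(parts, function(p) {
    sprintf("%s:%s|%s:%s", p[1], p[2], p[3], p[4])
  }, character(1))
  out <- data.frame(junction_id = ids, count = unlist(acc, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out[order(out$junction_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gap-free duplex optimum: best positive-sum window over every diagonal
oracle_duplex_ungapped <- function(mirna_seq, probe_seq,
                                   params = duplex_params()) {
  to_rna <- function(x) strsplit(toupper(gsub("T", "U", toupper(x))), "")[[1]]
  q <- rev(to_rna(mirna_seq))
  s <- to_rna(probe_seq)
  M <- length(q)
  N <- length(s)
  orig_pos <- rev(seq_len(M))
  pair_score <- function(a, b, pos) {
    wc <- paste0(a, b) %in% c("AU", "UA", "GC", "CG")
    gu <- paste0(a, b) %in% c("GU", "UG")
    sc <- if (wc) params$match else if (gu) params$wobble else params$mismatch
    if (pos >= 2 && pos <= 8) sc <- sc * params$seed_weight
    sc
  }
  best <- 0
  for (off in (-(M - 1L)):(N - 1L)) {
    i <- max(1L, 1L - off)
    run <- 0
    while (i <= M && i + off <= N) {
      sc <- pair_score(q[i], s[i + off], orig_pos[i])
      run <- max(0, run + sc)
      best <- max(best, run)
      i <- i + 1L
    }
  }
  best
}

# exact Mann-Whitney / signed-rank two-sided p by full enumeration (no ties)
oracle_wilcox_unpaired_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ranks <- seq_len(n + m)
  us <- apply(combos, 2, function(ix) sum(ranks[ix]) - n * (n + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

oracle_wilcox_paired_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% rk
  lo <- mean(vs <= v_obs)
  hi <- mean(vs >= v_obs)
  min(1, 2 * min(lo, hi))
}

# Cox partial likelihood for one covariate, maximized by golden-section
# search (independent of survival::coxph); assumes no tied event times
oracle_cox_beta <- function(time, event, x) {
  pll <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  stats::optimize(pll, c(-8, 8), maximum = TRUE, tol = 1e-9)$maximum
}

# direct TMM: doubly trimmed, inverse-variance-weighted mean of M-values
# for one column against a reference column
oracle_tmm_pair <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# product-limit survival by hand
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  list(times = ut, survival = surv)
}
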