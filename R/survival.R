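# Survival analysis keyed to candidate-circRNA detection burden: product-
# limit curves, reverse-KM follow-up, log-rank group comparison, and Cox
# proportional hazards (Efron ties) in univariate and multivariate modes.
# Overall survival runs from the diagnosis of brain metastases to death from
# any cause or last follow-up.

#' Kaplan-Meier product-limit estimate
#'
#' @param records Data.frame with `os_months` and `event` (1 death,
#'   0 censored); censored individuals at an event time remain at risk
#'   through that time.
#' @return List of class `km_curve`: `times` (event times), `survival`,
#'   `at_risk`, `median` (`NA` when the curve never reaches 0.5, i.e. median
#'   not reached).
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1L)
  if (any(records$os_months < 0)) stop("negative survival time")
  fit <- survival::survfit(
    survival::Surv(os_months, event) ~ 1, data = records,
    conf.type = "none"
  )
  ev <- fit$n.event > 0
  surv <- fit$surv[ev]
  times <- fit$time[ev]
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(list(times = times, survival = surv,
                 at_risk = fit$n.risk[ev], median = med),
            class = "km_curve")
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Applies the product-limit estimator with the event indicator flipped, so
#' censoring becomes the event of interest; returns that curve's median.
#'
#' @inheritParams km_estimate
#' @return Median follow-up in the time unit of `os_months` (`NA` if not
#'   reached).
#' @export
reverse_km_followup <- function(records) {
  flipped <- records
  flipped$event <- 1L - as.integer(records$event)
  km_estimate(flipped)$median
}

#' Log-rank test across groups
#'
#' @param records Data.frame with `os_months`, `event`.
#' @param grouping Vector of group labels aligned with `records` rows (or a
#'   column name in `records`).
#' @return List with `chisq`, `df`, `p`, `n_groups`.
#' @export
logrank_test <- function(records, grouping = "group") {
  g <- if (length(grouping) == 1L && is.character(grouping) &&
           grouping %in% names(records)) records[[grouping]] else grouping
  g <- as.factor(g)
  if (nlevels(droplevels(g)) < 2L) stop("need >= 2 non-empty groups")
  records$.group <- droplevels(g)
  sd_ <- survival::survdiff(survival::Surv(os_months, event) ~ .group,
                            data = records)
  df <- length(sd_$n) - 1L
  list(chisq = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df = df, lower.tail = FALSE),
       n_groups = length(sd_$n))
}

#' Cox proportional hazards fit (Efron ties)
#'
#' @param records Clinical data.frame.
#' @param covariates Character vector of covariate column names.
#' @param univariate Fit each covariate alone (`TRUE`) or jointly.
#' @return Data.frame with one row per coefficient: `model`, `term`, `beta`,
#'   `hr`, `ci_lo`, `ci_hi` (95%), `se`, `p` (Wald).
#' @export
cox_fit <- function(records, covariates, univariate = FALSE) {
  if (sum(records$event) < 1L) stop("no events in data")
  const <- covariates[vapply(covariates, function(v) {
    length(unique(records[[v]])) < 2L
  }, logical(1))]
  if (length(const)) {
    stop("covariate constant across records: ", paste(const, collapse = ", "))
  }
  fit_one <- function(vars, label) {
    fml <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                   paste(vars, collapse = " + ")))
    fit <- survival::coxph(fml, data = records, ties = "efron")
    s <- summary(fit)
    data.frame(
      model = label, term = rownames(s$coefficients),
      beta = s$coefficients[, "coef"],
      hr = s$coefficients[, "exp(coef)"],
      ci_lo = s$conf.int[, "lower .95"],
      ci_hi = s$conf.int[, "upper .95"],
      se = s$coefficients[, "se(coef)"],
      p = s$coefficients[, "Pr(>|z|)"],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (univariate) {
    do.call(rbind, lapply(covariates, function(v) fit_one(v, "univariate")))
  } else {
    fit_one(covariates, "multivariate")
  }
}

#' Per-candidate survival scan
#'
#' Dichotomizes patients per candidate circRNA -- by detection (FPKM or
#' count > 0) or by median FPKM -- then runs a log-rank test and a univariate
#' Cox fit for each. Raw p-values are reported with Benjamini-Hochberg
#' q-values alongside.
#'
#' @param circ_fpkm Candidates x patients matrix (CSF expression, columns
#'   named by patient).
#' @param records Clinical data.frame with `patient_id`, `os_months`,
#'   `event`.
#' @param candidates Character vector of candidate junction IDs (rows of
#'   `circ_fpkm`).
#' @param split `"detection"` (> 0) or `"median"` FPKM dichotomization.
#' @return Data.frame, one row per candidate: `junction_id`, `n_high`,
#'   `n_low`, `logrank_p`, `cox_beta`, `cox_hr`, `cox_p`, `degenerate`, `q`
#'   (BH over non-degenerate log-rank p-values).
#' @export
per_circ_survival_scan <- function(circ_fpkm, records, candidates,
                                   split = c("detection", "median")) {
  split <- match.arg(split)
  pats <- intersect(colnames(circ_fpkm), records$patient_id)
  if (length(pats) < 4L) stop("need CSF quantification for >= 4 patients")
  rec <- records[match(pats, records$patient_id), , drop = FALSE]
  rows <- lapply(candidates, function(id) {
    x <- circ_fpkm[id, pats]
    high <- if (split == "detection") x > 0 else x > median(x)
    out <- data.frame(junction_id = id, n_high = sum(high),
                      n_low = sum(!high), logrank_p = NA_real_,
                      cox_beta = NA_real_, cox_hr = NA_real_,
                      cox_p = NA_real_, degenerate = FALSE,
                      stringsAsFactors = FALSE)
    if (length(unique(high)) < 2L) {
      out$degenerate <- TRUE
      return(out)
    }
    lr <- logrank_test(rec, ifelse(high, "high", "low"))
    rec$.high <- as.integer(high)
    cx <- tryCatch(cox_fit(rec, ".high"), error = function(e) NULL)
    out$logrank_p <- lr$p
    if (!is.null(cx)) {
      out$cox_beta <- cx$beta
      out$cox_hr <- cx$hr
      out$cox_p <- cx$p
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  ok <- !tab$degenerate
  tab$q[ok] <- p.adjust(tab$logrank_p[ok], method = "BH")
  tab
}
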