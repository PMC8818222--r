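# Clinical outcome simulation. Overall survival is exponential with the
# baseline hazard set by the deficient-group median OS; the circRNA-abundant
# group's hazard is multiplied by hazard_ratio_abundant. Censoring is
# independent uniform on [0, max_followup], so the censoring median (what a
# reverse Kaplan-Meier estimates) is max_followup / 2. ctDNA concentration is
# drawn with a Gaussian copula against log CSF circRNA abundance, targeting
# the configured negative correlation.

#' Simulate the clinical table and ctDNA concentrations
#'
#' @param config A [cohort_config()].
#' @param groups Named character vector (patient_id -> "abundant" or
#'   "deficient").
#' @param csf_abundance Optional named numeric vector (patient_id -> total
#'   CSF circRNA abundance) used to anchor ctDNA; simulated when omitted.
#' @param seed_offset Internal RNG offset so the clinical draw is independent
#'   of the expression draw under the same config seed.
#' @return Data.frame with `patient_id`, `os_months`, `event`, `age`, `sex`,
#'   `smoking`, `metastasis`, `group`, `ctdna`.
#' @export
simulate_clinical <- function(config, groups, csf_abundance = NULL,
                              seed_offset = 606L) {
  validate_cohort_config(config)
  if (config$hazard_ratio_abundant <= 0) {
    stop("invalid config: hazard_ratio_abundant must be > 0")
  }
  set.seed(config$seed + seed_offset)
  pats <- names(groups)
  n <- length(pats)
  stopifnot(n >= 1L, all(groups %in% c("abundant", "deficient")))

  base_rate <- log(2) / config$baseline_median_os
  rate <- base_rate *
    ifelse(groups == "abundant", config$hazard_ratio_abundant, 1)
  t_event <- rexp(n, rate = rate)
  t_cens <- runif(n, 0, config$max_followup)
  os <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  age <- round(pmin(pmax(rnorm(n, 55, 8), 39), 74))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(12, 9) / 21)
  smoking <- rbinom(n, 1L, 6 / 21)
  metastasis <- rbinom(n, 1L, 18 / 21)

  if (is.null(csf_abundance)) {
    csf_abundance <- setNames(exp(rnorm(n, log(1000), 1)), pats)
  }
  z_ab <- scale(log1p(csf_abundance[pats]))[, 1]
  z_ab[is.na(z_ab)] <- 0
  rho <- config$ctdna_rho
  ctdna <- exp(1 + 0.8 * (rho * z_ab + sqrt(1 - rho^2) * rnorm(n)))
  ctdna[is.na(csf_abundance[pats])] <- NA_real_

  data.frame(
    patient_id = pats, os_months = os, event = event,
    age = age, sex = sex, smoking = smoking, metastasis = metastasis,
    group = unname(groups), ctdna = ctdna,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
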