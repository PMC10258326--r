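#' Simulate a two-arm trial with exponential survival and a fixed hazard ratio
#'
#' Draws exponential event times in a control arm (PC) with the given median
#' and in a treatment arm (TC) whose hazard is `hazard_ratio` times the
#' control hazard, allocated `allocation_ratio` TC:PC, with fixed
#' administrative censoring.
#'
#' @param n_total Total subjects.
#' @param allocation_ratio Length-2 TC:PC parts.
#' @param control_median Control-arm median survival (months).
#' @param hazard_ratio True TC:PC hazard ratio.
#' @param censor_time Administrative censoring time (months).
#' @param seed Optional local seed.
#' @return Data frame with columns `time`, `event`, `arm` (factor, `PC`
#'   reference).
#' @export
simulate_hr_trial <- function(n_total = 465, allocation_ratio = c(2, 1),
                              control_median = 5.6, hazard_ratio = 0.49,
                              censor_time = 16.2, seed = NULL) {
  draw <- function() {
    n_tc <- round(n_total * allocation_ratio[1] / sum(allocation_ratio))
    n_pc <- n_total - n_tc
    rate_pc <- log(2) / control_median
    t <- c(stats::rexp(n_tc, rate_pc * hazard_ratio), stats::rexp(n_pc, rate_pc))
    arm <- factor(rep(c("TC", "PC"), c(n_tc, n_pc)), levels = c("PC", "TC"))
    data.frame(time = pmin(t, censor_time),
               event = as.integer(t <= censor_time), arm = arm)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Cox proportional-hazards hazard ratio for a two-arm trial
#'
#' @param data Data frame with `time`, `event`, `arm` (reference level
#'   first).
#' @return The estimated hazard ratio (treatment vs reference).
#' @export
cox_hazard_ratio <- function(data) {
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, data = data)
  unname(exp(stats::coef(fit)))
}

#' Median-recovery protocol for a censored log-normal endpoint
#'
#' Repeatedly simulates `n` log-normal event times with the target median
#' under uniform-accrual administrative censoring, fits a log-normal by
#' censored maximum likelihood, and averages the fitted medians across
#' replicates. This is the calibration check that a fitted extrapolation
#' distribution reproduces a trial's published median.
#'
#' @param n Subjects per replicate.
#' @param median_months True (and target) median, months.
#' @param log_sd Log-scale SD.
#' @param followup_median Median follow-up (months) of the censoring scheme,
#'   or `NULL` for no censoring.
#' @param n_replicates Number of seeded replicates (default 200).
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @return List: `mean_median` (average fitted median), `medians`
#'   (per-replicate), `n`, `n_replicates`.
#' @export
median_recovery <- function(n, median_months, log_sd = 0.9,
                            followup_median = 16.2, n_replicates = 200,
                            seed = 1L) {
  meds <- vapply(seq_len(n_replicates), function(i) {
    ipd <- simulate_survival_arm(n, median_months, log_sd,
                                 followup_median = followup_median,
                                 seed = seed + i)
    fitted_median(fit_distribution(ipd, "lognormal"))
  }, numeric(1))
  list(mean_median = mean(meds), medians = meds, n = n,
       n_replicates = n_replicates)
}

#' Hazard-ratio-recovery protocol for a two-arm exponential trial
#'
#' Repeatedly simulates the trial of [simulate_hr_trial()], fits a Cox
#' model per replicate, and summarizes the estimated hazard ratios by their
#' median.
#'
#' @inheritParams simulate_hr_trial
#' @param n_replicates Number of seeded replicates (default 200).
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @return List: `median_hr`, `hrs` (per-replicate), `n_total`,
#'   `n_replicates`.
#' @export
hr_recovery <- function(n_total = 465, allocation_ratio = c(2, 1),
                        control_median = 5.6, hazard_ratio = 0.49,
                        censor_time = 16.2, n_replicates = 200, seed = 1L) {
  hrs <- vapply(seq_len(n_replicates), function(i) {
    cox_hazard_ratio(simulate_hr_trial(n_total, allocation_ratio,
                                       control_median, hazard_ratio,
                                       censor_time, seed = seed + i))
  }, numeric(1))
  list(median_hr = stats::median(hrs), hrs = hrs, n_total = n_total,
       n_replicates = n_replicates)
}
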