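#' Specify a synthetic two-arm immunotherapy trial
#'
#' Parameters for a simulated randomized trial of an immunotherapy+chemo arm
#' (TC) versus chemo alone (PC), with log-normal progression-free and overall
#' survival. Defaults emulate a 465-patient, 2:1-randomized first-line NSCLC
#' trial: TC/PC median PFS 8.3/5.6 months, PC median OS 17.1 months, and a
#' median follow-up of 16.2 months. The trial's TC-arm median OS was not
#' reached at data cut-off, so the default of 28 months is a placeholder for
#' an unobserved tail and should be treated as such.
#'
#' @param n_total Total subjects across arms (>= 10).
#' @param allocation_ratio Length-2 integer vector, TC:PC allocation parts.
#' @param pfs_median_tc,pfs_median_pc Target median PFS (months) per arm.
#' @param os_median_tc,os_median_pc Target median OS (months) per arm.
#' @param log_sd_pfs,log_sd_os Log-scale standard deviations of the
#'   log-normal event-time distributions (dimensionless).
#' @param followup_median Median follow-up (months) produced by the
#'   uniform-accrual administrative censoring scheme.
#' @param seed Integer seed; identical seeds give identical trials.
#' @return An object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(n_total = 465,
                                 allocation_ratio = c(2, 1),
                                 pfs_median_tc = 8.3, pfs_median_pc = 5.6,
                                 os_median_tc = 28, os_median_pc = 17.1,
                                 log_sd_pfs = 0.9, log_sd_os = 0.9,
                                 followup_median = 16.2,
                                 seed = 1L) {
  if (n_total < 10) stop("n_total must be >= 10", call. = FALSE)
  if (length(allocation_ratio) != 2 || any(allocation_ratio <= 0)) {
    stop("allocation_ratio must be two positive parts", call. = FALSE)
  }
  meds <- c(pfs_median_tc, pfs_median_pc, os_median_tc, os_median_pc)
  if (any(meds <= 0)) stop("medians must be positive", call. = FALSE)
  if (pfs_median_tc >= os_median_tc || pfs_median_pc >= os_median_pc) {
    stop("PFS median must be below OS median within each arm", call. = FALSE)
  }
  structure(
    list(n_total = as.integer(n_total), allocation_ratio = allocation_ratio,
         pfs_median_tc = pfs_median_tc, pfs_median_pc = pfs_median_pc,
         os_median_tc = os_median_tc, os_median_pc = os_median_pc,
         log_sd_pfs = log_sd_pfs, log_sd_os = log_sd_os,
         followup_median = followup_median, seed = as.integer(seed)),
    class = "synthetic_trial_spec"
  )
}

# Administrative censoring times under uniform accrual: subjects enter
# uniformly over an accrual window of half the target median follow-up, and
# the database locks at 1.25 x that median, so per-subject follow-up is
# uniform on [0.75, 1.25] x followup_median with the stated median.
accrual_censor_times <- function(n, followup_median) {
  stats::runif(n, 0.75 * followup_median, 1.25 * followup_median)
}

#' Calibrate the progression-fraction Beta distribution
#'
#' In the synthetic trial, per-subject PFS is drawn as OS times a Beta
#' fraction, which enforces PFS <= OS structurally. The Beta mean (at fixed
#' concentration) is solved so that the marginal median of the product equals
#' the target PFS median, using numerical integration of
#' P(OS x B <= m_target) over the Beta density and 1-D root finding.
#'
#' @param pfs_median Target marginal PFS median (months).
#' @param os_median Median of the log-normal OS distribution (months).
#' @param log_sd_os Log-scale SD of OS.
#' @param concentration Beta concentration (alpha + beta), default 4.
#' @return Named vector with Beta `shape1` and `shape2`.
#' @export
calibrate_pfs_fraction <- function(pfs_median, os_median, log_sd_os,
                                   concentration = 4) {
  stopifnot(pfs_median < os_median)
  # P(OS x B <= m) = E_Z[ P(B <= m / (m_os e^{sd Z})) ] with Z standard
  # normal; integrating over Z keeps the integrand bounded and uses the
  # accurate pbeta rather than Beta quantiles.
  p_below <- function(mu) {
    a <- mu * concentration; b <- (1 - mu) * concentration
    stats::integrate(function(z) {
      stats::dnorm(z) *
        stats::pbeta(pmin(1, pfs_median / (os_median * exp(log_sd_os * z))), a, b)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  # p_below is decreasing in the Beta mean
  root <- stats::uniroot(function(mu) p_below(mu) - 0.5,
                         lower = 1e-4, upper = 1 - 1e-4, tol = 1e-10)
  mu <- root$root
  c(shape1 = mu * concentration, shape2 = (1 - mu) * concentration)
}

#' Simulate one arm/endpoint of log-normal survival data
#'
#' Draws `n` log-normal event times with the given median and log-scale SD
#' and, optionally, applies uniform-accrual administrative censoring with the
#' given median follow-up. This is the building block the synthetic-trial
#' generator uses for overall survival, and is the reference protocol for
#' median-recovery exercises against published trial medians.
#'
#' @param n Number of subjects.
#' @param median_months Median event time (months); the log-normal log-mean
#'   is `log(median_months)`.
#' @param log_sd Log-scale SD.
#' @param followup_median Median follow-up in months for administrative
#'   censoring, or `NULL` for fully observed times.
#' @param endpoint,arm Labels for the returned object.
#' @param seed Optional seed applied locally.
#' @return A `pseudo_ipd`.
#' @examples
#' simulate_survival_arm(100, median_months = 8.3, log_sd = 0.9,
#'                       followup_median = 16.2, seed = 1)
#' @export
simulate_survival_arm <- function(n, median_months, log_sd,
                                  followup_median = NULL,
                                  endpoint = "PFS", arm = "TC", seed = NULL) {
  draw <- function() {
    t_true <- stats::rlnorm(n, meanlog = log(median_months), sdlog = log_sd)
    if (is.null(followup_median)) {
      pseudo_ipd(t_true, rep(1L, n), endpoint = endpoint, arm = arm)
    } else {
      cens <- accrual_censor_times(n, followup_median)
      pseudo_ipd(pmin(t_true, cens), as.integer(t_true <= cens),
                 endpoint = endpoint, arm = arm)
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic two-arm trial
#'
#' Simulates pseudo individual-patient data for both arms and both endpoints.
#' Overall survival is log-normal with the arm's target median; PFS is OS
#' times a Beta-distributed fraction calibrated (see
#' [calibrate_pfs_fraction()]) so the marginal PFS median hits its target
#' while PFS <= OS holds for every subject. Both endpoints of a subject share
#' one administrative censoring time from the uniform-accrual scheme.
#'
#' @param spec A [synthetic_trial_spec()].
#' @return A named list of `pseudo_ipd` objects with keys `TC_PFS`, `TC_OS`,
#'   `PC_PFS`, `PC_OS`.
#' @examples
#' trial <- generate_synthetic_trial(synthetic_trial_spec(n_total = 60, seed = 7))
#' sapply(trial, nrow)
#' @export
generate_synthetic_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  parts <- spec$allocation_ratio
  n_tc <- round(spec$n_total * parts[1] / sum(parts))
  n_pc <- spec$n_total - n_tc

  sim_arm <- function(n, arm, pfs_median, os_median) {
    beta_par <- calibrate_pfs_fraction(pfs_median, os_median, spec$log_sd_os)
    os_true <- stats::rlnorm(n, log(os_median), spec$log_sd_os)
    frac <- stats::rbeta(n, beta_par["shape1"], beta_par["shape2"])
    pfs_true <- os_true * frac
    cens <- accrual_censor_times(n, spec$followup_median)
    list(
      PFS = pseudo_ipd(pmin(pfs_true, cens), as.integer(pfs_true <= cens),
                       endpoint = "PFS", arm = arm),
      OS = pseudo_ipd(pmin(os_true, cens), as.integer(os_true <= cens),
                      endpoint = "OS", arm = arm)
    )
  }

  with_seed(spec$seed, {
    tc <- sim_arm(n_tc, "TC", spec$pfs_median_tc, spec$os_median_tc)
    pc <- sim_arm(n_pc, "PC", spec$pfs_median_pc, spec$os_median_pc)
    list(TC_PFS = tc$PFS, TC_OS = tc$OS, PC_PFS = pc$PFS, PC_OS = pc$OS)
  })
}
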