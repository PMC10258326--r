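#' Model settings for the partitioned survival engine
#'
#' @param cycle_length_days Model cycle length in days (default 21, i.e. one
#'   3-week treatment cycle).
#' @param horizon_years Time horizon in years (default 10).
#' @param discount_rate_costs,discount_rate_effects Annual discount rates as
#'   fractions (default 0.05 for both).
#' @param half_cycle_correction Apply the trapezoidal half-cycle correction
#'   to person-time in state (default `TRUE`).
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_length_days = 21, horizon_years = 10,
                           discount_rate_costs = 0.05,
                           discount_rate_effects = 0.05,
                           half_cycle_correction = TRUE) {
  if (cycle_length_days <= 0) stop("cycle_length_days must be > 0", call. = FALSE)
  if (horizon_years * DAYS_PER_YEAR < cycle_length_days) {
    stop("horizon shorter than one cycle", call. = FALSE)
  }
  if (discount_rate_costs < 0 || discount_rate_effects < 0) {
    stop("discount rates must be >= 0", call. = FALSE)
  }
  structure(
    list(cycle_length_days = cycle_length_days, horizon_years = horizon_years,
         discount_rate_costs = discount_rate_costs,
         discount_rate_effects = discount_rate_effects,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "model_settings"
  )
}

#' Discount factor
#'
#' Standard annual-compounding discounting, \eqn{(1+r)^{-t}} with `t` in
#' years. Per-cycle quantities in the engine are discounted at cycle
#' midpoints, which pairs naturally with the half-cycle correction.
#'
#' @param t_years Time since model start, in years.
#' @param rate Annual discount rate (fraction).
#' @return Discount multiplier(s) in `(0, 1]`.
#' @examples
#' discount_factor(1, 0.05)  # 1/1.05
#' @export
discount_factor <- function(t_years, rate) {
  stopifnot(all(t_years >= 0), rate >= 0)
  (1 + rate)^(-t_years)
}

#' State occupancy from fitted PFS and OS curves
#'
#' Core partitioned-survival computation: at each cycle boundary the
#' progression-free proportion is the fitted PFS survival, the dead
#' proportion is one minus fitted OS survival, and progressive disease is
#' the difference. Independently fitted PFS can cross above OS in the tail;
#' PFS is clamped to `min(S_pfs, S_os)` so PD stays non-negative and the
#' three states always sum to one.
#'
#' @param pfs_fit,os_fit `psm_fit` objects for the arm's PFS and OS.
#' @param settings A [model_settings()].
#' @return An `occupancy_trace`: data frame with columns `cycle` (0-based
#'   boundary index), `time_months`, `pfs`, `pd`, `dead`, `new_deaths`
#'   (deaths during the cycle ending at this boundary; 0 at cycle 0).
#' @export
occupancy_trace <- function(pfs_fit, os_fit, settings = model_settings()) {
  stopifnot(inherits(settings, "model_settings"))
  n_cycles <- floor(settings$horizon_years * DAYS_PER_YEAR /
                      settings$cycle_length_days)
  if (n_cycles < 1) stop("horizon shorter than one cycle", call. = FALSE)
  t_days <- (0:n_cycles) * settings$cycle_length_days
  t_months <- days_to_months(t_days)
  s_os <- survival_at(os_fit, t_months)
  s_pfs <- pmin(survival_at(pfs_fit, t_months), s_os)
  pd <- s_os - s_pfs
  dead <- 1 - s_os
  trace <- data.frame(cycle = 0:n_cycles, time_months = t_months,
                      pfs = s_pfs, pd = pd, dead = dead,
                      new_deaths = c(0, diff(dead)))
  attr(trace, "settings") <- settings
  class(trace) <- c("occupancy_trace", "data.frame")
  trace
}

#' Per-cycle person-time in each state
#'
#' With the half-cycle correction on, person-time in a state during cycle
#' `k` (boundaries `k-1 -> k`) is the trapezoid
#' `cycle_length x (s_{k-1} + s_k)/2`; with it off, the start-of-cycle
#' occupancy is carried through the whole cycle. Times are returned in
#' months.
#'
#' @param trace An [occupancy_trace()].
#' @param settings A [model_settings()]; defaults to the trace's own.
#' @return Data frame with one row per cycle (1-based) and columns `cycle`,
#'   `t_mid_months`, `pfs_months`, `pd_months`, `alive_months`.
#' @export
half_cycle_time_in_state <- function(trace, settings = attr(trace, "settings")) {
  stopifnot(inherits(trace, "occupancy_trace"))
  cl_m <- days_to_months(settings$cycle_length_days)
  n <- nrow(trace) - 1
  idx0 <- 1:n; idx1 <- 2:(n + 1)
  w <- function(s) {
    if (settings$half_cycle_correction) (s[idx0] + s[idx1]) / 2 else s[idx0]
  }
  data.frame(
    cycle = 1:n,
    t_mid_months = (trace$time_months[idx0] + trace$time_months[idx1]) / 2,
    pfs_months = cl_m * w(trace$pfs),
    pd_months = cl_m * w(trace$pd),
    alive_months = cl_m * (w(trace$pfs) + w(trace$pd))
  )
}

#' Discounted and undiscounted life-year summary of a trace
#'
#' @param trace An [occupancy_trace()].
#' @param settings A [model_settings()]; defaults to the trace's own.
#' @return Named list: `life_years`, `disc_life_years`, `pfs_years`,
#'   `disc_pfs_years`, `pd_years`, `disc_pd_years` (discounting at the
#'   effects rate, cycle midpoints).
#' @export
trace_life_years <- function(trace, settings = attr(trace, "settings")) {
  tis <- half_cycle_time_in_state(trace, settings)
  disc <- discount_factor(months_to_years(tis$t_mid_months),
                          settings$discount_rate_effects)
  m2y <- DAYS_PER_MONTH / DAYS_PER_YEAR
  list(
    life_years = sum(tis$alive_months) * m2y,
    disc_life_years = sum(tis$alive_months * disc) * m2y,
    pfs_years = sum(tis$pfs_months) * m2y,
    disc_pfs_years = sum(tis$pfs_months * disc) * m2y,
    pd_years = sum(tis$pd_months) * m2y,
    disc_pd_years = sum(tis$pd_months * disc) * m2y
  )
}

#' Export an occupancy trace to CSV
#'
#' Columns: cycle, time_months, pfs, pd, dead, new_deaths,
#' disc_factor_cost, disc_factor_effect (midpoint factors; NA at cycle 0).
#'
#' @param trace An [occupancy_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  settings <- attr(trace, "settings")
  t_mid <- c(NA, (trace$time_months[-nrow(trace)] + trace$time_months[-1]) / 2)
  out <- data.frame(
    trace,
    disc_factor_cost = ifelse(is.na(t_mid), NA,
                              discount_factor(months_to_years(ifelse(is.na(t_mid), 0, t_mid)),
                                              settings$discount_rate_costs)),
    disc_factor_effect = ifelse(is.na(t_mid), NA,
                                discount_factor(months_to_years(ifelse(is.na(t_mid), 0, t_mid)),
                                                settings$discount_rate_effects))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
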