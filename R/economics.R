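#' Strategy economics for one arm
#'
#' Bundles the arm label with the configuration slices the cost/QALY
#' accumulators need (prices, dosing, schedules, second-line mix, utilities,
#' adverse events).
#'
#' @param arm `"TC"` (toripalimab + chemotherapy) or `"PC"` (chemotherapy).
#' @param config A `psmcea_config`, see [default_config()].
#' @return Object of class `strategy_economics`.
#' @export
strategy_economics <- function(arm = c("TC", "PC"), config = default_config()) {
  arm <- match.arg(arm)
  structure(list(arm = arm, config = config), class = "strategy_economics")
}

# Histology-weighted chemotherapy backbone cost for one induction cycle.
# Squamous: paclitaxel d1/8/15 + carboplatin d1. Non-squamous: pemetrexed d1
# + cisplatin or carboplatin d1 (config mix). mg-exact dosing, no vial
# wastage.
chemo_cycle_cost <- function(config) {
  bsa <- config$population$bsa
  dose <- config$dosing; pr <- config$prices
  sq <- dose$paclitaxel_mg_per_m2 * bsa * dose$paclitaxel_admin_per_cycle *
    pr$paclitaxel_per_mg +
    dose$carboplatin_mg_per_m2 * bsa * pr$carboplatin_per_mg
  platinum <- config$population$cisplatin_fraction *
    dose$cisplatin_mg_per_m2 * bsa * pr$cisplatin_per_mg +
    (1 - config$population$cisplatin_fraction) *
    dose$carboplatin_mg_per_m2 * bsa * pr$carboplatin_per_mg
  nonsq <- dose$pemetrexed_mg_per_m2 * bsa * pr$pemetrexed_per_mg + platinum
  f_sq <- config$population$squamous_fraction
  f_sq * sq + (1 - f_sq) * nonsq
}

pemetrexed_cycle_cost <- function(config) {
  config$dosing$pemetrexed_mg_per_m2 * config$population$bsa *
    config$prices$pemetrexed_per_mg
}

#' First-line drug cost for one cycle
#'
#' Induction cycles price the chemotherapy backbone (histology-weighted,
#' body-surface-area dosed) plus flat-dose toripalimab in the TC arm.
#' Maintenance cycles price toripalimab (TC only) plus pemetrexed for the
#' non-squamous fraction (both arms; in the PC arm maintenance is pemetrexed
#' alone).
#'
#' @param econ A [strategy_economics()].
#' @param cycle_index 1-based cycle number.
#' @param in_maintenance Logical; if missing, derived from
#'   `schedule.induction_cycles`.
#' @return Cost in USD for one patient-cycle in the progression-free state.
#' @export
per_cycle_drug_cost <- function(econ, cycle_index,
                                in_maintenance = cycle_index > econ$config$schedule$induction_cycles) {
  stopifnot(inherits(econ, "strategy_economics"))
  config <- econ$config
  tori <- if (econ$arm == "TC") config$prices$toripalimab_per_cycle else 0
  nonsq <- 1 - config$population$squamous_fraction
  if (in_maintenance) {
    tori + nonsq * pemetrexed_cycle_cost(config)
  } else {
    tori + chemo_cycle_cost(config)
  }
}

# Monitoring (tumor-surveillance laboratory) test times in days: baseline,
# then every 6 weeks for 12 months, every 9 weeks thereafter.
monitoring_test_days <- function(config, horizon_days) {
  mon <- config$monitoring
  first <- seq(0, mon$first_year_days, by = mon$interval_first_year_days)
  start_later <- first[length(first)] + mon$interval_after_days
  later <- if (start_later <= horizon_days) {
    seq(start_later, horizon_days, by = mon$interval_after_days)
  } else numeric(0)
  c(first[first <= horizon_days], later)
}

# Per-cycle second-line cost for one patient-cycle in the progressed state:
# mix of second-line toripalimab and BSC (or docetaxel in that scenario).
second_line_cycle_cost <- function(econ) {
  config <- econ$config
  key <- tolower(econ$arm)
  f_tori <- config$second_line[[paste0("toripalimab_fraction_", key)]]
  f_bsc <- config$second_line[[paste0("bsc_fraction_", key)]]
  bsc_cost <- if (identical(config$second_line$drug, "docetaxel")) {
    config$dosing$docetaxel_mg_per_m2 * config$population$bsa *
      config$prices$docetaxel_per_mg
  } else {
    config$costs$bsc_per_cycle
  }
  f_tori * config$prices$toripalimab_per_cycle + f_bsc * bsc_cost
}

ae_cost_bundle <- function(econ) {
  key <- paste0("incidence_", tolower(econ$arm))
  sum(vapply(econ$config$adverse_events,
             function(ae) ae[[key]] * ae$unit_cost, numeric(1)))
}

ae_disutility_bundle <- function(econ) {
  key <- paste0("incidence_", tolower(econ$arm))
  sum(vapply(econ$config$adverse_events,
             function(ae) ae[[key]] * ae$disutility, numeric(1)))
}

#' Accumulate discounted costs over an occupancy trace
#'
#' Sums, cycle by cycle and discounted at cycle midpoints: first-line drug,
#' administration and monitoring costs weighted by progression-free
#' occupancy; hospitalization/nursing weighted by alive occupancy;
#' second-line mix costs weighted by progressed occupancy; one-time hospice
#' cost on new deaths; and the one-time grade-3/4 adverse-event cost bundle
#' in cycle 1. Occupancy weights are half-cycle corrected when the setting
#' is on.
#'
#' @param trace An [occupancy_trace()].
#' @param econ A [strategy_economics()].
#' @param settings A [model_settings()]; defaults to the trace's own.
#' @return Total discounted cost (USD) per model entrant.
#' @export
accumulate_costs <- function(trace, econ, settings = attr(trace, "settings")) {
  stopifnot(inherits(trace, "occupancy_trace"), inherits(econ, "strategy_economics"))
  config <- econ$config
  tis <- half_cycle_time_in_state(trace, settings)
  cl_m <- days_to_months(settings$cycle_length_days)
  w_pfs <- tis$pfs_months / cl_m   # person-cycles in PFS
  w_pd <- tis$pd_months / cl_m
  n <- nrow(tis)
  disc <- discount_factor(months_to_years(tis$t_mid_months),
                          settings$discount_rate_costs)

  ic <- config$schedule$induction_cycles
  drug <- ifelse(seq_len(n) <= ic,
                 per_cycle_drug_cost(econ, 1, in_maintenance = FALSE),
                 per_cycle_drug_cost(econ, ic + 1, in_maintenance = TRUE))
  admin <- config$costs$administration_per_cycle

  test_days <- monitoring_test_days(config, n * settings$cycle_length_days)
  tests_per_cycle <- tabulate(
    findInterval(test_days, (0:(n - 1)) * settings$cycle_length_days), nbins = n
  )
  monitor <- config$costs$laboratory_test * tests_per_cycle

  sl <- second_line_cycle_cost(econ)
  hosp <- config$costs$hospitalization_per_cycle
  new_deaths <- trace$new_deaths[-1]

  per_cycle <- w_pfs * (drug + admin + monitor) +
    w_pd * (sl + hosp) + w_pfs * hosp +
    new_deaths * config$costs$hospice_one_time
  per_cycle[1] <- per_cycle[1] + ae_cost_bundle(econ)
  sum(per_cycle * disc)
}

#' Accumulate discounted quality-adjusted life years
#'
#' Utility-weighted, half-cycle-corrected person-time per state, discounted
#' at cycle midpoints, minus the one-time adverse-event disutility bundle in
#' cycle 1. The death state carries utility 0.
#'
#' @inheritParams accumulate_costs
#' @return Discounted QALYs per model entrant.
#' @export
accumulate_qalys <- function(trace, econ, settings = attr(trace, "settings")) {
  stopifnot(inherits(trace, "occupancy_trace"), inherits(econ, "strategy_economics"))
  u <- econ$config$utilities
  if (u$u_pfs < 0 || u$u_pfs > 1 || u$u_pd < 0 || u$u_pd > 1) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  tis <- half_cycle_time_in_state(trace, settings)
  disc <- discount_factor(months_to_years(tis$t_mid_months),
                          settings$discount_rate_effects)
  m2y <- DAYS_PER_MONTH / DAYS_PER_YEAR
  q <- sum((u$u_pfs * tis$pfs_months + u$u_pd * tis$pd_months) * m2y * disc)
  q - ae_disutility_bundle(econ) * disc[1]
}

#' Incremental cost-effectiveness of two evaluated arms
#'
#' @param ref Named list with `arm`, `cost`, `qaly` for the reference
#'   strategy (comparator, e.g. PC).
#' @param comp Same for the comparison strategy (e.g. TC).
#' @return A `ce_result`: per-arm totals plus `inc_cost`, `inc_qaly`,
#'   `icer` (NA when the QALY difference is numerically zero) and
#'   `dominance` (`"none"`, `"dominant"`, `"dominated"`, or
#'   `"undefined"` when `inc_qaly` is ~0).
#' @examples
#' icer(list(arm = "PC", cost = 26768, qaly = 0.83),
#'      list(arm = "TC", cost = 45268, qaly = 1.40))
#' @export
icer <- function(ref, comp) {
  dc <- comp$cost - ref$cost
  de <- comp$qaly - ref$qaly
  dominance <- "none"
  if (abs(de) < 1e-9) {
    dominance <- "undefined"
    ratio <- NA_real_
  } else {
    ratio <- dc / de
    if (de > 0 && dc < 0) dominance <- "dominant"
    if (de < 0 && dc > 0) dominance <- "dominated"
  }
  structure(
    list(ref = ref, comp = comp, inc_cost = dc, inc_qaly = de,
         icer = ratio, dominance = dominance),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness result\n")
  cat(sprintf("  %-4s cost $%10.0f  QALYs %6.3f\n", x$ref$arm, x$ref$cost, x$ref$qaly))
  cat(sprintf("  %-4s cost $%10.0f  QALYs %6.3f\n", x$comp$arm, x$comp$cost, x$comp$qaly))
  cat(sprintf("  incremental: $%.0f / %.3f QALYs", x$inc_cost, x$inc_qaly))
  if (!is.na(x$icer)) cat(sprintf("  ->  ICER $%.0f/QALY", x$icer))
  if (x$dominance != "none") cat(sprintf("  [%s]", x$dominance))
  cat("\n")
  invisible(x)
}

#' Willingness-to-pay decision
#'
#' The comparison strategy is cost-effective if it dominates, or if it gains
#' QALYs at an ICER at or below the threshold.
#'
#' @param result A [icer()] result.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return `TRUE` if cost-effective at the threshold.
#' @export
wtp_decision <- function(result, wtp) {
  stopifnot(inherits(result, "ce_result"))
  if (result$dominance == "dominant") return(TRUE)
  if (result$dominance %in% c("dominated", "undefined")) return(FALSE)
  result$inc_qaly > 0 && result$icer <= wtp
}

#' Results table in the base-case layout
#'
#' @param result A `ce_result`.
#' @return Data frame with columns `arm`, `cost`, `qaly`, `inc_cost`,
#'   `inc_qaly`, `icer` (one row per arm; incrementals on the comparison
#'   row).
#' @export
ce_table <- function(result) {
  data.frame(
    arm = c(result$ref$arm, result$comp$arm),
    cost = c(result$ref$cost, result$comp$cost),
    qaly = c(result$ref$qaly, result$comp$qaly),
    inc_cost = c(NA, result$inc_cost),
    inc_qaly = c(NA, result$inc_qaly),
    icer = c(NA, result$icer)
  )
}
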