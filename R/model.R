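#' Evaluate both strategies under one configuration
#'
#' Runs the partitioned-survival engine and the economics accumulators for
#' both arms from a set of fitted survival curves, returning the
#' cost-effectiveness comparison of TC (comparison) versus PC (reference).
#' Survival fits are held fixed; everything downstream (cycle structure,
#' horizon, discounting, costs, utilities) is taken from `config`, which is
#' what the sensitivity analyses perturb.
#'
#' @param fits Named list of `psm_fit` objects: `TC_PFS`, `TC_OS`,
#'   `PC_PFS`, `PC_OS`.
#' @param config A `psmcea_config`.
#' @param traces Optional precomputed occupancy traces (named list `TC`,
#'   `PC`) to reuse when neither the fits nor the engine settings change
#'   between calls, as in the probabilistic sensitivity analysis.
#' @return A `ce_result` (see [icer()]).
#' @export
evaluate_strategies <- function(fits, config = default_config(), traces = NULL) {
  need <- c("TC_PFS", "TC_OS", "PC_PFS", "PC_OS")
  if (!all(need %in% names(fits))) {
    stop("fits must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  settings <- settings_from_config(config)
  arm_result <- function(arm) {
    trace <- traces[[arm]] %||%
      occupancy_trace(fits[[paste0(arm, "_PFS")]],
                      fits[[paste0(arm, "_OS")]], settings)
    econ <- strategy_economics(arm, config)
    list(arm = arm,
         cost = accumulate_costs(trace, econ, settings),
         qaly = accumulate_qalys(trace, econ, settings))
  }
  icer(arm_result("PC"), arm_result("TC"))
}

#' Fit and select survival models for all arm/endpoint series
#'
#' Fits all six candidate families to each pseudo-IPD set and selects the
#' best by the chosen information criterion.
#'
#' @param ipd_sets Named list of `pseudo_ipd` (`TC_PFS`, `TC_OS`, `PC_PFS`,
#'   `PC_OS`).
#' @param criterion Selection criterion passed to [select_best()].
#' @return List with `fits` (selected `psm_fit` per series) and
#'   `comparison` (per-series model-comparison data frames).
#' @export
fit_trial_curves <- function(ipd_sets, criterion = "aic") {
  all_fits <- lapply(ipd_sets, fit_all_distributions)
  list(
    fits = lapply(all_fits, select_best, criterion = criterion),
    comparison = lapply(all_fits, model_comparison_table)
  )
}
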