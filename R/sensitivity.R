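#' One-way sensitivity range
#'
#' @param parameter Dotted config path, e.g. `"utilities.u_pfs"`.
#' @param base,low,high Base value and excursion bounds (`low <= base <= high`).
#' @param source Provenance label: `"reported 95% CI"`, `"pm10_noncost"`,
#'   `"pm20_cost"`, or `"custom"`.
#' @return A `one_way_range` list.
#' @export
one_way_range <- function(parameter, base, low, high, source = "custom") {
  if (!(low <= base && base <= high)) {
    stop(sprintf("%s: need low <= base <= high (%g, %g, %g)",
                 parameter, low, base, high), call. = FALSE)
  }
  structure(list(parameter = parameter, base = base, low = low, high = high,
                 source = source), class = "one_way_range")
}

#' Default one-way sensitivity ranges
#'
#' Builds the deterministic sensitivity battery from a configuration:
#' \itemize{
#'   \item cost parameters (unit prices, state costs, adverse-event costs):
#'     +/-20\% of base;
#'   \item the toripalimab cycle price: +/-36\% (the wider band reflecting
#'     pending reimbursement renegotiation);
#'   \item non-cost parameters (utilities, histology mix, second-line mix is
#'     excluded): +/-10\%, capped at 1 for probabilities;
#'   \item body-surface area: the reported population limits;
#'   \item both discount rates: 0 to 8\%.
#' }
#'
#' @param config A `psmcea_config`.
#' @return List of [one_way_range()] objects.
#' @export
default_oneway_ranges <- function(config = default_config()) {
  rng <- list()
  add <- function(parameter, base, low, high, source) {
    rng[[length(rng) + 1]] <<- one_way_range(parameter, base, low, high, source)
  }
  for (k in names(config$prices)) {
    p <- paste0("prices.", k); v <- config$prices[[k]]
    if (k == "toripalimab_per_cycle") add(p, v, 0.64 * v, 1.36 * v, "custom")
    else add(p, v, 0.8 * v, 1.2 * v, "pm20_cost")
  }
  for (k in names(config$costs)) {
    v <- config$costs[[k]]
    add(paste0("costs.", k), v, 0.8 * v, 1.2 * v, "pm20_cost")
  }
  for (k in c("u_pfs", "u_pd")) {
    v <- config$utilities[[k]]
    add(paste0("utilities.", k), v, 0.9 * v, min(1, 1.1 * v), "pm10_noncost")
  }
  add("population.bsa", config$population$bsa,
      config$population$bsa_low, config$population$bsa_high, "reported 95% CI")
  for (k in c("discount_rate_costs", "discount_rate_effects")) {
    add(paste0("settings.", k), config$settings[[k]], 0, 0.08, "custom")
  }
  rng
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the model at each parameter's low and high excursion with
#' all other parameters at base, and ranks parameters by ICER span.
#'
#' @param ranges List of [one_way_range()] (default:
#'   [default_oneway_ranges()]).
#' @param fits Fitted survival curves, as for [evaluate_strategies()].
#' @param config Base configuration.
#' @param wtp Willingness-to-pay threshold for the crossing flag (default
#'   `config$wtp`).
#' @return A `tornado_table` data frame: `parameter`, `source`, `base`,
#'   `low`, `high`, `icer_low`, `icer_high`, `span`, `crosses_wtp`, sorted
#'   by descending span. The base-case ICER is attached as attribute
#'   `base_icer`.
#' @export
one_way <- function(ranges = NULL, fits, config = default_config(),
                    wtp = config$wtp) {
  if (is.null(ranges)) ranges <- default_oneway_ranges(config)
  base_res <- evaluate_strategies(fits, config)
  rows <- lapply(ranges, function(r) {
    lo <- evaluate_strategies(fits, config_set(config, r$parameter, r$low))
    hi <- evaluate_strategies(fits, config_set(config, r$parameter, r$high))
    data.frame(parameter = r$parameter, source = r$source, base = r$base,
               low = r$low, high = r$high,
               icer_low = lo$icer, icer_high = hi$icer,
               span = abs(hi$icer - lo$icer),
               crosses_wtp = (min(lo$icer, hi$icer) <= wtp) !=
                 (max(lo$icer, hi$icer) <= wtp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_res$icer
  attr(out, "wtp") <- wtp
  class(out) <- c("tornado_table", "data.frame")
  out
}

#' Probabilistic sensitivity analysis specification
#'
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed Integer seed.
#' @param sd_scale Multiplier on every parameter's standard deviation;
#'   `0` collapses all distributions to their base values (useful for
#'   degeneracy checks).
#' @return A `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 1000, seed = 1L, sd_scale = 1) {
  stopifnot(n_iterations >= 1, sd_scale >= 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), sd_scale = sd_scale),
            class = "psa_spec")
}

# Parameter table for the PSA: dotted path, base value, SD (from the
# one-way excursion, (high-low)/(2*1.96)), and distribution class.
psa_parameter_table <- function(config) {
  ranges <- default_oneway_ranges(config)
  keep <- vapply(ranges, function(r) !grepl("^settings\\.", r$parameter),
                 logical(1))
  ranges <- ranges[keep]
  df <- do.call(rbind, lapply(ranges, function(r) {
    dist <- if (grepl("^utilities\\.", r$parameter)) "beta"
    else if (r$parameter == "population.bsa") "normal"
    else "gamma"
    data.frame(parameter = r$parameter, base = r$base,
               sd = (r$high - r$low) / (2 * 1.96), dist = dist,
               lower = if (dist == "normal") config$population$bsa_low else NA,
               upper = if (dist == "normal") config$population$bsa_high else NA,
               stringsAsFactors = FALSE)
  }))
  df
}

#' Draw probabilistic sensitivity-analysis input samples
#'
#' Samples every uncertain parameter once per iteration: gamma for costs
#' and prices, beta for utilities, truncated normal for body-surface area.
#' Gamma and beta distributions are moment-matched so the mean equals the
#' base value and the SD is the one-way half-range divided by 1.96.
#'
#' @param spec A [psa_spec()].
#' @param config Base configuration.
#' @return List with `draws` (matrix `n_iterations` x parameters) and
#'   `parameters` (the parameter table).
#' @export
draw_psa_inputs <- function(spec, config = default_config()) {
  stopifnot(inherits(spec, "psa_spec"))
  pt <- psa_parameter_table(config)
  with_seed(spec$seed, {
    draws <- vapply(seq_len(nrow(pt)), function(j) {
      base <- pt$base[j]; sd <- pt$sd[j] * spec$sd_scale
      if (sd == 0 || base == 0) return(rep(base, spec$n_iterations))
      switch(pt$dist[j],
        gamma = {
          shape <- (base / sd)^2; scale <- sd^2 / base
          stats::rgamma(spec$n_iterations, shape = shape, scale = scale)
        },
        beta = {
          if (base >= 1) stop(pt$parameter[j],
                              ": beta distribution requires base < 1", call. = FALSE)
          kappa <- base * (1 - base) / sd^2 - 1
          if (kappa <= 0) stop(pt$parameter[j], ": SD too large for beta",
                               call. = FALSE)
          stats::rbeta(spec$n_iterations, base * kappa, (1 - base) * kappa)
        },
        normal = {
          x <- stats::rnorm(spec$n_iterations, base, sd)
          pmin(pmax(x, pt$lower[j]), pt$upper[j])
        })
    }, numeric(spec$n_iterations))
    if (spec$n_iterations == 1) draws <- matrix(draws, nrow = 1)
    colnames(draws) <- pt$parameter
    list(draws = draws, parameters = pt)
  })
}

#' Moment-matched distribution parameters
#'
#' Helper exposing the PSA's moment matching: gamma `shape`/`scale` or beta
#' `shape1`/`shape2` with the given mean and SD.
#'
#' @param mean,sd Target mean and standard deviation.
#' @param dist `"gamma"` or `"beta"`.
#' @return Named numeric vector of distribution parameters.
#' @examples
#' moment_match(100, 20, "gamma")  # shape 25, scale 4
#' moment_match(0.8, 0.05, "beta") # shape1 + shape2 = 63
#' @export
moment_match <- function(mean, sd, dist = c("gamma", "beta")) {
  dist <- match.arg(dist)
  if (dist == "gamma") {
    c(shape = (mean / sd)^2, scale = sd^2 / mean)
  } else {
    stopifnot(mean > 0, mean < 1)
    kappa <- mean * (1 - mean) / sd^2 - 1
    stopifnot(kappa > 0)
    c(shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
  }
}

#' Run the probabilistic sensitivity analysis
#'
#' Propagates sampled inputs through the full strategy evaluation, records
#' per-iteration incremental cost and QALYs, and computes the
#' cost-effectiveness acceptability curve (CEAC) as the fraction of
#' iterations with positive net monetary benefit at each threshold of a WTP
#' grid (default 0 to 2x the configured WTP in 200 steps).
#'
#' @param spec A [psa_spec()].
#' @param fits Fitted survival curves (held fixed across iterations).
#' @param config Base configuration.
#' @param wtp_grid Vector of WTP thresholds for the CEAC.
#' @return A `psa_output`: `draws` (data frame `iteration`, `dc`, `de`),
#'   `ceac` (data frame `wtp`, `p_tc`, `p_pc`), `n_failed` (iterations whose
#'   model evaluation errored, excluded with a count), `base` (the base-case
#'   `ce_result`).
#' @export
run_psa <- function(spec, fits, config = default_config(),
                    wtp_grid = seq(0, 2 * config$wtp, length.out = 201)) {
  stopifnot(inherits(spec, "psa_spec"))
  inputs <- draw_psa_inputs(spec, config)
  paths <- colnames(inputs$draws)
  dc <- de <- rep(NA_real_, spec$n_iterations)
  n_failed <- 0L
  # survival fits and engine settings are fixed across iterations, so the
  # occupancy traces can be computed once
  settings <- settings_from_config(config)
  traces <- list(
    TC = occupancy_trace(fits$TC_PFS, fits$TC_OS, settings),
    PC = occupancy_trace(fits$PC_PFS, fits$PC_OS, settings)
  )
  for (i in seq_len(spec$n_iterations)) {
    cfg_i <- config
    for (j in seq_along(paths)) {
      cfg_i <- config_set(cfg_i, paths[j], inputs$draws[i, j])
    }
    res <- tryCatch(evaluate_strategies(fits, cfg_i, traces = traces),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    dc[i] <- res$inc_cost; de[i] <- res$inc_qaly
  }
  ok <- !is.na(dc)
  ceac <- data.frame(
    wtp = wtp_grid,
    p_tc = vapply(wtp_grid, function(w) mean(w * de[ok] - dc[ok] > 0), numeric(1))
  )
  ceac$p_pc <- 1 - ceac$p_tc
  structure(
    list(draws = data.frame(iteration = which(ok), dc = dc[ok], de = de[ok]),
         ceac = ceac, n_failed = n_failed,
         base = evaluate_strategies(fits, config)),
    class = "psa_output"
  )
}

#' @export
print.psa_output <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (%d failed)\n",
              nrow(x$draws) + x$n_failed, x$n_failed))
  cat(sprintf("  mean dC $%.0f, mean dE %.3f QALYs\n",
              mean(x$draws$dc), mean(x$draws$de)))
  invisible(x)
}

#' Probability cost-effective at a threshold
#'
#' @param psa A `psa_output`.
#' @param wtp Threshold (USD/QALY).
#' @return Fraction of PSA iterations in which the comparison strategy has
#'   positive net monetary benefit.
#' @export
prob_cost_effective <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_output"))
  mean(wtp * psa$draws$de - psa$draws$dc > 0)
}

#' Scenario analyses
#'
#' Re-runs the full evaluation with a single scenario delta applied to the
#' base configuration. Built-in scenarios: `horizon_20y`, `horizon_30y`
#' (extended time horizons) and `docetaxel_second_line` (second-line best
#' supportive care replaced by BSA-dosed docetaxel). Custom scenarios are
#' lists `list(id = ..., delta = list("<path>" = value, ...))`.
#'
#' @param scenarios Character vector of built-in ids and/or custom scenario
#'   lists. Default: the three built-ins.
#' @param fits Fitted survival curves.
#' @param config Base configuration.
#' @return Data frame with one row per scenario (base case first):
#'   `scenario`, `cost_pc`, `qaly_pc`, `cost_tc`, `qaly_tc`, `inc_cost`,
#'   `inc_qaly`, `icer`.
#' @export
run_scenarios <- function(scenarios = c("horizon_20y", "horizon_30y",
                                        "docetaxel_second_line"),
                          fits, config = default_config()) {
  builtin <- list(
    horizon_20y = list("settings.horizon_years" = 20),
    horizon_30y = list("settings.horizon_years" = 30),
    docetaxel_second_line = list("second_line.drug" = "docetaxel")
  )
  norm <- lapply(scenarios, function(s) {
    if (is.character(s)) {
      if (!s %in% names(builtin)) stop("unknown scenario id: ", s, call. = FALSE)
      list(id = s, delta = builtin[[s]])
    } else if (is.list(s) && !is.null(s$id)) {
      list(id = s$id, delta = s$delta %||% list())
    } else stop("scenario must be an id or list(id=, delta=)", call. = FALSE)
  })
  evals <- c(list(list(id = "base_case", delta = list())), norm)
  rows <- lapply(evals, function(sc) {
    cfg <- config
    for (p in names(sc$delta)) cfg <- config_set(cfg, p, sc$delta[[p]])
    r <- evaluate_strategies(fits, cfg)
    data.frame(scenario = sc$id,
               cost_pc = r$ref$cost, qaly_pc = r$ref$qaly,
               cost_tc = r$comp$cost, qaly_tc = r$comp$qaly,
               inc_cost = r$inc_cost, inc_qaly = r$inc_qaly, icer = r$icer,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tornado diagram
#'
#' Horizontal-bar plot of one-way ICER excursions around the base-case ICER.
#'
#' @param tornado A [one_way()] result.
#' @param top Number of parameters to show (default 10).
#' @return Invisibly, the plotted subset.
#' @export
plot_tornado <- function(tornado, top = 10) {
  stopifnot(inherits(tornado, "tornado_table"))
  tt <- utils::head(tornado, top)
  tt <- tt[rev(seq_len(nrow(tt))), ]
  base_icer <- attr(tornado, "base_icer")
  xlim <- range(c(tt$icer_low, tt$icer_high, base_icer, attr(tornado, "wtp")))
  old <- graphics::par(mar = c(4, 14, 2, 1)); on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = xlim, ylim = c(0.5, nrow(tt) + 0.5),
                 yaxt = "n", xlab = "ICER (USD/QALY)", ylab = "",
                 main = "One-way sensitivity")
  graphics::axis(2, at = seq_len(nrow(tt)), labels = tt$parameter, las = 1,
                 cex.axis = 0.7)
  graphics::segments(tt$icer_low, seq_len(nrow(tt)), tt$icer_high,
                     lwd = 8, col = "steelblue")
  graphics::abline(v = base_icer, lty = 2)
  graphics::abline(v = attr(tornado, "wtp"), col = "red", lty = 3)
  invisible(tt)
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param psa A `psa_output`.
#' @param wtp Optional threshold to mark.
#' @return Invisibly, the CEAC data frame.
#' @export
plot_ceac <- function(psa, wtp = NULL) {
  stopifnot(inherits(psa, "psa_output"))
  graphics::plot(psa$ceac$wtp, psa$ceac$p_tc, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "Probability cost-effective", col = "steelblue")
  graphics::lines(psa$ceac$wtp, psa$ceac$p_pc, col = "firebrick")
  if (!is.null(wtp)) graphics::abline(v = wtp, lty = 3)
  graphics::legend("right", c("TC", "PC"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(psa$ceac)
}
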