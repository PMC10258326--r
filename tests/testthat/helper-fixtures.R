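# Hand-built parametric fits (bypassing the optimizer) for engine tests.
make_fit <- function(family, params) {
  structure(list(family = family, params = params, loglik = NA_real_,
                 k = length(params), n_obs = NA_integer_,
                 aic = NA_real_, bic = NA_real_, converged = TRUE),
            class = "psm_fit")
}

exp_fit <- function(rate) make_fit("exponential", c(rate = rate))
lnorm_fit <- function(meanlog, sdlog) {
  make_fit("lognormal", c(meanlog = meanlog, sdlog = sdlog))
}

# A fake fit carrying only selection criteria, for select_best tests.
crit_fit <- function(family, aic, bic, k) {
  structure(list(family = family, aic = aic, bic = bic, k = k),
            class = "psm_fit")
}

# Hand-built occupancy trace from explicit state proportions.
make_trace <- function(pfs, pd, settings = model_settings()) {
  stopifnot(length(pfs) == length(pd))
  dead <- 1 - pfs - pd
  n <- length(pfs) - 1
  t_months <- (0:n) * settings$cycle_length_days / 30.4375
  trace <- data.frame(cycle = 0:n, time_months = t_months,
                      pfs = pfs, pd = pd, dead = dead,
                      new_deaths = c(0, diff(dead)))
  attr(trace, "settings") <- settings
  class(trace) <- c("occupancy_trace", "data.frame")
  trace
}

# Config with every monetary input zeroed, for isolating single cost terms.
zero_cost_config <- function() {
  cfg <- default_config()
  cfg$prices <- lapply(cfg$prices, function(x) 0)
  cfg$costs <- lapply(cfg$costs, function(x) 0)
  cfg$adverse_events <- lapply(cfg$adverse_events, function(ae) {
    ae$unit_cost <- 0; ae$disutility <- 0; ae
  })
  cfg
}

# Small fitted curve set shared across economics/sensitivity tests:
# smooth exponential/lognormal stand-ins, TC better on both endpoints.
toy_fits <- function() {
  list(
    TC_PFS = lnorm_fit(log(8.3), 0.9),
    TC_OS = lnorm_fit(log(28), 0.9),
    PC_PFS = lnorm_fit(log(5.6), 0.9),
    PC_OS = lnorm_fit(log(17.1), 0.9)
  )
}
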