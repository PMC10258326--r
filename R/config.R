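#' Default model configuration
#'
#' Complete configuration for the base-case analysis: model settings, trial
#' parameters for the synthetic generator, dosing schedules, unit prices,
#' state costs, utilities and the grade-3/4 adverse-event bundle. Monetary
#' values are in USD (CNY configs are converted at the stated exchange rate).
#'
#' Unit prices, state costs, utilities and adverse-event inputs that the
#' source trial's economic appendix would normally supply are shipped here as
#' clearly-flagged placeholders (`placeholder_keys`): they are plausible
#' values from the Chinese NSCLC cost-effectiveness literature, and
#' [validate_config()] warns about each of them. Replace them with local
#' values before relying on absolute cost or ICER outputs. The docetaxel
#' price ($0.22/mg) and all trial-derived quantities (dosing, histology mix,
#' second-line allocation, body-surface area) are not placeholders.
#'
#' @return A nested named list of class `psmcea_config`.
#' @export
default_config <- function() {
  cfg <- list(
    currency = "USD",
    exchange_rate_cny_per_usd = 6.4515,
    wtp = 37654,
    settings = list(
      cycle_length_days = 21, horizon_years = 10,
      discount_rate_costs = 0.05, discount_rate_effects = 0.05,
      half_cycle_correction = TRUE
    ),
    trial = list(
      n_total = 465, allocation_tc = 2, allocation_pc = 1,
      pfs_median_tc = 8.3, pfs_median_pc = 5.6,
      os_median_tc = 28, os_median_pc = 17.1,
      log_sd_pfs = 0.9, log_sd_os = 0.9, followup_median = 16.2
    ),
    population = list(
      bsa = 1.67, bsa_low = 1.40, bsa_high = 1.94,
      squamous_fraction = 0.473, cisplatin_fraction = 0.5
    ),
    schedule = list(induction_cycles = 6),
    dosing = list(
      toripalimab_mg_flat = 240,
      paclitaxel_mg_per_m2 = 100, paclitaxel_admin_per_cycle = 3,
      carboplatin_mg_per_m2 = 400,
      cisplatin_mg_per_m2 = 75,
      pemetrexed_mg_per_m2 = 500,
      docetaxel_mg_per_m2 = 75
    ),
    prices = list(
      toripalimab_per_cycle = 296.52,
      paclitaxel_per_mg = 0.09,
      carboplatin_per_mg = 0.047,
      cisplatin_per_mg = 0.10,
      pemetrexed_per_mg = 0.12,
      docetaxel_per_mg = 0.22
    ),
    costs = list(
      administration_per_cycle = 50,
      laboratory_test = 120,
      hospitalization_per_cycle = 150,
      bsc_per_cycle = 300,
      hospice_one_time = 1500
    ),
    utilities = list(u_pfs = 0.804, u_pd = 0.321),
    second_line = list(
      toripalimab_fraction_tc = 0.133, bsc_fraction_tc = 0.867,
      toripalimab_fraction_pc = 0.654, bsc_fraction_pc = 0.346,
      drug = "bsc"
    ),
    monitoring = list(
      interval_first_year_days = 42, interval_after_days = 63,
      first_year_days = 365.25
    ),
    adverse_events = list(
      list(name = "neutropenia", incidence_tc = 0.37, incidence_pc = 0.33,
           unit_cost = 520, disutility = 0.046),
      list(name = "leukopenia", incidence_tc = 0.21, incidence_pc = 0.18,
           unit_cost = 410, disutility = 0.040),
      list(name = "anemia", incidence_tc = 0.12, incidence_pc = 0.10,
           unit_cost = 560, disutility = 0.073),
      list(name = "thrombocytopenia", incidence_tc = 0.17, incidence_pc = 0.15,
           unit_cost = 700, disutility = 0.050)
    ),
    placeholder_keys = c(
      "prices.toripalimab_per_cycle", "prices.paclitaxel_per_mg",
      "prices.carboplatin_per_mg", "prices.cisplatin_per_mg",
      "prices.pemetrexed_per_mg",
      "costs.administration_per_cycle", "costs.laboratory_test",
      "costs.hospitalization_per_cycle", "costs.bsc_per_cycle",
      "costs.hospice_one_time",
      "utilities.u_pfs", "utilities.u_pd",
      "adverse_events", "trial.os_median_tc"
    )
  )
  class(cfg) <- c("psmcea_config", "list")
  cfg
}

#' Load a configuration from YAML or JSON
#'
#' Reads the file, fills unspecified keys from [default_config()], converts
#' CNY monetary values to USD when `currency: CNY`, and validates.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param strict If `TRUE` (default), stop on validation errors.
#' @return A `psmcea_config` list (monetary values in USD).
#' @export
load_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(default_config(), raw, keep.null = TRUE)
  class(cfg) <- c("psmcea_config", "list")
  if (identical(toupper(cfg$currency %||% "USD"), "CNY")) {
    rate <- cfg$exchange_rate_cny_per_usd
    cfg$prices <- lapply(cfg$prices, function(p) p / rate)
    cfg$costs <- lapply(cfg$costs, function(p) p / rate)
    cfg$adverse_events <- lapply(cfg$adverse_events, function(ae) {
      ae$unit_cost <- ae$unit_cost / rate; ae
    })
    cfg$wtp <- cfg$wtp / rate
    cfg$currency <- "USD"
  }
  rep <- validate_config(cfg)
  if (strict && length(rep$errors)) {
    stop("invalid configuration:\n  ", paste(rep$errors, collapse = "\n  "),
         call. = FALSE)
  }
  cfg
}

#' Validate a configuration
#'
#' Checks structural invariants (probabilities in range, prices
#' non-negative, second-line fractions summing to one, histology mix,
#' discount-rate range) and reports each violation with the offending key
#' path. Placeholder-flagged values produce warnings, not errors.
#'
#' @param config A `psmcea_config` (or plain list with the same shape), or a
#'   file path.
#' @return A list with character vectors `errors` and `warnings`, of class
#'   `config_validation`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- load_config(config, strict = FALSE)
  errors <- character(0); warnings <- character(0)
  err <- function(msg) errors <<- c(errors, msg)

  u <- config$utilities
  for (k in c("u_pfs", "u_pd")) {
    if (is.null(u[[k]]) || u[[k]] < 0 || u[[k]] > 1) {
      err(sprintf("utilities.%s: must be in [0, 1] (got %s)", k,
                  u[[k]] %||% "missing"))
    }
  }
  for (k in names(config$prices)) {
    if (config$prices[[k]] < 0) err(sprintf("prices.%s: negative price", k))
  }
  for (k in names(config$costs)) {
    if (config$costs[[k]] < 0) err(sprintf("costs.%s: negative cost", k))
  }
  sl <- config$second_line
  for (arm in c("tc", "pc")) {
    tot <- sl[[paste0("toripalimab_fraction_", arm)]] +
      sl[[paste0("bsc_fraction_", arm)]]
    if (abs(tot - 1) > 1e-6) {
      err(sprintf("second_line.*_fraction_%s: fractions sum to %.4f, not 1", arm, tot))
    }
  }
  if (!sl$drug %in% c("bsc", "docetaxel")) {
    err("second_line.drug: must be 'bsc' or 'docetaxel'")
  }
  pop <- config$population
  if (pop$squamous_fraction < 0 || pop$squamous_fraction > 1) {
    err("population.squamous_fraction: must be in [0, 1]")
  }
  if (pop$bsa <= 0) err("population.bsa: must be positive")
  if (!(pop$bsa_low <= pop$bsa && pop$bsa <= pop$bsa_high)) {
    err("population.bsa: mean outside [bsa_low, bsa_high]")
  }
  st <- config$settings
  for (k in c("discount_rate_costs", "discount_rate_effects")) {
    if (st[[k]] < 0) err(sprintf("settings.%s: negative discount rate", k))
    else if (st[[k]] > 0.08) {
      warnings <- c(warnings, sprintf(
        "settings.%s: %.3f is outside the usual 0-8%% sensitivity range", k, st[[k]]))
    }
  }
  ic <- config$schedule$induction_cycles
  if (is.null(ic) || ic < 1) err("schedule.induction_cycles: must be >= 1")
  else if (ic < 4 || ic > 6) {
    warnings <- c(warnings,
                  "schedule.induction_cycles: trial protocol allowed 4-6 cycles")
  }
  for (i in seq_along(config$adverse_events)) {
    ae <- config$adverse_events[[i]]
    for (k in c("incidence_tc", "incidence_pc")) {
      if (ae[[k]] < 0 || ae[[k]] > 1) {
        err(sprintf("adverse_events[%d].%s (%s): incidence outside [0, 1]",
                    i, k, ae$name))
      }
    }
    if (ae$unit_cost < 0) {
      err(sprintf("adverse_events[%d].unit_cost (%s): negative", i, ae$name))
    }
  }
  for (k in config$placeholder_keys) {
    warnings <- c(warnings, sprintf(
      "%s: placeholder value - calibrate to local/appendix data before use", k))
  }
  structure(list(errors = errors, warnings = warnings),
            class = "config_validation")
}

#' @export
print.config_validation <- function(x, ...) {
  if (!length(x$errors)) cat("Configuration valid.\n")
  else cat("Errors:\n", paste0("  - ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) {
    cat(sprintf("%d warning(s), including placeholder flags:\n", length(x$warnings)))
    cat(paste0("  - ", utils::head(x$warnings, 5), "\n"), sep = "")
    if (length(x$warnings) > 5) cat(sprintf("  ... and %d more\n", length(x$warnings) - 5))
  }
  invisible(x)
}

# model_settings view of a config
settings_from_config <- function(config) {
  st <- config$settings
  model_settings(st$cycle_length_days, st$horizon_years,
                 st$discount_rate_costs, st$discount_rate_effects,
                 st$half_cycle_correction)
}

# synthetic_trial_spec view of a config
trial_spec_from_config <- function(config, seed = 1L) {
  tr <- config$trial
  synthetic_trial_spec(
    n_total = tr$n_total,
    allocation_ratio = c(tr$allocation_tc, tr$allocation_pc),
    pfs_median_tc = tr$pfs_median_tc, pfs_median_pc = tr$pfs_median_pc,
    os_median_tc = tr$os_median_tc, os_median_pc = tr$os_median_pc,
    log_sd_pfs = tr$log_sd_pfs, log_sd_os = tr$log_sd_os,
    followup_median = tr$followup_median, seed = seed
  )
}
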