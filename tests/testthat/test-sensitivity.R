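test_that("moment matching reproduces closed-form gamma and beta parameters", {
  g <- moment_match(100, 20, "gamma")
  expect_equal(unname(g), c(25, 4))
  b <- moment_match(0.8, 0.05, "beta")
  expect_equal(unname(b["shape1"] + b["shape2"]), 63)
  expect_equal(unname(b["shape1"]), 50.4)
  # distributions actually have the requested moments
  expect_equal(g["shape"] * g["scale"], c(shape = 100))
  expect_equal(unname(b["shape1"] / (b["shape1"] + b["shape2"])), 0.8)
})

test_that("PSA draws are mean-centred on base values and seed-reproducible", {
  cfg <- default_config()
  draws <- draw_psa_inputs(psa_spec(100000, seed = 5), cfg)
  for (j in seq_len(nrow(draws$parameters))) {
    base <- draws$parameters$base[j]
    if (draws$parameters$dist[j] == "normal") next # truncation shifts the mean
    expect_equal(mean(draws$draws[, j]), base, tolerance = 0.005)
  }
  # BSA truncated at the population limits
  bsa <- draws$draws[, "population.bsa"]
  expect_true(all(bsa >= cfg$population$bsa_low & bsa <= cfg$population$bsa_high))

  again <- draw_psa_inputs(psa_spec(100000, seed = 5), cfg)
  expect_identical(draws$draws, again$draws)
  expect_false(identical(draws$draws,
                         draw_psa_inputs(psa_spec(100000, seed = 6), cfg)$draws))
})

test_that("beta sampling rejects utilities at or above one", {
  cfg <- default_config()
  cfg$utilities$u_pfs <- 1
  expect_error(draw_psa_inputs(psa_spec(10, seed = 1), cfg), "beta")
})

test_that("zero-variance PSA degenerates to the base case with a step CEAC", {
  fits <- toy_fits()
  cfg <- default_config()
  psa <- run_psa(psa_spec(1000, seed = 3, sd_scale = 0), fits, cfg)
  base <- evaluate_strategies(fits, cfg)
  expect_equal(nrow(psa$draws), 1000)
  expect_equal(psa$n_failed, 0)
  expect_true(all(abs(psa$draws$dc - base$inc_cost) < 1e-9))
  expect_true(all(abs(psa$draws$de - base$inc_qaly) < 1e-9))
  # CEAC is a unit step at the base-case ICER
  below <- psa$ceac$wtp < base$icer
  expect_true(all(psa$ceac$p_tc[below] == 0))
  expect_true(all(psa$ceac$p_tc[!below & psa$ceac$wtp > base$icer + 1] == 1))
})

test_that("two-strategy CEAC probabilities are complementary at every threshold", {
  fits <- toy_fits()
  psa <- run_psa(psa_spec(200, seed = 17), fits, default_config())
  expect_true(all(abs(psa$ceac$p_tc + psa$ceac$p_pc - 1) < 1e-12))
  expect_true(all(psa$ceac$p_tc >= 0 & psa$ceac$p_tc <= 1))
  expect_equal(prob_cost_effective(psa, 37654),
               psa$ceac$p_tc[which.min(abs(psa$ceac$wtp - 37654))],
               tolerance = 0.05)
})

test_that("CEAC estimate at 1000 draws sits inside the CI of a larger run", {
  # PSA estimator convergence, checked at a threshold near the base ICER
  # where the probability is non-trivial
  fits <- toy_fits()
  cfg <- default_config()
  base <- evaluate_strategies(fits, cfg)
  w <- base$icer * 1.02
  small <- prob_cost_effective(run_psa(psa_spec(400, seed = 21), fits, cfg), w)
  big <- prob_cost_effective(run_psa(psa_spec(4000, seed = 22), fits, cfg), w)
  half_width <- 2.58 * sqrt(big * (1 - big) / 400)
  expect_lt(abs(small - big), half_width + 2.58 * sqrt(big * (1 - big) / 4000))
})

test_that("tornado ranks parameters by span and flags irrelevant ones", {
  fits <- toy_fits()
  cfg <- default_config()
  ranges <- list(
    one_way_range("utilities.u_pfs", 0.804, 0.72, 0.88, "pm10_noncost"),
    one_way_range("prices.toripalimab_per_cycle", 296.52, 190, 403, "custom"),
    one_way_range("trial.followup_median", 16.2, 14, 18, "custom") # ignored by the model
  )
  tt <- one_way(ranges, fits, cfg)
  expect_s3_class(tt, "tornado_table")
  expect_true(!is.unsorted(rev(tt$span)))
  ignored <- tt[tt$parameter == "trial.followup_median", ]
  expect_equal(ignored$span, 0)
  expect_equal(tt$parameter[nrow(tt)], "trial.followup_median")

  # lower PFS utility raises the ICER when TC gains mostly PFS time
  u_row <- tt[tt$parameter == "utilities.u_pfs", ]
  expect_gt(u_row$icer_low, u_row$icer_high)

  # order invariance
  tt2 <- one_way(rev(ranges), fits, cfg)
  expect_equal(as.data.frame(tt), as.data.frame(tt2))

  expect_error(one_way(list(one_way_range("prices.nonexistent", 1, 0.5, 2)),
                       fits, cfg), "unknown config parameter")
})

test_that("default one-way battery applies the documented range rules", {
  cfg <- default_config()
  ranges <- default_oneway_ranges(cfg)
  by_param <- setNames(ranges, vapply(ranges, `[[`, "", "parameter"))
  tor <- by_param[["prices.toripalimab_per_cycle"]]
  expect_equal(tor$low, 0.64 * cfg$prices$toripalimab_per_cycle)
  expect_equal(tor$high, 1.36 * cfg$prices$toripalimab_per_cycle)
  bsc <- by_param[["costs.bsc_per_cycle"]]
  expect_equal(c(bsc$low, bsc$high), c(0.8, 1.2) * cfg$costs$bsc_per_cycle)
  upfs <- by_param[["utilities.u_pfs"]]
  expect_equal(c(upfs$low, upfs$high), c(0.9, 1.1) * cfg$utilities$u_pfs)
  bsa <- by_param[["population.bsa"]]
  expect_equal(c(bsa$low, bsa$high), c(1.40, 1.94))
  disc <- by_param[["settings.discount_rate_costs"]]
  expect_equal(c(disc$low, disc$high), c(0, 0.08))
})

test_that("no single excursion crosses the threshold at shipped defaults", {
  fits <- toy_fits()
  tt <- one_way(NULL, fits, default_config())
  expect_false(any(tt$crosses_wtp))
})

test_that("scenario runner applies single deltas and reproduces the base case", {
  fits <- toy_fits()
  cfg <- default_config()
  tab <- run_scenarios(fits = fits, config = cfg)
  expect_equal(tab$scenario,
               c("base_case", "horizon_20y", "horizon_30y", "docetaxel_second_line"))
  base <- evaluate_strategies(fits, cfg)
  expect_identical(tab$cost_tc[1], base$comp$cost)
  expect_identical(tab$qaly_pc[1], base$ref$qaly)

  # an empty custom delta is bit-identical to the base case
  empty <- run_scenarios(list(list(id = "noop")), fits, cfg)
  expect_identical(unlist(empty[empty$scenario == "noop", -1], use.names = FALSE),
                   unlist(empty[empty$scenario == "base_case", -1], use.names = FALSE))

  # QALYs never decrease with a longer horizon
  expect_true(all(diff(tab$qaly_tc[1:3]) >= 0))
  expect_true(all(diff(tab$qaly_pc[1:3]) >= 0))

  expect_error(run_scenarios("horizon_50y", fits, cfg), "unknown scenario")
})

test_that("the docetaxel switch touches only progressed-state costs", {
  cfg <- default_config()
  cfg_doc <- cfg
  cfg_doc$second_line$drug <- "docetaxel"
  s <- model_settings()
  # cohort that never progresses: PFS == OS
  f <- lnorm_fit(log(17.1), 0.9)
  tr_pfs_only <- occupancy_trace(f, f, s)
  expect_identical(accumulate_costs(tr_pfs_only, strategy_economics("TC", cfg), s),
                   accumulate_costs(tr_pfs_only, strategy_economics("TC", cfg_doc), s))
  # with progression, only the cost side moves
  fits <- toy_fits()
  a <- evaluate_strategies(fits, cfg); b <- evaluate_strategies(fits, cfg_doc)
  expect_identical(a$comp$qaly, b$comp$qaly)
  expect_false(identical(a$comp$cost, b$comp$cost))
})
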