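test_that("per-cycle drug quantities follow BSA dosing", {
  # paclitaxel 100 mg/m2 on days 1/8/15 at BSA 1.67 = 501 mg per cycle
  cfg <- zero_cost_config()
  cfg$population$squamous_fraction <- 1
  cfg$prices$paclitaxel_per_mg <- 1
  expect_equal(per_cycle_drug_cost(strategy_economics("TC", cfg), 1), 501)
  # pemetrexed 500 mg/m2 day 1 = 835 mg per cycle
  cfg2 <- zero_cost_config()
  cfg2$population$squamous_fraction <- 0
  cfg2$prices$pemetrexed_per_mg <- 1
  expect_equal(per_cycle_drug_cost(strategy_economics("TC", cfg2), 1), 835)
  # maintenance prices pemetrexed only for the non-squamous fraction
  cfg2$population$squamous_fraction <- 0.4
  expect_equal(per_cycle_drug_cost(strategy_economics("PC", cfg2), 7,
                                   in_maintenance = TRUE), 0.6 * 835)
  # zero prices mean zero cost
  expect_equal(per_cycle_drug_cost(strategy_economics("TC", zero_cost_config()), 1), 0)
})

test_that("toripalimab is priced in the TC arm only", {
  cfg <- zero_cost_config()
  cfg$prices$toripalimab_per_cycle <- 100
  expect_equal(per_cycle_drug_cost(strategy_economics("TC", cfg), 1), 100)
  expect_equal(per_cycle_drug_cost(strategy_economics("PC", cfg), 1), 0)
  expect_equal(per_cycle_drug_cost(strategy_economics("TC", cfg), 10,
                                   in_maintenance = TRUE), 100)
})

test_that("cost accumulation matches a hand-computed three-cycle oracle", {
  s <- model_settings(horizon_years = 63 / 365.25) # exactly 3 cycles
  tr <- make_trace(pfs = c(1, .8, .6, .5), pd = c(0, .1, .2, .2), settings = s)

  cfg <- zero_cost_config()
  cfg$population$bsa <- 2
  cfg$population$squamous_fraction <- 0.5
  cfg$population$cisplatin_fraction <- 1
  cfg$schedule$induction_cycles <- 2
  cfg$prices$paclitaxel_per_mg <- 0.01
  cfg$prices$carboplatin_per_mg <- 0.02
  cfg$prices$cisplatin_per_mg <- 0.03
  cfg$prices$pemetrexed_per_mg <- 0.04
  cfg$prices$toripalimab_per_cycle <- 100
  cfg$costs$administration_per_cycle <- 10
  cfg$costs$laboratory_test <- 20
  cfg$costs$hospitalization_per_cycle <- 5
  cfg$costs$bsc_per_cycle <- 50
  cfg$costs$hospice_one_time <- 200
  cfg$adverse_events <- list(list(name = "ae", incidence_tc = 0.2,
                                  incidence_pc = 0.1, unit_cost = 30,
                                  disutility = 0.01))
  econ <- strategy_economics("TC", cfg)

  # -- independent spreadsheet-style arithmetic ------------------------------
  cl_m <- 21 / 30.4375; m2y <- 30.4375 / 365.25
  w_pfs <- c(0.9, 0.7, 0.55); w_pd <- c(0.05, 0.15, 0.2); nd <- c(.1, .1, .1)
  chemo <- 0.5 * (100 * 2 * 3 * 0.01 + 400 * 2 * 0.02) +
    0.5 * (500 * 2 * 0.04 + 75 * 2 * 0.03)          # 33.25
  c_ind <- 100 + chemo; c_mnt <- 100 + 0.5 * 500 * 2 * 0.04
  drug <- c(c_ind, c_ind, c_mnt)
  monitor <- c(20, 0, 20)                            # lab tests at day 0 and 42
  sl <- 0.133 * 100 + 0.867 * 50                     # second-line mix per PD cycle
  cyc <- w_pfs * (drug + 10 + monitor) + w_pd * (sl + 5) + w_pfs * 5 + nd * 200
  cyc[1] <- cyc[1] + 0.2 * 30                        # one-time AE bundle
  disc <- 1.05^(-((1:3) - 0.5) * cl_m * m2y)
  expect_equal(accumulate_costs(tr, econ, s), sum(cyc * disc), tolerance = 1e-9)

  # -- QALY oracle -----------------------------------------------------------
  cfg$utilities <- list(u_pfs = 0.8, u_pd = 0.6)
  econ <- strategy_economics("TC", cfg)
  q <- sum((0.8 * w_pfs + 0.6 * w_pd) * cl_m * m2y * disc) - 0.2 * 0.01 * disc[1]
  expect_equal(accumulate_qalys(tr, econ, s), q, tolerance = 1e-9)
})

test_that("an immediately-dead cohort accrues only the hospice cost", {
  s <- model_settings(horizon_years = 63 / 365.25)
  tr <- make_trace(pfs = c(1, 0, 0, 0), pd = c(0, 0, 0, 0), settings = s)
  cfg <- zero_cost_config()
  cfg$costs$hospice_one_time <- 1500
  cost <- accumulate_costs(tr, strategy_economics("TC", cfg), s)
  d1 <- discount_factor((0.5 * 21) / 365.25, 0.05)
  expect_equal(cost, 1500 * d1, tolerance = 1e-12)
})

test_that("costs are linear and QALYs scale with utilities", {
  fits <- toy_fits()
  s <- model_settings()
  tr <- occupancy_trace(fits$TC_PFS, fits$TC_OS, s)
  cfg <- default_config()
  base <- accumulate_costs(tr, strategy_economics("TC", cfg), s)
  cfg2 <- cfg
  cfg2$prices <- lapply(cfg$prices, function(x) 2 * x)
  cfg2$costs <- lapply(cfg$costs, function(x) 2 * x)
  cfg2$adverse_events <- lapply(cfg$adverse_events, function(ae) {
    ae$unit_cost <- 2 * ae$unit_cost; ae
  })
  expect_equal(accumulate_costs(tr, strategy_economics("TC", cfg2), s),
               2 * base, tolerance = 1e-12)

  # utility identity: u = 1 everywhere, no disutility -> discounted life-years
  cfg3 <- cfg
  cfg3$utilities <- list(u_pfs = 1, u_pd = 1)
  cfg3$adverse_events <- lapply(cfg$adverse_events, function(ae) {
    ae$disutility <- 0; ae
  })
  expect_equal(accumulate_qalys(tr, strategy_economics("TC", cfg3), s),
               trace_life_years(tr, s)$disc_life_years, tolerance = 1e-12)
  cfg3$utilities <- list(u_pfs = 0, u_pd = 0)
  expect_equal(accumulate_qalys(tr, strategy_economics("TC", cfg3), s), 0)

  cfg4 <- cfg
  cfg4$utilities <- list(u_pfs = 1.2, u_pd = 0.3)
  expect_error(accumulate_qalys(tr, strategy_economics("TC", cfg4), s),
               "\\[0, 1\\]")
})

test_that("TC cost is non-decreasing in induction cycles when PD costs vanish", {
  fits <- toy_fits()
  s <- model_settings()
  tr <- occupancy_trace(fits$TC_PFS, fits$TC_OS, s)
  cfg <- default_config()
  cfg$costs$bsc_per_cycle <- 0
  cfg$costs$hospitalization_per_cycle <- 0
  cfg$costs$hospice_one_time <- 0
  cfg$second_line$toripalimab_fraction_tc <- 0
  cfg$second_line$bsc_fraction_tc <- 1
  costs <- vapply(4:6, function(ic) {
    cfg$schedule$induction_cycles <- ic
    accumulate_costs(tr, strategy_economics("TC", cfg), s)
  }, numeric(1))
  expect_true(all(diff(costs) >= 0))
})

test_that("ICER arithmetic, dominance flags and antisymmetry", {
  r <- icer(list(arm = "PC", cost = 0, qaly = 0),
            list(arm = "TC", cost = 18501, qaly = 0.57))
  expect_equal(r$icer, 18501 / 0.57) # 32458.0
  expect_equal(round(r$icer), 32458)
  expect_equal(r$dominance, "none")

  dom <- icer(list(arm = "PC", cost = 100, qaly = 1),
              list(arm = "TC", cost = 0, qaly = 1.5))
  expect_equal(dom$dominance, "dominant")
  expect_lt(dom$icer, 0)
  dtd <- icer(list(arm = "PC", cost = 0, qaly = 1.5),
              list(arm = "TC", cost = 100, qaly = 1))
  expect_equal(dtd$dominance, "dominated")
  und <- icer(list(arm = "PC", cost = 0, qaly = 1),
              list(arm = "TC", cost = 100, qaly = 1))
  expect_equal(und$dominance, "undefined")
  expect_true(is.na(und$icer))

  # antisymmetry
  a <- list(arm = "A", cost = 500, qaly = 1.1)
  b <- list(arm = "B", cost = 900, qaly = 1.4)
  expect_equal(icer(a, b)$inc_cost, -icer(b, a)$inc_cost)
  expect_equal(icer(a, b)$inc_qaly, -icer(b, a)$inc_qaly)
})

test_that("WTP decisions agree with net monetary benefit", {
  expect_true(wtp_decision(icer(list(arm = "PC", cost = 0, qaly = 0),
                                list(arm = "TC", cost = 32237 * 0.57, qaly = 0.57)),
                           37654))
  expect_false(wtp_decision(icer(list(arm = "PC", cost = 0, qaly = 0),
                                 list(arm = "TC", cost = 40000 * 0.57, qaly = 0.57)),
                            37654))
  # dominant strategies are cost-effective at any threshold
  dom <- icer(list(arm = "PC", cost = 100, qaly = 1),
              list(arm = "TC", cost = 50, qaly = 1.2))
  expect_true(wtp_decision(dom, 0))

  set.seed(88)
  for (i in 1:50) {
    dc <- runif(1, -5000, 30000); de <- runif(1, 0.01, 1); w <- runif(1, 0, 6e4)
    r <- icer(list(arm = "PC", cost = 0, qaly = 0),
              list(arm = "TC", cost = dc, qaly = de))
    if (r$dominance == "none") {
      expect_equal(wtp_decision(r, w), w * de - dc >= 0)
    }
  }
})
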