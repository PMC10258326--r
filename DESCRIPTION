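Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for Two-Arm
    Oncology Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based cost-effectiveness analysis of oncology
    regimens with a three-state partitioned survival model. Reconstructs
    pseudo individual-patient data from digitized Kaplan-Meier curves,
    fits and selects parametric survival distributions (Weibull,
    exponential, Gompertz, gamma, log-logistic, log-normal) by AIC/BIC,
    converts fitted progression-free and overall survival curves into
    per-cycle state occupancy with half-cycle correction and discounting,
    accrues drug, monitoring, supportive-care and adverse-event costs and
    quality-adjusted life years, and computes incremental
    cost-effectiveness ratios. Includes one-way (tornado), probabilistic
    (Monte Carlo with cost-effectiveness acceptability curves) and
    scenario sensitivity analyses, a synthetic-trial generator emulating a
    2:1 randomized immunotherapy trial, and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    flexsurv,
    survival,
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
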