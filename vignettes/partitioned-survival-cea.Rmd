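---
title: "Methods: a partitioned survival cost-effectiveness model for first-line NSCLC immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned survival cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem and the model

`psmcea` evaluates whether adding a PD-1 antibody (toripalimab, 240 mg flat
every 3 weeks) to platinum-doublet chemotherapy is good value for money in
first-line advanced NSCLC, against chemotherapy alone, from a healthcare-system
perspective. The vehicle is a three-state partitioned survival model (PSM):
progression-free (PFS), progressed disease (PD) and death. Unlike a Markov
cohort model, a PSM needs no transition probabilities — state membership is
read directly from the two survival functions at each cycle boundary:

* PFS occupancy = \(S_{\mathrm{pfs}}(t)\),
* PD occupancy = \(S_{\mathrm{os}}(t) - S_{\mathrm{pfs}}(t)\),
* dead = \(1 - S_{\mathrm{os}}(t)\).

The implicit assumptions are worth stating: the two curves jointly determine
the cohort's path (no memory of *when* a patient progressed), progression is
irreversible, and any structural dependence between endpoints is inherited
from the curves rather than modelled. When PFS and OS are extrapolated with
independently fitted distributions the PFS curve can cross above the OS curve
in the far tail; we clamp PFS to `min(S_pfs, S_os)` so PD occupancy is never
negative and the three states always sum to exactly one. This clamp is
standard PSM practice and is exercised directly in the test suite.

## Survival inputs

Individual-patient data (IPD) enter three ways:

1. **Reconstruction from digitized curves.** Published Kaplan–Meier
   coordinates `(time, survival)` are converted to pseudo-IPD by an interval
   method: within each digitized interval the number of events is
   \(k_i = \mathrm{round}(n_i (1 - S_i/S_{i-1}))\) with \(n_i\) the running
   risk set, event times at interval midpoints, and everyone left at the end
   administratively censored. The method is deterministic and auditable, and
   is exact whenever the digitized points coincide with KM steps: the
   round-trip test (simulate → KM → digitize → reconstruct → KM) agrees
   within ±0.01 survival probability. We deliberately do not implement
   risk-set-calibrated (Guyot-type) reconstruction: it requires the
   numbers-at-risk table, which published figures do not always carry, and
   the interval method is adequate at digitization resolution. Censoring
   before end of follow-up is therefore not recovered — a known limitation.

2. **The synthetic-trial generator** (below), used when no digitized curves
   are supplied, and for all property-based testing.

3. **Direct pseudo-IPD files** (`time_months,event` CSV).

Six parametric families — Weibull, exponential, Gompertz, gamma,
log-logistic, log-normal — are fitted to each arm × endpoint series by
right-censored maximum likelihood (via `flexsurv`, whose parameterizations we
adopt and document in the fit object; the Gompertz shape may be negative,
giving a plateauing survival function whose median can be infinite).
Selection minimizes AIC; BIC is also computed and any disagreement is
reported, but AIC is authoritative so that selection is a single
deterministic path. Ties break toward fewer parameters, then a fixed family
order. The BIC sample size is the number of subjects.

## The synthetic trial

The generator emulates a 465-patient, 2:1-randomized, double-blind trial of
TC vs PC with 16.2 months median follow-up. Defaults (the study conditions,
not tuning knobs): TC/PC median PFS 8.3/5.6 months, PC median OS 17.1
months, and TC median OS 28 months — the last is a **placeholder**, because
the emulated trial's TC-arm median OS was not reached at data cut-off (95%
CI lower bound 21.7 months); 28 months is a deliberately long-tailed choice
consistent with that bound and is flagged in `placeholder_keys`.

Event times are log-normal with log-median \( \mu = \ln(\text{median}) \)
and log-scale SD 0.9 for both endpoints. The SD is not recoverable from
published medians alone; 0.9 gives the heavy right tail characteristic of
immunotherapy OS curves and is config-overridable.

Marginal log-normals cannot guarantee the structural constraint
\( \mathrm{PFS} \le \mathrm{OS} \) per subject, so PFS is drawn as OS × a
Beta-distributed fraction. The Beta concentration is fixed at 4 and its mean
is calibrated deterministically so the *marginal* PFS median is exact:
\(P(\mathrm{OS}\cdot B \le m_{\mathrm{target}})=1/2\) is solved by
one-dimensional root finding, with the probability evaluated by integrating
`pbeta` against the normal density of log-OS (integrating over the Beta
quantile function instead is numerically fragile for shapes below 1). A
2-million-draw Monte Carlo check confirms the calibrated median to three
decimals. One consequence is that coupled PFS is a log-normal–Beta product,
not itself log-normal — so model selection on synthetic PFS legitimately
picks other flexible families, and the median-recovery protocols
(`median_recovery()`) use the single-endpoint log-normal generator
(`simulate_survival_arm()`) instead.

Administrative censoring mimics staggered accrual: subjects enter uniformly
over a window of half the target median follow-up and the database locks at
1.25× that median, making per-subject follow-up uniform on
\([0.75, 1.25] \times 16.2\) months with the stated median. Both endpoints
of a subject share one censoring time.

What the generator does *not* emulate: dropout or informative censoring,
treatment switching/crossover after progression (present in the real trial
and acknowledged there as diluting the OS contrast), cure fractions, or
covariate heterogeneity. Tests passing on synthetic data therefore validate
the machinery — estimation, selection, accounting, and arithmetic — not the
clinical realism of any particular extrapolation.

## Engine numerics

* **Cycle length** 21 days, matching the dosing schedule; the horizon
  (default 10 years, scenarios 20/30) is truncated to whole cycles and
  survival mass beyond it is ignored (no terminal value). Calendar
  conversions use 30.4375 days/month and 365.25 days/year.
* **Half-cycle correction**: person-time in state during a cycle is the
  trapezoid of boundary occupancies; it applies to both QALYs and
  recurring costs and can be switched off. Against a 100×-finer uncorrected
  grid, corrected life-years agree within 0.1%.
* **Discounting** at 5%/year (sensitivity 0–8%) with annual compounding,
  evaluated at cycle midpoints — the natural pairing with the trapezoid. At
  3-week resolution the discounted-annuity sum converges to the
  continuous-annuity closed form \((1-(1+r)^{-T})/\ln(1+r)\), and
  engine discounted life-years match direct numerical integration of
  \(S_{\mathrm{os}}(t)(1+r)^{-t}\) within 0.2%.

## Economic accounting

Per cycle, discounted at the midpoint: PFS occupancy carries first-line drug
cost (induction: histology-weighted chemotherapy backbone at BSA-scaled
doses, plus flat-dose toripalimab in TC; maintenance: toripalimab ±
pemetrexed for the non-squamous fraction, pemetrexed alone for PC),
administration, and surveillance laboratory tests (baseline, 6-weekly for 12
months, 9-weekly after); PD occupancy carries the second-line mix
(toripalimab for 13.3%/65.4% of TC/PC progressors, best supportive care —
or docetaxel at $0.22/mg in that scenario — for the rest);
hospitalization/nursing accrues in both alive states (the source is silent
on which; both is the conservative reading, separately configurable); new
deaths trigger a one-time hospice cost; and the grade-3/4 (≥5% incidence)
adverse-event cost and disutility bundles are charged once in cycle 1.
Dosing is mg-exact with no vial wastage. Induction length defaults to 6
cycles (protocol allowed 4–6; 6 is the conservative cost bound,
configurable). Second-line toripalimab is priced for the full PD dwell time,
mirroring BSC's per-cycle treatment, since its duration is otherwise
unstated. All computation is in USD; CNY configs convert at 6.4515 CNY/USD.

A hand-computed three-cycle ledger reproduces the accumulator to 1e−9, and
homogeneity (doubling every price doubles cost; utilities scale QALYs) is
tested as a property.

## Sensitivity analyses

* **One-way**: ±20% for cost parameters, ±10% for non-cost, the reported
  population limits for BSA (1.40–1.94 m²), 0–8% for discount rates, and
  ±36% for the toripalimab price. The source's "36% (20% up or down)"
  wording is internally inconsistent; we read the intent as a
  wider-than-default price band and implement ±36%, overridable. Output is
  a span-sorted tornado table with a WTP-crossing flag.
* **Probabilistic**: 1000 iterations; gamma for costs/prices, beta for
  utilities, truncated normal for BSA, moment-matched so the mean equals the
  base value and the SD is the one-way half-range ÷ 1.96 (a convention
  chosen to keep the two analyses consistent; it is recorded in the PSA
  parameter table). Second-line allocation fractions and all survival
  parameters are held fixed — no distribution is stated for them, and the
  survival-fit uncertainty is deliberately out of PSA scope, a known
  limitation. Survival fits and settings being fixed, occupancy traces are
  computed once and reused across iterations. Failed iterations are counted
  and excluded, never silently dropped. The CEAC grid is 0 to 2× WTP in 200
  steps.
* **Scenarios**: 20- and 30-year horizons and the docetaxel second-line
  switch, each applied as a single delta to the base configuration; an
  empty delta reproduces the base case bit-exactly.

## Calibration targets and problem sizes

The package's anchor to its source trial is parameter recovery at trial
scale: `median_recovery()` (censored log-normal MLE on arms of n = 220, 110
and 156, averaged over 200 replicates) reproduces the published medians of
8.3, 5.6 and 17.1 months, and `hr_recovery()` (Cox fits on simulated 2:1
exponential trials of n = 465) reproduces the published PFS hazard ratio of
0.49. The OS target tolerates a wider band (±0.8 months): with 16.2-month
median follow-up more than half of a 17.1-month-median arm is censored
beyond the median, so the fitted median is substantially extrapolated.

The published absolute results — base-case costs of $26,768 (PC) and
$45,268 (TC), the $32,237/QALY headline ICER, the scenario ICERs and the
90% CEAC probability at $37,654/QALY — depend on appendix-level unit costs,
utilities and digitized trial curves that are not publicly available.
They are therefore **not** reproduction targets of this package: the shipped
economic defaults are placeholders (every one flagged), and what *is*
verified exactly is the incremental arithmetic of the published table
(1.40 − 0.83 = 0.57 QALYs; $18,501/0.57 = $32,458/QALY from the printed
rounded values — the published $32,237 arises from unrounded internals) and
the threshold decision. Users replacing the placeholders with the appendix
values can attempt the headline ICER directly via `load_config()`.

Test-suite problem sizes were chosen to keep the full suite under about a
minute while leaving Monte Carlo margins comfortable: 10,000-subject
generator checks, 100-replicate model-recovery, 200-replicate HR recovery,
400- vs 4000-iteration PSA convergence.

## Known limitations

* No background general-population mortality is blended into the
  extrapolation; at 10–30-year horizons this can overstate tail survival.
* Survival uncertainty is excluded from the PSA (point extrapolations).
* The interval KM reconstruction assumes censoring only at end of follow-up.
* No vial-size rounding or drug wastage; no subgroup or crossover modelling;
  no EVPI.
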