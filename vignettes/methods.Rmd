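---
title: "Model and methods: sintilimab plus chemoradiotherapy in high-risk locoregionally advanced NPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npccea)
```

## The decision problem

Adding the PD-1 inhibitor sintilimab to gemcitabine–cisplatin induction
plus concurrent cisplatin radiotherapy improves event-free survival in
high-risk locoregionally advanced nasopharyngeal carcinoma, at the price
of twelve cycles of drug, more grade ≥3 toxicity, and different
post-progression management. `npccea` implements the cohort model that
weighs these against each other from the Chinese payer perspective.

## Model structure and assumptions

The cohort starts in the event-free state (EFS) and moves through
progressive disease (PD) to death on 21-day cycles, matching the
treatment cycle. Arm-level behaviour is driven entirely by two
parametric curves per arm — event-free survival and overall survival
(OS) — taken as log-logistic,

$$S(t) = \frac{1}{1 + \lambda t^{\gamma}},$$

with the published shape/scale values on the cycle timescale. That the
parameters are per-cycle is not arbitrary: evaluated at 36 months
(≈52.18 cycles) the fixture curves give 75.1% (standard arm EFS) and
84.2% (intervention arm), in line with the trial's reported 76% and
86%; month- or week-based readings do not reproduce these rates. The
log-logistic family was the published best fit by AIC/BIC; its heavy
tail is what makes the discounted lifetime horizon meaningful.

Occupancy is **partitioned survival** by default:
$occ_{EFS} = \min(S_{EFS}, S_{OS})$, $occ_{Death} = 1 - S_{OS}$, PD the
remainder. The standard-arm OS curve (shape 2.214) eventually falls
below its own EFS curve, and the intervention EFS curve crosses above
its OS curve at late times; in both cases EFS is clamped to OS, the
standard partitioned-survival convention. A **state-transition** mode is
provided as a structural cross-check: per-cycle exit probabilities
$p(t) = 1 - S(t+1)/S(t)$ move patients out of EFS, deaths are bounded by
the OS-implied death probability, and the PD death hazard is calibrated
each cycle so total deaths track OS. On non-crossing curves the two
modes agree exactly (the transition probabilities telescope back to the
curves), which the test suite asserts.

Discounting is 5% per year compounded continuously over cycle time,
$w(t) = 1.05^{-t \cdot 21/365.25}$. Half-cycle correction (averaging
state membership across cycle boundaries) is available but off in the
frozen settings; at a 21-day cycle its effect is far below the other
calibration uncertainties.

## Parameters

All parameters live in `fixture_inputs()` and are config-exposed:

* **Survival curves** — four log-logistic (shape, scale) pairs, unitless
  shape, scale per cycle^shape.
* **Unit costs (USD, 2024)** — per-cycle drug prices (sintilimab
  $303.85, induction agents, antiemetics), radiotherapy one-offs
  ($9,633.84 + $681.52 preparation), hospitalization ($126.78/cycle),
  laboratory ($74.85/cycle), follow-up testing ($378.12/time), PICC
  ($134.15/time), per-arm aggregate subsequent-therapy costs
  ($300.02 vs $540.60 per PD cycle), and per-event management costs for
  grade ≥3 adverse events with incidence ≥3%. Each carries its
  published (low, high) range. A body surface area of 1.72 m² and the
  exchange rate (1 USD = 7.1088 CNY) are metadata: the tables already
  print per-cycle USD, so neither is used in computation.
* **Adverse-event risks** — per-arm incidences; costed once per patient
  at treatment start as $\sum_i risk_i \times cost_i$ ($296.88
  intervention, $238.27 comparator, exact sums of the printed
  products).
* **Utilities** — $u_{EFS} = 0.76$ (0.61–0.91), $u_{PD} = 0.57$
  (0.46–0.68), death 0. QALYs are state person-years times the state
  utility.
* **Settings** — cycle 21 days, discount 0.05/year, horizon 800 cycles,
  WTP $37,710/QALY.

## Calibration of unpublished settings

The published analysis does not state its time horizon, half-cycle
setting, or the accrual windows for hospitalization, laboratory and
follow-up costs. These were treated as calibration knobs, set **once**
against the published baseline results table, then frozen in the
fixture; they are package settings, not estimates:

* **Horizon 800 cycles (~46 years).** The published 12.51 discounted
  intervention-arm life-years require a multi-decade horizon under the
  heavy-tailed OS curve; 800 cycles reproduces the arm totals and the
  4.24 incremental life-years closely.
* **Treatment phase** 7 cycles (comparator) / 12 cycles (intervention,
  spanning the sintilimab course), with hospitalization + laboratory per
  in-phase cycle; induction drugs cycles 1–3, radiotherapy at cycle 4
  with three concurrent cisplatin administrations; one PICC per
  induction cycle.
* **Surveillance**: one follow-up test per cycle while event-free after
  the treatment phase. This is the calibrated value (the natural prior
  would be quarterly): in this package's partitioned construction more
  person-time remains in EFS than the original model assigned there
  (see Limitations), so EFS carries the surveillance intensity needed
  to reproduce the aggregate arm costs.
* **PD state**: the arm-specific aggregate subsequent-therapy cost plus
  hospitalization and laboratory per cycle. The granular
  subsequent-therapy component prices are carried for reference only.

With these frozen settings the base case lands within the calibration
tolerances used throughout (±10% on arm-level life-years and QALYs,
±15% on arm-level costs and the ICER); the acceptance tests compute the
residuals rather than restating them here.

## Survival fitting and model selection

`fit_param_surv()` supports the five conventional families
(exponential, Weibull, log-logistic, log-normal, Gompertz) in two
modes:

* **Individual patient data** (`time`, `event`): right-censored maximum
  likelihood via `optim` on log-transformed parameters (raw shape for
  Gompertz, whose shape may be negative — a plateau/cure fraction; the
  shape→0 limit recovers the exponential). Starting values come from
  linearizing transforms of the Kaplan–Meier estimate. A test
  cross-checks parameters and log-likelihood against an independent
  fitting engine (`flexsurv`).
* **Digitized curve coordinates** (`time`, `survival`): weighted least
  squares on the survival fraction with weights proportional to the
  time interval each point represents, since digitizers sample curves
  unevenly. AIC/BIC use a Gaussian pseudo-likelihood on the residuals
  with $k = 1$ (exponential) or 2 parameters and $n$ = number of
  points. Non-monotone digitized input — the signature of digitization
  noise — is antitonic-regressed before fitting, with a warning.

The log-normal uses the mapping $\sigma = 1/\gamma$,
$\mu = -\log(\lambda)/\gamma$, so $\Phi^{-1}(1-S)$ is linear in
$\log t$ with slope $\gamma$ and intercept $\log\lambda$ — the same
(shape, scale) reading as the other families. `select_best()` takes the
lowest AIC; exact ties fall to BIC, then parsimony, and an AIC/BIC
disagreement is recorded on the result rather than silently resolved.

## Sensitivity analyses

**One-way (tornado).** Every wired parameter is set to its low and high
bound with the rest at base, and the ICER recomputed. The wired set is
every ranged cost row, every adverse-event risk (±20%, as no ranges are
published), and both utilities. Addressing parameters by name through
`set_param()` means an unwired name is an error, never a silent no-op.

**Probabilistic.** Beta (probabilities, utilities) and Gamma (costs)
distributions are matched by method of moments to the point estimate
and $SD = (high - low)/(2 \times 1.96)$, reading the published ranges
as 95% intervals. The survival parameters are *not* sampled — the
published distribution assignments cover only risks, costs and
utilities — though an exploratory switch (`sample_survival`) perturbs
log-parameters with a chosen CV and rebuilds the traces per draw.
Because the curves are fixed by default, the traces are computed once
and 1,000 iterations take seconds. A single `set.seed(seed)` governs
all draws sequentially; identical seeds give identical results to the
byte.

**A consequence worth stating plainly:** with the curves fixed, the
incremental QALY gain never approaches zero across draws, so the
simulated probability of cost-effectiveness at $37,710/QALY is
essentially 1.0, whereas the published analysis reports 95.4%. The
published probability evidently reflects uncertainty sources (most
plausibly survival-parameter uncertainty inside TreeAge) that its
tables do not parameterize. We keep the documented wiring and report
the discrepancy rather than back-fitting an arbitrary survival-
uncertainty level to hit 95.4%; the corresponding acceptance test is
expected to fail and says why.

**Subgroups.** Biomarker strata (PD-L1 CPS/TPS, baseline EBV DNA) are
published only as EFS hazard ratios, so `subgroup_scenario()` derives
the subgroup intervention curve by proportional hazards,
$S_{sub}(t) = S_{comp}(t)^{HR}$, and re-runs the pipeline. No default
HR values ship; they are user inputs.

## Synthetic data

The generators exist so the fitting and selection stages are testable
without any external download:

* `generate_km_points()` emulates graph digitization: the true $S(t)$
  sampled at chosen times plus Gaussian noise (default SD 0.01 survival
  fraction, a pixel-read error scale), clipped to [0, 1], optionally
  isotonized.
* `generate_pseudo_ipd()` draws event times by inverse CDF and applies
  independent exponential censoring whose rate is solved numerically so
  the expected censored fraction matches the request.

They emulate sampling noise and censoring, not the things that make
real digitized curves hard: step-function granularity at risk-set
sizes, correlated axis-calibration error, or informative censoring.
Passing recovery tests therefore demonstrates correctness of the
fitting machinery, not robustness to every real-world digitization
artifact.

## Numerical choices

* Degenerate inputs: $S(t) = 0$ makes the exit probability 1 with a
  warning (absorbing tail); zero-event curves are rejected as
  degenerate; a one-cycle horizon is legal.
* Optimizer non-convergence is flagged on the fit object, never
  silently accepted.
* Reports round to 2 decimals; all computation is full precision.
* The YAML fixture serializes numbers at 17 significant digits so a
  write/read round-trip is value-exact.

## Limitations

* **The published per-state split is not reproducible from its own
  curves.** The published baseline table assigns ~3.67 discounted PD
  life-years to the intervention arm, but the integral of
  $S_{OS} - S_{EFS}$ under its printed curves is ~0.46 years; no
  occupancy construction built from these curves can match the split.
  Totals, increments and ICERs are reproducible and are what this
  package targets; the EFS/PD decomposition it reports is internally
  consistent but intentionally not calibrated to the published split.
* The probabilistic probability of cost-effectiveness differs from the
  published 95.4% for the structural reason described above.
* Accrual windows for hospitalization/laboratory/follow-up are
  calibrated decisions, not published facts.
* No background (other-cause) mortality, tunnel states or
  microsimulation; the model inherits the trial population and the
  extrapolation risk of a 41.9-month-median-follow-up fit carried to a
  lifetime horizon.
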