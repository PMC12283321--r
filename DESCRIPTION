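Package: npccea
Title: Cost-Effectiveness of Adding Sintilimab to Chemoradiotherapy in
    High-Risk Locoregionally Advanced Nasopharyngeal Carcinoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-state (event-free survival, progressive disease,
    death) Markov cohort model on 21-day cycles for evaluating the
    addition of the PD-1 inhibitor sintilimab to induction-concurrent
    chemoradiotherapy in high-risk locoregionally advanced
    nasopharyngeal carcinoma, from the Chinese payer perspective.
    Provides parametric survival curves (exponential, Weibull,
    log-logistic, log-normal, Gompertz) with maximum-likelihood fitting
    to individual patient data and weighted least-squares fitting to
    digitized Kaplan-Meier coordinates, AIC/BIC model selection,
    partitioned-survival and state-transition cohort traces with
    discounting, cost and QALY accrual, incremental cost-effectiveness
    ratios, one-way deterministic sensitivity analysis (tornado),
    probabilistic sensitivity analysis with method-of-moments
    Beta/Gamma sampling, cost-effectiveness acceptability curves,
    proportional-hazards subgroup scenarios, and synthetic-data
    generators (digitized-curve points and censored pseudo individual
    patient data) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
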