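# shared ground-truth curves covering all five families, parameter values
# chosen so S spans most of (0, 1) over the first 60 cycles
truth_curves <- function() {
  list(
    exponential = param_surv("exponential", scale = 0.05),
    weibull     = param_surv("weibull", shape = 1.2, scale = 0.01),
    loglogistic = param_surv("loglogistic", shape = 1.23, scale = 0.00256),
    lognormal   = param_surv("lognormal", shape = 1.5, scale = 0.02),
    gompertz    = param_surv("gompertz", shape = 0.05, scale = 0.01))
}

# fixture with every unit cost set to zero (ranges collapsed accordingly)
zeroed_cost_inputs <- function() {
  inp <- fixture_inputs()
  inp$costs$base <- inp$costs$low <- inp$costs$high <- 0
  inp$ae_costs$base <- inp$ae_costs$low <- inp$ae_costs$high <- 0
  inp
}

make_strategy <- function(strategy, cost, ly, qaly) {
  structure(list(strategy = strategy, cost = cost, ly = ly, qaly = qaly,
                 by_state = data.frame(state = c("EFS", "PD"),
                                       cost = c(cost, 0), ly = c(ly, 0),
                                       qaly = c(qaly, 0))),
            class = "strategy_result")
}
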