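test_that("expected adverse-event costs reproduce the hand-summed products", {
  inp <- fixture_inputs()
  costs <- setNames(inp$ae_costs$base, inp$ae_costs$name)
  # oracle: explicit sums of the printed incidence x cost products
  sint <- 0.16 * 508.2 + 0.25 * 406.37 + 0.14 * 44.3 + 0.33 * 19.94 +
    0.10 * 26 + 0.21 * 406.37 + 0.04 * 16.64 + 0.07 * 110.3 + 0.11 * 44.3
  std <- 0.11 * 508.2 + 0.22 * 406.37 + 0.15 * 44.3 + 0.30 * 19.94 +
    0.07 * 26 + 0.18 * 406.37 + 0.03 * 16.64 + 0.11 * 44.3
  expect_equal(expected_ae_cost(inp$ae_risks$sintilimab, costs), sint)
  expect_equal(expected_ae_cost(inp$ae_risks$standard, costs), std)
  # exact to the cent
  expect_equal(round(sint, 2), 296.88)
  expect_equal(round(std, 2), 238.27)
  expect_equal(expected_ae_cost(c(anaemia = 0, nausea = 0), costs), 0)
  expect_error(expected_ae_cost(c(typhoid = 0.1), costs), "typhoid")
})

test_that("zero unit costs accrue zero cost", {
  fit <- cea_model(zeroed_cost_inputs(), horizon = 300)
  expect_equal(fit$strategies$sintilimab$cost, 0)
  expect_equal(fit$strategies$standard$cost, 0)
})

test_that("costs are linear: doubling every unit cost doubles the totals", {
  inp <- fixture_inputs()
  inp2 <- inp
  for (col in c("base", "low", "high")) {
    inp2$costs[[col]] <- 2 * inp$costs[[col]]
    inp2$ae_costs[[col]] <- 2 * inp$ae_costs[[col]]
  }
  f1 <- cea_model(inp, horizon = 300)
  f2 <- cea_model(inp2, horizon = 300)
  for (arm in c("sintilimab", "standard"))
    expect_equal(f2$strategies[[arm]]$cost,
                 2 * f1$strategies[[arm]]$cost, tolerance = 1e-12)
})

test_that("the sintilimab drug line sums to 12 cycles at the unit price", {
  inp <- fixture_inputs()
  sch_with <- treatment_schedule(inp, "sintilimab", horizon = 100)
  sch_without <- treatment_schedule(set_param(inp, "cost.sintilimab", 0),
                                    "sintilimab", horizon = 100)
  drug_line <- sch_with$efs_cycle - sch_without$efs_cycle
  expect_equal(sum(drug_line), 12 * 303.85)
  # discounted accrual is strictly below the undiscounted sum
  tr <- npccea:::arm_trace(inp, "sintilimab")
  disc <- sum(drug_line * tr$occ_efs[1:100] * tr$discount[1:100])
  expect_lt(disc, 12 * 303.85)
  expect_gt(disc, 0.9 * 12 * 303.85)  # accrues early, discount mild
})

test_that("QALYs are state years weighted by utilities", {
  expect_equal(8.84 * 0.76, 6.72, tolerance = 0.001)  # printed identity
  expect_equal(3.03 * 0.57, 1.73, tolerance = 0.002)
  tr <- run_trace(markov_spec(param_surv("exponential", scale = 0.05),
                              param_surv("exponential", scale = 0.02),
                              horizon = 300))
  eff <- accrue_qalys(tr, c(efs = 0.76, pd = 0.57))
  expect_equal(eff$qaly_efs, eff$ly_efs * 0.76)
  expect_equal(eff$qaly_pd, eff$ly_pd * 0.57)
  expect_equal(eff$ly, eff$ly_efs + eff$ly_pd)
  # utility 1 collapses QALYs to LYs
  eff1 <- accrue_qalys(tr, c(efs = 1, pd = 1))
  expect_equal(eff1$qaly, eff1$ly)
  expect_lte(eff$qaly, eff$ly)
  expect_error(accrue_qalys(tr, c(efs = 1.2, pd = 0.5)), "\\[0, 1\\]")
})

test_that("state decompositions sum to strategy totals", {
  fit <- cea_model(horizon = 400)
  for (arm in names(fit$strategies)) {
    st <- fit$strategies[[arm]]
    expect_equal(sum(st$by_state$cost), st$cost, tolerance = 1e-6)
    expect_equal(sum(st$by_state$ly), st$ly, tolerance = 1e-9)
    expect_equal(sum(st$by_state$qaly), st$qaly, tolerance = 1e-9)
    expect_true(st$cost >= 0 && st$ly >= 0 && st$qaly >= 0)
  }
})

test_that("totals are monotone non-decreasing in the horizon", {
  f1 <- cea_model(horizon = 200)
  f2 <- cea_model(horizon = 400)
  for (arm in c("sintilimab", "standard")) {
    expect_lt(f1$strategies[[arm]]$cost, f2$strategies[[arm]]$cost)
    expect_lt(f1$strategies[[arm]]$ly, f2$strategies[[arm]]$ly)
    expect_lt(f1$strategies[[arm]]$qaly, f2$strategies[[arm]]$qaly)
  }
})

test_that("incremental ratios follow their definition, with dominance flags", {
  a <- make_strategy("a", cost = 100000 + 24208.60, ly = 10, qaly = 8.1)
  b <- make_strategy("b", cost = 100000, ly = 10 - 4.24, qaly = 8.1 - 3.10)
  ic <- icer(a, b)
  expect_equal(ic$d_cost, 24208.60)
  expect_equal(ic$icer_qaly, 24208.60 / 3.10)  # 7809.23 on rounded inputs
  expect_equal(round(ic$icer_qaly, 2), 7809.23)
  expect_equal(ic$icer_ly, 24208.60 / 4.24)
  expect_equal(ic$dominance, "none")
  # identical strategies: equivalent, no ratio
  expect_equal(icer(a, a)$dominance, "equivalent")
  expect_true(is.na(icer(a, a)$icer_qaly))
  # costlier and less effective: dominated
  worse <- make_strategy("w", cost = 2e5, ly = 5, qaly = 4)
  expect_equal(icer(worse, a)$dominance, "dominated")
  expect_equal(icer(a, worse)$dominance, "dominant")
})

test_that("schedule horizon must match the trace", {
  inp <- fixture_inputs()
  tr <- npccea:::arm_trace(inp, "standard")
  sch <- treatment_schedule(inp, "standard", horizon = 10)
  expect_error(accrue_costs(tr, sch), "horizon")
})
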