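test_that("method-of-moments Beta/Gamma match the documented construction", {
  # u_EFS: mean 0.76, SD (0.91-0.61)/3.92 -> beta(22.9, 7.2)
  mp <- mom_params(0.76, 0.61, 0.91, "beta", "utility.efs")
  expect_equal(mp$alpha, 22.9, tolerance = 0.01)
  expect_equal(mp$beta, 7.23, tolerance = 0.01)
  expect_equal(mp$alpha / (mp$alpha + mp$beta), 0.76)
  # sintilimab price: gamma with mean 303.85, SD ~31.0
  mg <- mom_params(303.85, 243.08, 364.62, "gamma", "cost.sintilimab")
  expect_equal(mg$shape / mg$rate, 303.85)
  expect_equal(sqrt(mg$shape) / mg$rate, (364.62 - 243.08) / 3.92,
               tolerance = 1e-12)
  expect_equal(sqrt(mg$shape) / mg$rate, 31.0, tolerance = 0.001)
  # degenerate range passes the base through
  expect_equal(mom_params(5, 5, 5, "gamma")$dist, "fixed")
  # infeasible beta SD is refused, naming the parameter
  expect_error(mom_params(0.5, -3, 4, "beta", "utility.efs"),
               "utility.efs")
})

test_that("sampled moments match their targets within Monte-Carlo error", {
  set.seed(101)
  pt <- data.frame(name = c("u", "c"), base = c(0.76, 303.85),
                   low = c(0.61, 243.08), high = c(0.91, 364.62),
                   dist = c("beta", "gamma"))
  d <- sample_parameters(pt, n = 1e5)
  expect_equal(mean(d[, "u"]), 0.76, tolerance = 0.005)
  expect_equal(mean(d[, "c"]), 303.85, tolerance = 0.005)
  expect_true(all(d[, "u"] > 0 & d[, "u"] < 1))
  expect_true(all(d[, "c"] > 0))
  expect_equal(sd(d[, "u"]), (0.91 - 0.61) / 3.92, tolerance = 0.02)
})

test_that("tornado ranks by spread; flat parameters rank last", {
  inp <- fixture_inputs()
  pt <- param_table(inp)
  pt <- pt[pt$name %in% c("utility.efs", "cost.sintilimab",
                          "cost.followup_test", "risk.sintilimab.leukopenia"), ]
  pt[pt$name == "risk.sintilimab.leukopenia", c("low", "high")] <- 0.25
  tor <- one_way_dsa(inp, pt)
  expect_true(all(diff(tor$spread) <= 0))
  expect_equal(tor$name[nrow(tor)], "risk.sintilimab.leukopenia")
  expect_equal(tor$spread[nrow(tor)], 0)
  # EFS utility is a top-ranked parameter
  expect_true("utility.efs" %in% tor$name[1:2])
  # intervention-only price raises the ICER monotonically
  srow <- tor[tor$name == "cost.sintilimab", ]
  expect_lt(srow$icer_low, srow$icer_high)
  expect_error(one_way_dsa(inp, data.frame(
    name = "cost.unobtainium", base = 1, low = 0, high = 2,
    dist = "gamma", role = "cost")), "not wired")
})

test_that("a cost borne by both arms moves the ICER less than an intervention-only cost", {
  inp <- fixture_inputs()
  swing <- 50  # identical absolute low/high swing for both parameters
  pt <- data.frame(
    name = c("cost.antiemetics", "cost.sintilimab"),
    base = c(65.55, 303.85),
    low = c(65.55 - swing, 303.85 - swing),
    high = c(65.55 + swing, 303.85 + swing),
    dist = "gamma", role = "cost")
  tor <- one_way_dsa(inp, pt)
  shared <- tor$spread[tor$name == "cost.antiemetics"]
  only_int <- tor$spread[tor$name == "cost.sintilimab"]
  expect_lt(shared, only_int / 3)
})

test_that("the probabilistic analysis is reproducible and degenerates correctly", {
  inp <- fixture_inputs()
  p1 <- run_psa(inp, n_iter = 50, seed = 7)
  p2 <- run_psa(inp, n_iter = 50, seed = 7)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$prob_ce, p2$prob_ce)
  p3 <- run_psa(inp, n_iter = 50, seed = 8)
  expect_false(identical(p1$draws, p3$draws))
  # collapsed ranges: every draw reproduces the base case
  base <- cea_model(inp)
  pt <- param_table(inp)
  pt$low <- pt$high <- pt$base
  pd <- run_psa(inp, n_iter = 5, seed = 1, params = pt)
  expect_equal(unique(round(pd$draws$d_cost, 8)),
               round(base$icer$d_cost, 8))
  expect_equal(unique(round(pd$draws$d_qaly, 8)),
               round(base$icer$d_qaly, 8))
})

test_that("the acceptability curve is the NMB exceedance fraction", {
  # single synthetic draw: step from 0 to 1 at WTP = dC/dQ
  psa <- structure(list(draws = data.frame(d_cost = 100, d_ly = 0.02,
                                           d_qaly = 0.01, nmb = NA),
                        wtp = 37710), class = "cea_psa")
  cc <- ceac(psa, wtp_grid = c(0, 5000, 9999, 10001, 50000))
  expect_equal(cc$prob_ce, c(0, 0, 0, 1, 1))
  # order invariance of the grid
  cc_rev <- ceac(psa, wtp_grid = rev(c(0, 5000, 9999, 10001, 50000)))
  expect_identical(cc, cc_rev)
  expect_error(ceac(psa, wtp_grid = numeric(0)), "non-empty")

  inp <- fixture_inputs()
  p <- run_psa(inp, n_iter = 100, seed = 2)
  cc2 <- ceac(p, wtp_grid = c(0, 37710, 80000))
  # the curve at the reference threshold equals the summary probability
  expect_equal(cc2$prob_ce[cc2$wtp == 37710], p$prob_ce)
  # at WTP 0 the NMB reduces to -dCost
  expect_equal(cc2$prob_ce[cc2$wtp == 0], mean(p$draws$d_cost < 0))
  # all draws gain QALYs here, so the curve is non-decreasing
  expect_true(all(p$draws$d_qaly > 0))
  expect_true(all(diff(cc2$prob_ce) >= 0))
})

test_that("subgroup hazard-ratio scenarios behave analytically", {
  inp <- fixture_inputs()
  base_efs <- inp$curves$standard$efs
  # HR = 1 reproduces the comparator's event-free curve
  f1 <- subgroup_scenario(inp, 1)
  tt <- c(1, 20, 100)
  expect_equal(surv_prob(f1$inputs$curves$sintilimab$efs, tt),
               surv_prob(base_efs, tt))
  # HR -> 0: no events at any finite time
  expect_equal(surv_prob(ph_surv(base_efs, 1e-12), c(10, 500)), c(1, 1),
               tolerance = 1e-9)
  # smaller HR -> uniformly higher subgroup EFS and a lower ICER
  s_half <- surv_prob(ph_surv(base_efs, 0.5), 1:400)
  s_08 <- surv_prob(ph_surv(base_efs, 0.8), 1:400)
  expect_true(all(s_half > s_08))
  f_half <- subgroup_scenario(inp, 0.5)
  f_08 <- subgroup_scenario(inp, 0.8)
  expect_lt(f_half$icer$icer_qaly, f_08$icer$icer_qaly)
  expect_error(subgroup_scenario(inp, -1), "positive")
})
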