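test_that("closed-form survival matches the trial's printed 36-month rates", {
  t36 <- 36 * 30.4375 / 21  # 36 months in 21-day cycles (~52.18)
  std <- param_surv("loglogistic", shape = 1.2297630, scale = 0.0025608)
  sint <- param_surv("loglogistic", shape = 0.7947444, scale = 0.0081186)
  expect_equal(surv_prob(std, t36), 0.751, tolerance = 0.001 / 0.751)
  expect_equal(surv_prob(sint, t36), 0.842, tolerance = 0.001 / 0.842)
  # OS curve at 36 months drives the death occupancy used downstream
  os_std <- param_surv("loglogistic", shape = 2.214, scale = 0.00001507)
  expect_equal(1 - surv_prob(os_std, t36), 0.087, tolerance = 0.01)
})

test_that("S(0) = 1, S is non-increasing and in [0,1] for every family", {
  grid <- seq(0, 400, by = 0.5)
  for (m in truth_curves()) {
    s <- surv_prob(m, grid)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    # heavy computation families decay towards 0
    expect_lt(surv_prob(m, 1e5), 0.02)
  }
  expect_error(surv_prob(truth_curves()$weibull, -1), "non-negative")
  expect_error(param_surv("weibull", shape = -1, scale = 1), "positive")
  expect_error(param_surv("loglogistic", shape = 1, scale = Inf), "finite")
  # Gompertz admits negative shape (plateau) without error
  g <- param_surv("gompertz", shape = -0.05, scale = 0.01)
  expect_gt(surv_prob(g, 1e6), 0)
})

test_that("per-cycle exit probabilities follow 1 - S(t+1)/S(t)", {
  ex <- param_surv("exponential", scale = 0.05)
  expect_equal(trans_prob(ex, 0:9), rep(1 - exp(-0.05), 10))
  ll <- param_surv("loglogistic", shape = 1.2297630, scale = 0.0025608)
  expect_equal(trans_prob(ll, 0), 1 - 1 / (1 + 0.0025608),
               tolerance = 1e-10)
  # telescoping: cumulative product of survivals reproduces S(t)
  for (m in truth_curves()) {
    p <- trans_prob(m, 0:49)
    expect_equal(cumprod(1 - p), surv_prob(m, 1:50), tolerance = 1e-12)
  }
  expect_error(trans_prob(ex, 1.5), "integer")
})

test_that("AIC/BIC follow their defining arithmetic", {
  f <- npccea:::new_fit(param_surv("weibull", 1, 1), ll = -10, k = 2,
                        n = 30, converged = TRUE, method = "ipd")
  expect_equal(f$AIC, 24)               # 2*2 - 2*(-10)
  expect_equal(f$BIC, 2 * log(30) + 20) # k log n - 2 loglik
  expect_equal(AIC(f), f$AIC)
  expect_equal(BIC(f), f$BIC)
})

test_that("noiseless digitized curves are recovered within 1% for all families", {
  for (fam in names(truth_curves())) {
    m <- truth_curves()[[fam]]
    pts <- generate_km_points(m, times = 1:60, noise_sd = 0)
    fit <- fit_param_surv(pts, fam)
    expect_true(fit$converged, info = fam)
    expect_equal(fit$model$shape, m$shape, tolerance = 0.01, info = fam)
    expect_equal(fit$model$scale, m$scale, tolerance = 0.01, info = fam)
  }
})

test_that("censored maximum likelihood recovers the exponential rate", {
  ipd <- generate_pseudo_ipd(param_surv("exponential", scale = 0.05),
                             n = 5000, censor_rate = 0.2, seed = 11)
  fit <- fit_param_surv(ipd, "exponential")
  expect_equal(fit$model$scale, 0.05, tolerance = 0.03)
  expect_equal(fit$df, 1)
  expect_equal(fit$n_obs, 5000)
})

test_that("likelihood fits agree with an independent survival-fitting engine", {
  skip_if_not_installed("flexsurv")
  ipd <- generate_pseudo_ipd(param_surv("weibull", 1.2, 0.01), n = 800,
                             censor_rate = 0.2, seed = 5)
  ours <- fit_param_surv(ipd, "weibull")
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                              dist = "weibull")
  a <- fs$res["shape", "est"]; b <- fs$res["scale", "est"]
  expect_equal(ours$loglik, fs$loglik, tolerance = 1e-5)
  expect_equal(ours$model$shape, a, tolerance = 1e-3)
  expect_equal(ours$model$scale, b^(-a), tolerance = 1e-3)
})

test_that("degenerate and malformed fitting inputs are rejected", {
  flat <- data.frame(time = 1:10, survival = rep(1, 10))
  expect_error(fit_param_surv(flat, "weibull"), "degenerate")
  expect_error(fit_param_surv(data.frame(time = 1:2, survival = c(.9, .8)),
                              "weibull"), "at least 3")
  expect_error(fit_param_surv(data.frame(time = 1:5, survival = c(.9, .8, .7, 1.2, .5)),
                              "weibull"), "\\(0, 1\\]")
  noevents <- data.frame(time = 1:20, event = rep(0, 20))
  expect_error(fit_param_surv(noevents, "exponential"), "no events")
  expect_error(fit_param_surv(data.frame(time = 1:20, event = rep(1, 20)),
                              "cauchy"))
})

test_that("non-monotone digitized input is isotonized with a warning", {
  m <- param_surv("weibull", 1.2, 0.01)
  pts <- generate_km_points(m, times = 1:40, noise_sd = 0)
  pts$survival[20] <- pts$survival[19] + 0.05  # digitization glitch
  expect_warning(fit <- fit_param_surv(pts, "weibull"), "antitonic")
  expect_equal(fit$model$shape, 1.2, tolerance = 0.05)
})

test_that("model selection picks the generating family at large n", {
  ipd <- generate_pseudo_ipd(param_surv("loglogistic", 1.23, 0.00256),
                             n = 2000, censor_rate = 0.1, seed = 42)
  best <- select_best(fit_all_families(ipd))
  expect_equal(best$family, "loglogistic")
})

test_that("selection tie-breaks and edge cases behave as documented", {
  expect_error(select_best(list()), "non-empty")
  m <- param_surv("weibull", 1, 1)
  f1 <- npccea:::new_fit(m, ll = -10, k = 2, n = 50, TRUE, "ipd")
  expect_identical(select_best(list(f1)), f1)
  # equal AIC: lower BIC (i.e. fewer parameters at equal AIC) wins
  f2 <- npccea:::new_fit(param_surv("exponential", scale = 1),
                         ll = -11, k = 1, n = 50, TRUE, "ipd")
  expect_equal(f1$AIC, f2$AIC)
  expect_lt(f2$BIC, f1$BIC)
  expect_equal(select_best(list(f1, f2))$family, "exponential")
  # AIC/BIC disagreement is recorded
  f3 <- npccea:::new_fit(m, ll = -9.5, k = 2, n = 50, TRUE, "ipd")
  pick <- select_best(list(f2, f3))
  expect_equal(pick$family, "weibull")        # lower AIC
  expect_match(attr(pick, "selection_note"), "BIC selects exponential")
})

test_that("proportional-hazards transform powers the baseline curve", {
  base <- param_surv("loglogistic", 1.23, 0.00256)
  sub <- ph_surv(base, 0.5)
  tt <- c(1, 10, 50)
  expect_equal(surv_prob(sub, tt), surv_prob(base, tt)^0.5)
  expect_error(ph_surv(base, 0), "positive")
})
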