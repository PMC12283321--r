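#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the incremental cost-effectiveness ratio per QALY with
#' each wired parameter set to its low and to its high value in turn,
#' all other parameters held at base. Rows are sorted by decreasing
#' ICER spread, the ordering drawn in a tornado diagram.
#'
#' @param inputs A `cea_inputs` object.
#' @param params Parameter table as produced by [param_table()]; rows
#'   may be dropped to restrict the analysis. Names not wired into the
#'   model raise an error.
#' @return A data frame of class `tornado` with columns `name`, `base`,
#'   `low`, `high`, `icer_low`, `icer_high`, `spread`, sorted by
#'   descending `spread`. The base-case ICER is attached as attribute
#'   `"icer_base"`.
#' @export
one_way_dsa <- function(inputs, params = param_table(inputs)) {
  validate_inputs(inputs)
  if (any(!is.finite(params$low)) || any(!is.finite(params$high)))
    stop("every parameter needs finite low/high bounds", call. = FALSE)
  base_fit <- cea_model(inputs)
  icer_at <- function(name, value) {
    fit <- cea_model(set_param(inputs, name, value))
    fit$icer$icer_qaly
  }
  icer_low <- icer_high <- numeric(nrow(params))
  for (i in seq_len(nrow(params))) {
    icer_low[i] <- icer_at(params$name[i], params$low[i])
    icer_high[i] <- icer_at(params$name[i], params$high[i])
  }
  out <- data.frame(params[c("name", "base", "low", "high")],
                    icer_low = icer_low, icer_high = icer_high,
                    spread = abs(icer_high - icer_low))
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base_fit$icer$icer_qaly
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
print.tornado <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis (base ICER $%.2f/QALY)\n",
              attr(x, "icer_base")))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... %d more parameters\n", nrow(x) - n))
  invisible(x)
}

#' Tornado diagram
#'
#' @param x A [one_way_dsa()] result.
#' @param n Number of top-ranked parameters to draw.
#' @param ... Unused.
#' @export
plot.tornado <- function(x, n = 12, ...) {
  d <- utils::head(as.data.frame(x), n)
  d <- d[rev(seq_len(nrow(d))), ]
  b <- attr(x, "icer_base")
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  ylim <- c(0.5, nrow(d) + 0.5)
  xlim <- range(c(d$icer_low, d$icer_high, b))
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "",
                 main = "One-way sensitivity analysis")
  for (i in seq_len(nrow(d)))
    graphics::rect(pmin(d$icer_low[i], d$icer_high[i]), i - 0.35,
                   pmax(d$icer_low[i], d$icer_high[i]), i + 0.35,
                   col = "steelblue", border = NA)
  graphics::abline(v = b, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$name, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

## ---- probabilistic sensitivity analysis --------------------------------

#' Method-of-moments distribution parameters
#'
#' The published tables give a point estimate and a (low, high) range
#' for each sampled parameter but no standard deviation; the range is
#' treated as a 95% interval, so \eqn{SD = (high - low) / (2 \times
#' 1.96)}. Beta parameters (for probabilities and utilities) and Gamma
#' parameters (for costs) are then matched to the mean and that SD.
#'
#' @param base,low,high Point estimate and range.
#' @param dist `"beta"` or `"gamma"`.
#' @param name Parameter name used in error messages.
#' @return List with the distribution family and its parameters
#'   (`alpha`/`beta` or `shape`/`rate`); `sd = 0` collapses to a
#'   degenerate (fixed) draw.
#' @export
mom_params <- function(base, low, high, dist = c("beta", "gamma"),
                       name = "parameter") {
  dist <- match.arg(dist)
  sdev <- (high - low) / (2 * 1.96)
  if (sdev == 0) return(list(dist = "fixed", value = base))
  if (dist == "beta") {
    if (base <= 0 || base >= 1)
      stop(sprintf("beta mean for '%s' must be in (0, 1)", name),
           call. = FALSE)
    if (sdev^2 >= base * (1 - base))
      stop(sprintf("method of moments infeasible for '%s': SD too large for a beta mean of %g",
                   name, base), call. = FALSE)
    nu <- base * (1 - base) / sdev^2 - 1
    list(dist = "beta", alpha = base * nu, beta = (1 - base) * nu)
  } else {
    if (base <= 0)
      stop(sprintf("gamma mean for '%s' must be positive", name),
           call. = FALSE)
    list(dist = "gamma", shape = base^2 / sdev^2, rate = base / sdev^2)
  }
}

#' Sample parameter vectors for the probabilistic analysis
#'
#' @param params Parameter table ([param_table()]).
#' @param n Number of draws.
#' @return An `n` by `nrow(params)` matrix with parameter names as
#'   column names. Uses the current RNG state; seed upstream for
#'   reproducibility.
#' @export
sample_parameters <- function(params, n = 1) {
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(params),
                  dimnames = list(NULL, params$name))
  for (i in seq_len(nrow(params))) {
    mp <- mom_params(params$base[i], params$low[i], params$high[i],
                     params$dist[i], params$name[i])
    draws[, i] <- switch(mp$dist,
      fixed = rep(mp$value, n),
      beta  = stats::rbeta(n, mp$alpha, mp$beta),
      gamma = stats::rgamma(n, shape = mp$shape, rate = mp$rate))
  }
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of all wired parameters (Beta for
#' probabilities and utilities, Gamma for costs; survival-curve
#' parameters fixed unless `sample_survival = TRUE`), with a full model
#' evaluation per draw. Because the survival curves are fixed by
#' default, the cohort traces are computed once and only the accrual is
#' repeated, which keeps 1,000 iterations under a few seconds.
#'
#' With `sample_survival = TRUE` the log shape and log scale of each
#' curve are additionally perturbed by independent normals with
#' coefficient of variation `survival_cv`, and the traces are rebuilt
#' per draw (an exploratory switch; no published uncertainty is
#' available for these parameters).
#'
#' @param inputs A `cea_inputs` object.
#' @param n_iter Number of draws (>= 1); 1,000 in the reference
#'   analysis.
#' @param seed Integer seed; all randomness flows from it.
#' @param wtp Willingness-to-pay threshold for the cost-effectiveness
#'   probability.
#' @param params Parameter table ([param_table()]); rows may be dropped
#'   or ranges altered to restrict what is sampled.
#' @param sample_survival,survival_cv See Details.
#' @return An object of class `cea_psa`: list with `draws` (data frame
#'   with one row per iteration: `d_cost`, `d_ly`, `d_qaly`, `nmb`),
#'   `prob_ce`, `mean_d_cost`, `mean_d_qaly`, `wtp`, `seed`, `n_iter`.
#' @export
run_psa <- function(inputs, n_iter = 1000, seed = 1,
                    wtp = inputs$settings$wtp,
                    params = param_table(inputs),
                    sample_survival = FALSE, survival_cv = 0.1) {
  validate_inputs(inputs)
  if (n_iter < 1) stop("'n_iter' must be >= 1", call. = FALSE)
  set.seed(seed)
  draws <- sample_parameters(params, n_iter)
  arms <- names(inputs$curves)
  traces <- NULL
  if (!sample_survival) {
    traces <- lapply(arms, function(a) arm_trace(inputs, a))
    names(traces) <- arms
  }
  d_cost <- d_ly <- d_qaly <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    inp <- inputs
    for (j in seq_len(ncol(draws)))
      inp <- set_param(inp, colnames(draws)[j], draws[it, j])
    if (sample_survival) {
      inp$curves <- lapply(inp$curves, function(arm) lapply(arm, function(cv) {
        param_surv(cv$family,
                   shape = exp(stats::rnorm(1, log(cv$shape), survival_cv)),
                   scale = exp(stats::rnorm(1, log(cv$scale), survival_cv)))
      }))
      tr <- lapply(arms, function(a) arm_trace(inp, a))
      names(tr) <- arms
    } else tr <- traces
    res <- lapply(arms, function(a)
      evaluate_strategy(inp, a, trace = tr[[a]]))
    names(res) <- arms
    d_cost[it] <- res$sintilimab$cost - res$standard$cost
    d_ly[it] <- res$sintilimab$ly - res$standard$ly
    d_qaly[it] <- res$sintilimab$qaly - res$standard$qaly
  }
  nmb <- wtp * d_qaly - d_cost
  structure(list(
    draws = data.frame(d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
                       nmb = nmb),
    prob_ce = mean(nmb > 0), mean_d_cost = mean(d_cost),
    mean_d_qaly = mean(d_qaly), wtp = wtp, seed = seed,
    n_iter = n_iter), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %d)\n",
              x$n_iter, x$seed))
  cat(sprintf("  mean dCost $%.2f, mean dQALY %.4f\n",
              x$mean_d_cost, x$mean_d_qaly))
  cat(sprintf("  P(cost-effective at $%s/QALY) = %.3f\n",
              format(x$wtp, big.mark = ","), x$prob_ce))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic
#' draws with positive incremental net monetary benefit
#' \eqn{NMB = WTP \times \Delta QALY - \Delta Cost}.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty vector of willingness-to-pay values
#'   (USD/QALY); the default covers $0 to $80,000 and includes the
#'   $37,710 threshold.
#' @return A data frame of class `ceac` with columns `wtp` and
#'   `prob_ce`, sorted by `wtp`.
#' @export
ceac <- function(psa, wtp_grid = c(seq(0, 80000, by = 2000), 37710)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) == 0) stop("'wtp_grid' must be non-empty",
                                  call. = FALSE)
  wtp_grid <- sort(unique(wtp_grid))
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$d_qaly - psa$draws$d_cost > 0), 0)
  structure(data.frame(wtp = wtp_grid, prob_ce = prob),
            class = c("ceac", "data.frame"))
}

#' @export
#' @param x A `cea_psa` object.
#' @param type `"ceac"` for the acceptability curve, `"plane"` for the
#'   incremental cost-effectiveness plane.
#' @param ... Unused.
#' @rdname run_psa
plot.cea_psa <- function(x, type = c("ceac", "plane"), ...) {
  type <- match.arg(type)
  if (type == "ceac") {
    cc <- ceac(x)
    graphics::plot(cc$wtp, cc$prob_ce, type = "l", ylim = c(0, 1),
                   xlab = "willingness-to-pay (USD/QALY)",
                   ylab = "P(sintilimab cost-effective)",
                   main = "Cost-effectiveness acceptability curve")
    graphics::abline(v = x$wtp, lty = 2)
  } else {
    graphics::plot(x$draws$d_qaly, x$draws$d_cost, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "incremental QALYs",
                   ylab = "incremental cost (USD)",
                   main = "Incremental cost-effectiveness plane")
    graphics::abline(0, x$wtp, lty = 2)
  }
  invisible(x)
}

## ---- subgroup scenarios -------------------------------------------------

#' Subgroup scenario via a proportional-hazards shift
#'
#' Biomarker-defined subgroups (PD-L1 CPS/TPS strata, baseline EBV DNA
#' level) are reported only as hazard ratios for event-free survival.
#' The subgroup's intervention EFS curve is derived from the comparator
#' curve by proportional hazards, \eqn{S_{sub}(t) = S_{comp}(t)^{HR}},
#' and the model is re-run with all other inputs unchanged.
#'
#' @param inputs A `cea_inputs` object.
#' @param hr_efs Subgroup hazard ratio for event-free survival (> 0).
#' @param label Optional subgroup label.
#' @return A `cea` object for the subgroup scenario.
#' @export
subgroup_scenario <- function(inputs, hr_efs, label = NULL) {
  if (!is.numeric(hr_efs) || length(hr_efs) != 1L || !is.finite(hr_efs) ||
      hr_efs <= 0)
    stop("'hr_efs' must be a single positive hazard ratio", call. = FALSE)
  inputs$curves$sintilimab$efs <- ph_surv(inputs$curves$standard$efs,
                                          hr_efs)
  fit <- cea_model(inputs)
  fit$subgroup <- list(hr_efs = hr_efs,
                       label = label %||% sprintf("HR %.2f", hr_efs))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
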