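#' Quantile function of a parametric survival curve
#'
#' Solves \eqn{S(t) = p} for `t` (cycles). Used by the inverse-CDF
#' event-time simulator.
#'
#' @param x A [param_surv()] curve.
#' @param p Survival fractions in (0, 1].
#' @return Times in cycles; `Inf` where the curve plateaus above `p`
#'   (possible only for Gompertz with negative shape).
#' @export
surv_quantile <- function(x, p) {
  stopifnot(inherits(x, "param_surv"), all(p > 0), all(p <= 1))
  g <- x$shape; l <- x$scale
  switch(x$family,
    exponential = -log(p) / l,
    weibull     = (-log(p) / l)^(1 / g),
    loglogistic = ((1 / p - 1) / l)^(1 / g),
    lognormal   = stats::qlnorm(p, meanlog = -log(l) / g, sdlog = 1 / g,
                                lower.tail = FALSE),
    gompertz    = {
      if (abs(g) < 1e-12) -log(p) / l
      else {
        arg <- 1 - g * log(p) / l
        ifelse(arg > 0, log(arg) / g, Inf)
      }
    })
}

#' Simulate pseudo individual patient data
#'
#' Draws event times from a parametric curve by inverse-CDF sampling and
#' applies independent exponential right censoring whose rate is solved
#' so that the expected censored fraction matches `censor_rate`. This is
#' the ground-truth generator used to exercise the fitting and
#' model-selection stages without any external data.
#'
#' @param object A [param_surv()] curve.
#' @param nsim Number of subjects.
#' @param seed Integer seed (required for reproducibility; `NULL` uses
#'   the current RNG state).
#' @param censor_rate Expected censored fraction in \eqn{[0, 1)}.
#' @param ... Unused.
#' @return A data frame with columns `time` (cycles) and `event` (1 =
#'   event, 0 = censored).
#' @examples
#' ipd <- simulate(param_surv("exponential", scale = 0.05), 500, seed = 7)
#' @export
simulate.param_surv <- function(object, nsim = 1, seed = NULL,
                                censor_rate = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (nsim < 1) stop("'nsim' must be >= 1", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must be in [0, 1)", call. = FALSE)
  u <- stats::runif(nsim)
  t_event <- surv_quantile(object, u)
  # a Gompertz plateau leaves never-event subjects; treat them as
  # censored at the largest finite draw
  if (any(!is.finite(t_event))) {
    cap <- max(t_event[is.finite(t_event)], 1) * 10
    t_event[!is.finite(t_event)] <- cap
  }
  if (censor_rate == 0)
    return(data.frame(time = t_event, event = rep(1, nsim)))
  # solve the exponential censoring rate so the expected censored
  # fraction over the drawn event times equals censor_rate
  f <- function(rate) mean(1 - exp(-rate * t_event)) - censor_rate
  rate <- stats::uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-10)$root
  t_cens <- stats::rexp(nsim, rate)
  data.frame(time = pmin(t_event, t_cens),
             event = as.numeric(t_event <= t_cens))
}

#' @rdname simulate.param_surv
#' @param model A [param_surv()] curve.
#' @param n Number of subjects.
#' @export
generate_pseudo_ipd <- function(model, n, censor_rate = 0, seed = NULL) {
  simulate(model, nsim = n, seed = seed, censor_rate = censor_rate)
}

#' Generate digitized Kaplan-Meier-style coordinates
#'
#' Emulates graph digitization of a published survival curve: the true
#' \eqn{S(t)} is read at the given times and perturbed with Gaussian
#' noise (default SD 0.01 survival fraction, mimicking pixel-reading
#' error), clipped to \eqn{[0, 1]}. Optionally the noisy points are made
#' monotone by antitonic regression, as a careful digitizer would.
#'
#' @param model A survival-curve object.
#' @param times Increasing positive times in cycles.
#' @param noise_sd Gaussian noise SD on the survival fraction (>= 0).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param isotonic Enforce monotone non-increasing output?
#' @param arm,endpoint Optional labels carried as attributes.
#' @return A data frame with columns `time` and `survival`, suitable for
#'   [fit_param_surv()].
#' @export
generate_km_points <- function(model, times, noise_sd = 0.01, seed = NULL,
                               isotonic = FALSE, arm = NULL,
                               endpoint = NULL) {
  if (any(diff(times) <= 0) || any(times < 0))
    stop("'times' must be non-negative and strictly increasing",
         call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- surv_prob(model, times)
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), 0, noise_sd)
  s <- pmin(pmax(s, 1e-9), 1)
  if (isotonic) s <- pmin(pmax(-stats::isoreg(times, -s)$yf, 1e-9), 1)
  structure(data.frame(time = times, survival = s),
            arm = arm, endpoint = endpoint)
}

#' Write / read digitized-curve coordinates as CSV
#'
#' The on-disk format is a two-column CSV with header
#' `time_cycles,survival`, one curve per file.
#'
#' @param points A data frame from [generate_km_points()] (columns
#'   `time`, `survival`).
#' @param path File path.
#' @return `write_km_csv` returns `path` invisibly; `read_km_csv`
#'   returns a data frame with columns `time` and `survival`.
#' @export
write_km_csv <- function(points, path) {
  utils::write.csv(data.frame(time_cycles = points$time,
                              survival = points$survival),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_km_csv
#' @export
read_km_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_cycles", "survival") %in% names(d)))
    stop("expected columns 'time_cycles' and 'survival'", call. = FALSE)
  data.frame(time = d$time_cycles, survival = d$survival)
}
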