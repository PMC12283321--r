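#' Parametric survival curve
#'
#' Constructs a parametric survival curve \eqn{S(t)} on the model's cycle
#' timescale (1 cycle = 21 days). Five families are supported, in the
#' shape/scale parameterizations conventional in partitioned-survival
#' decision models:
#'
#' \describe{
#'   \item{exponential}{\eqn{S(t) = e^{-\lambda t}} (one free parameter,
#'     the rate \eqn{\lambda}; `shape` is fixed at 1).}
#'   \item{weibull}{\eqn{S(t) = e^{-\lambda t^{\gamma}}}.}
#'   \item{loglogistic}{\eqn{S(t) = 1 / (1 + \lambda t^{\gamma})}.}
#'   \item{lognormal}{\eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)} with the
#'     mapping \eqn{\sigma = 1/\gamma}, \eqn{\mu = -\log(\lambda)/\gamma},
#'     so that \eqn{\Phi^{-1}(1 - S) = \gamma \log t + \log \lambda} is
#'     linear in \eqn{\log t} with slope `shape` and intercept
#'     \eqn{\log(\lambda)}.}
#'   \item{gompertz}{\eqn{S(t) = \exp(-\lambda (e^{\gamma t} - 1)/\gamma)}.
#'     The shape \eqn{\gamma} may be any real number; \eqn{\gamma < 0}
#'     gives a plateau (cure fraction) \eqn{\exp(\lambda/\gamma)} and
#'     \eqn{\gamma \to 0} recovers the exponential.}
#' }
#'
#' Throughout, `shape` is \eqn{\gamma} and `scale` is \eqn{\lambda}.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param shape Shape parameter \eqn{\gamma} (> 0 except Gompertz, where any
#'   real value is allowed; ignored and fixed at 1 for the exponential).
#' @param scale Scale parameter \eqn{\lambda} (> 0), on the per-cycle
#'   timescale appropriate to the family.
#' @return An object of class `param_surv`.
#' @examples
#' efs_std <- param_surv("loglogistic", shape = 1.2297630, scale = 0.0025608)
#' surv_prob(efs_std, 52.18)  # ~0.751 at 36 months
#' @seealso [surv_prob()], [trans_prob()], [fit_param_surv()],
#'   [simulate.param_surv()]
#' @export
param_surv <- function(family, shape = 1, scale) {
  family <- match.arg(family, surv_families())
  if (family == "exponential") shape <- 1
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape))
    stop("'shape' must be a single finite number", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("'scale' must be a single positive finite number", call. = FALSE)
  if (family != "gompertz" && shape <= 0)
    stop("'shape' must be positive for the ", family, " family",
         call. = FALSE)
  structure(list(family = family, shape = as.numeric(shape),
                 scale = as.numeric(scale), time_unit = "cycle"),
            class = "param_surv")
}

surv_families <- function() {
  c("exponential", "weibull", "loglogistic", "lognormal", "gompertz")
}

#' @export
print.param_surv <- function(x, ...) {
  cat(sprintf("Parametric survival curve: %s (per 21-day cycle)\n",
              x$family))
  cat(sprintf("  shape (gamma) = %g\n  scale (lambda) = %g\n",
              x$shape, x$scale))
  invisible(x)
}

#' Survival probability generic
#'
#' `surv_prob(x, t)` evaluates \eqn{S(t)} at times `t` (in cycles). Methods
#' exist for [param_surv()] curves, fitted curves, and proportional-hazards
#' transformed curves ([ph_surv()]).
#'
#' @param x A survival-curve object.
#' @param t Vector of non-negative times in cycles.
#' @param ... Passed to methods.
#' @return Numeric vector of survival fractions in \eqn{[0, 1]}.
#' @export
surv_prob <- function(x, t, ...) UseMethod("surv_prob")

#' @rdname surv_prob
#' @export
surv_prob.param_surv <- function(x, t, ...) {
  if (!is.numeric(t) || any(!is.finite(t) & !is.infinite(t)))
    stop("'t' must be numeric", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  g <- x$shape; l <- x$scale
  switch(x$family,
    exponential = exp(-l * t),
    weibull     = exp(-l * t^g),
    loglogistic = 1 / (1 + l * t^g),
    lognormal   = {
      s <- ifelse(t == 0, 1,
                  stats::plnorm(t, meanlog = -log(l) / g, sdlog = 1 / g,
                                lower.tail = FALSE))
      as.numeric(s)
    },
    gompertz    = if (abs(g) < 1e-12) exp(-l * t)
                  else exp(-l / g * (expm1(g * t)))
  )
}

#' Per-cycle transition (exit) probability
#'
#' The probability of leaving the curve's numerator state during cycle
#' `t`, \eqn{p(t) = 1 - S(t+1)/S(t)}. This is the discrete-cycle hazard
#' used to drive the state-transition trace; the cumulative product
#' \eqn{\prod_{u < t} (1 - p(u))} telescopes back to \eqn{S(t)} exactly.
#'
#' @param x A survival-curve object.
#' @param t Vector of non-negative integer cycle indices.
#' @return Vector of probabilities in \eqn{[0, 1]}. Where \eqn{S(t) = 0}
#'   the state is exhausted and 1 is returned with a warning.
#' @examples
#' trans_prob(param_surv("exponential", scale = 0.05), 0:3)  # constant
#' @export
trans_prob <- function(x, t) {
  if (any(t < 0) || any(t != floor(t)))
    stop("'t' must be non-negative integer cycle indices", call. = FALSE)
  s0 <- surv_prob(x, t)
  s1 <- surv_prob(x, t + 1)
  p <- ifelse(s0 > 0, 1 - s1 / s0, 1)
  if (any(s0 <= 0))
    warning("S(t) = 0 at some requested cycles; returning 1 (absorbing tail)")
  pmin(pmax(p, 0), 1)
}

#' @export
#' @param object,newdata,type `predict` method arguments: times in cycles and
#'   whether to return the survival fraction or the per-cycle exit
#'   probability.
#' @rdname surv_prob
predict.param_surv <- function(object, newdata,
                               type = c("survival", "transition"), ...) {
  type <- match.arg(type)
  if (type == "survival") surv_prob(object, newdata)
  else trans_prob(object, newdata)
}

#' Proportional-hazards transform of a survival curve
#'
#' Applies a hazard ratio to a baseline curve, \eqn{S_{HR}(t) = S(t)^{HR}},
#' used for biomarker-defined subgroup scenarios where only a subgroup
#' hazard ratio for event-free survival is reported.
#'
#' @param base A survival-curve object.
#' @param hr Hazard ratio (> 0).
#' @return An object of class `ph_surv` usable wherever a [param_surv()]
#'   curve is.
#' @export
ph_surv <- function(base, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0)
    stop("'hr' must be a single positive hazard ratio", call. = FALSE)
  structure(list(base = base, hr = as.numeric(hr)), class = "ph_surv")
}

#' @rdname surv_prob
#' @export
surv_prob.ph_surv <- function(x, t, ...) surv_prob(x$base, t)^x$hr

#' @export
print.ph_surv <- function(x, ...) {
  cat(sprintf("Proportional-hazards curve: HR = %g applied to\n", x$hr))
  print(x$base)
  invisible(x)
}

## ---- density / log-likelihood internals -------------------------------

surv_density <- function(x, t) {
  g <- x$shape; l <- x$scale
  switch(x$family,
    exponential = l * exp(-l * t),
    weibull     = l * g * t^(g - 1) * exp(-l * t^g),
    loglogistic = l * g * t^(g - 1) / (1 + l * t^g)^2,
    lognormal   = stats::dlnorm(t, meanlog = -log(l) / g, sdlog = 1 / g),
    gompertz    = if (abs(g) < 1e-12) l * exp(-l * t)
                  else l * exp(g * t) * exp(-l / g * expm1(g * t))
  )
}

ipd_loglik <- function(x, time, event) {
  f <- surv_density(x, time)
  s <- surv_prob(x, time)
  ll <- event * log(pmax(f, 1e-300)) + (1 - event) * log(pmax(s, 1e-300))
  sum(ll)
}

n_params <- function(family) if (family == "exponential") 1L else 2L

## parameter vector <-> param_surv on the optimizer scale:
## log(scale) always; log(shape) except gompertz (raw shape); exponential
## has no shape entry.
par_to_model <- function(family, par) {
  if (family == "exponential")
    param_surv(family, scale = exp(par[1]))
  else if (family == "gompertz")
    param_surv(family, shape = par[1], scale = exp(par[2]))
  else
    param_surv(family, shape = exp(par[1]), scale = exp(par[2]))
}

model_to_par <- function(x) {
  if (x$family == "exponential") log(x$scale)
  else if (x$family == "gompertz") c(x$shape, log(x$scale))
  else c(log(x$shape), log(x$scale))
}

## crude regression starts on a (time, survival) grid
curve_starts <- function(family, t, s) {
  keep <- t > 0 & s > 0 & s < 1
  t <- t[keep]; s <- s[keep]
  fallback <- param_surv(family, shape = if (family == "gompertz") 0.01 else 1,
                         scale = 0.01)
  if (length(t) < 2) return(fallback)
  lt <- log(t)
  est <- try(switch(family,
    exponential = {
      lam <- exp(stats::coef(stats::lm(log(-log(s)) ~ offset(lt)))[1])
      param_surv(family, scale = lam)
    },
    weibull = {
      co <- stats::coef(stats::lm(log(-log(s)) ~ lt))
      param_surv(family, shape = max(co[2], 1e-3), scale = exp(co[1]))
    },
    loglogistic = {
      co <- stats::coef(stats::lm(log(1 / s - 1) ~ lt))
      param_surv(family, shape = max(co[2], 1e-3), scale = exp(co[1]))
    },
    lognormal = {
      co <- stats::coef(stats::lm(stats::qnorm(1 - s) ~ lt))
      param_surv(family, shape = max(co[2], 1e-3), scale = exp(co[1]))
    },
    gompertz = {
      lam <- -log(s[length(s)]) / t[length(t)]
      param_surv(family, shape = 1e-3, scale = max(lam, 1e-8))
    }), silent = TRUE)
  if (inherits(est, "try-error") || !is.finite(est$scale)) fallback else est
}

## ---- fitting ----------------------------------------------------------

#' Fit a parametric survival family
#'
#' Fits one of the five supported families either to right-censored
#' individual patient data (maximum likelihood) or to digitized
#' Kaplan-Meier coordinates (weighted least squares on the survival
#' fraction, with weights proportional to the time spacing of the points
#' and a Gaussian pseudo-likelihood supplying AIC/BIC).
#'
#' `data` determines the mode: a data frame with columns `time` and
#' `event` (0/1) is treated as individual patient data; columns `time`
#' (or `time_cycles`) and `survival` as digitized curve coordinates.
#' Digitized coordinates that are not monotone non-increasing -- the
#' usual symptom of digitization noise -- are replaced by their
#' antitonic regression before fitting, with a warning.
#'
#' AIC and BIC follow the usual definitions \eqn{2k - 2\ell} and
#' \eqn{k \log n - 2\ell} with \eqn{k = 1} for the exponential and 2
#' otherwise; in curve mode \eqn{n} is the number of digitized points.
#'
#' @param data Data frame, see Details.
#' @param family Family name, as in [param_surv()].
#' @return An object of class `param_surv_fit`: a list with elements
#'   `model` (the fitted [param_surv()]), `loglik`, `AIC`, `BIC`,
#'   `n_obs`, `converged`, `method` (`"ipd"` or `"curve"`), `family`.
#' @examples
#' curve <- param_surv("loglogistic", 1.23, 0.00256)
#' pts <- generate_km_points(curve, times = 1:60, noise_sd = 0, seed = 1)
#' fit <- fit_param_surv(pts, "loglogistic")
#' coef_err <- c(fit$model$shape, fit$model$scale) / c(1.23, 0.00256) - 1
#' @seealso [fit_all_families()], [select_best()]
#' @export
fit_param_surv <- function(data, family) {
  family <- match.arg(family, surv_families())
  if (!is.data.frame(data)) stop("'data' must be a data frame", call. = FALSE)
  nm <- names(data)
  if ("time_cycles" %in% nm) names(data)[nm == "time_cycles"] <- "time"
  if (all(c("time", "event") %in% names(data)))
    fit_ipd(data, family)
  else if (all(c("time", "survival") %in% names(data)))
    fit_curve(data, family)
  else
    stop("'data' must have columns (time, event) or (time, survival)",
         call. = FALSE)
}

fit_ipd <- function(data, family) {
  time <- data$time; event <- data$event
  if (length(time) < 10)
    stop("individual-patient fitting needs at least 10 subjects",
         call. = FALSE)
  if (any(time < 0) || any(!event %in% c(0, 1)))
    stop("'time' must be non-negative and 'event' must be 0/1",
         call. = FALSE)
  if (sum(event) == 0)
    stop("degenerate input: no events observed", call. = FALSE)
  time <- pmax(time, 1e-8)  # guard log(0) in densities
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  start <- curve_starts(family, km$time, pmax(km$surv, 1e-6))
  negll <- function(par) {
    m <- try(par_to_model(family, par), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    v <- -ipd_loglik(m, time, event)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(model_to_par(start), negll, method = "BFGS",
                      control = list(maxit = 500))
  model <- par_to_model(family, opt$par)
  ll <- -opt$value
  k <- n_params(family)
  n <- length(time)
  new_fit(model, ll, k, n, converged = opt$convergence == 0,
          method = "ipd")
}

fit_curve <- function(data, family) {
  t <- data$time; s <- data$survival
  ord <- order(t); t <- t[ord]; s <- s[ord]
  if (length(t) < 3)
    stop("curve fitting needs at least 3 digitized points", call. = FALSE)
  if (anyDuplicated(t))
    stop("digitized times must be strictly increasing", call. = FALSE)
  if (any(s <= 0) || any(s > 1))
    stop("'survival' values must lie in (0, 1]", call. = FALSE)
  if (all(s == s[1]) && s[1] == 1)
    stop("degenerate input: survival constant at 1, no events to fit",
         call. = FALSE)
  if (is.unsorted(rev(s))) {
    warning("digitized survival not monotone non-increasing; ",
            "applying antitonic regression before fitting")
    s <- -stats::isoreg(t, -s)$yf
    s <- pmin(pmax(s, 1e-9), 1)
  }
  # weights proportional to the time interval each point represents
  gaps <- diff(c(0, t))
  w <- gaps / mean(gaps)
  start <- curve_starts(family, t, s)
  obj <- function(par) {
    m <- try(par_to_model(family, par), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    v <- sum(w * (s - surv_prob(m, t))^2)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(model_to_par(start), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  model <- par_to_model(family, opt$par)
  n <- length(t)
  sigma2 <- max(opt$value / n, 1e-20)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)  # Gaussian pseudo-likelihood
  k <- n_params(family)
  new_fit(model, ll, k, n, converged = opt$convergence == 0,
          method = "curve")
}

new_fit <- function(model, ll, k, n, converged, method) {
  structure(list(model = model, loglik = ll,
                 AIC = 2 * k - 2 * ll, BIC = k * log(n) - 2 * ll,
                 n_obs = n, df = k, converged = converged,
                 method = method, family = model$family),
            class = "param_surv_fit")
}

#' @export
print.param_surv_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s mode, n = %d)%s\n", x$family, x$method, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  shape = %g, scale = %g\n", x$model$shape, x$model$scale))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, BIC = %.3f\n",
              x$loglik, x$AIC, x$BIC))
  invisible(x)
}

#' @export
logLik.param_surv_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @rdname surv_prob
#' @export
surv_prob.param_surv_fit <- function(x, t, ...) surv_prob(x$model, t, ...)

#' Fit all five families to the same data
#'
#' @param data As in [fit_param_surv()].
#' @param families Character vector of families to fit.
#' @return Named list of `param_surv_fit` objects.
#' @export
fit_all_families <- function(data, families = surv_families()) {
  fits <- lapply(families, function(f)
    tryCatch(fit_param_surv(data, f), error = function(e) NULL))
  names(fits) <- families
  Filter(Negate(is.null), fits)
}

#' Select the best-fitting family
#'
#' Picks the fit with the lowest AIC; exact AIC ties are broken by the
#' lower BIC, then by fewer parameters. When AIC and BIC disagree on the
#' winner, the AIC winner is returned and the disagreement is recorded in
#' the `"selection_note"` attribute.
#'
#' @param fits Non-empty list of `param_surv_fit` objects over the same
#'   data.
#' @return The winning `param_surv_fit`.
#' @export
select_best <- function(fits) {
  if (!is.list(fits) || length(fits) == 0 ||
      !all(vapply(fits, inherits, TRUE, "param_surv_fit")))
    stop("'fits' must be a non-empty list of param_surv_fit objects",
         call. = FALSE)
  aic <- vapply(fits, `[[`, 0, "AIC")
  bic <- vapply(fits, `[[`, 0, "BIC")
  df <- vapply(fits, `[[`, 0, "df")
  ord <- order(aic, bic, df)
  best <- fits[[ord[1]]]
  if (aic[which.min(bic)] > min(aic)) {
    note <- sprintf("AIC selects %s but BIC selects %s; AIC winner kept",
                    best$family, fits[[which.min(bic)]]$family)
    attr(best, "selection_note") <- note
  }
  best
}
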