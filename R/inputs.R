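#' Reference model inputs (frozen fixture)
#'
#' Returns the complete set of model inputs for the base-case analysis:
#' the four log-logistic survival curves (event-free and overall
#' survival, both arms) on the 21-day-cycle timescale, all unit costs in
#' 2024 USD with their low/high ranges, grade >= 3 adverse-event risks
#' (incidence >= 3%) per arm, state utilities, and the simulation
#' settings (cycle length, 5% annual discount, 800-cycle lifetime
#' horizon, willingness-to-pay threshold of $37,710/QALY -- three times
#' China's 2023 per-capita GDP).
#'
#' The treatment schedule encodes the trial regimens: three cycles of
#' gemcitabine + cisplatin induction (with antiemetics and a PICC line
#' per cycle), radiotherapy (plus preparation) starting at cycle 4 with
#' three concurrent cisplatin administrations, and -- in the intervention
#' arm -- sintilimab for 12 cycles. Accrual windows (treatment-phase
#' length, surveillance frequency, progressive-disease cost bundle) were
#' calibrated once against the published base-case results and are
#' frozen here; see the package vignette.
#'
#' The granular subsequent-therapy component prices (chemotherapy,
#' immunotherapy, surgery, re-irradiation, targeted therapy, supportive
#' care) are carried under `reference_costs` for documentation; cost
#' accrual uses the per-arm aggregate subsequent-therapy lines, which is
#' what reproduces the published arm-level asymmetry.
#'
#' @return An object of class `cea_inputs` (a named list).
#' @examples
#' inp <- fixture_inputs()
#' inp$curves$sintilimab$efs$shape  # 0.7947444
#' @export
fixture_inputs <- function() {
  costs <- data.frame(
    name = c("sintilimab", "gemcitabine", "cisplatin",
             "concurrent_cisplatin", "antiemetics", "radiotherapy",
             "radiotherapy_prep", "subsequent_sint", "subsequent_std",
             "hospitalization", "laboratory", "followup_test", "picc"),
    base = c(303.85, 9.63, 11.61, 15.84, 65.55, 9633.84, 681.52,
             300.02, 540.6, 126.78, 74.85, 378.12, 134.15),
    low  = c(243.08, 7.7, 9.29, 12.38, 52.44, 7707.07, 545.22,
             240.02, 432.48, 101.43, 59.88, 302.5, 107.32),
    high = c(364.62, 11.56, 13.93, 18.57, 78.66, 11560.61, 817.83,
             360.02, 648.72, 152.14, 89.82, 453.74, 160.98),
    stringsAsFactors = FALSE)
  ae_costs <- data.frame(
    name = c("anaemia", "leukopenia", "nausea", "mucositis", "anorexia",
             "neutropenia", "dermatitis", "fatigue", "vomiting", "rash"),
    base = c(508.2, 406.37, 44.3, 19.94, 26, 406.37, 16.64, 110.3,
             44.3, 59.57),
    low  = c(406.56, 325.10, 35.44, 15.95, 20.8, 325.10, 13.31, 88.24,
             35.44, 47.66),
    high = c(609.84, 487.64, 53.16, 23.93, 31.2, 487.64, 19.97, 132.36,
             53.16, 71.48),
    stringsAsFactors = FALSE)
  ae_risks <- list(
    sintilimab = c(anaemia = 0.16, leukopenia = 0.25, nausea = 0.14,
                   mucositis = 0.33, anorexia = 0.10, neutropenia = 0.21,
                   dermatitis = 0.04, fatigue = 0.07, vomiting = 0.11),
    standard   = c(anaemia = 0.11, leukopenia = 0.22, nausea = 0.15,
                   mucositis = 0.30, anorexia = 0.07, neutropenia = 0.18,
                   dermatitis = 0.03, vomiting = 0.11))
  utilities <- data.frame(
    state = c("efs", "pd", "death"),
    base = c(0.76, 0.57, 0),
    low  = c(0.61, 0.46, 0),
    high = c(0.91, 0.68, 0),
    stringsAsFactors = FALSE)
  curves <- list(
    sintilimab = list(
      efs = param_surv("loglogistic", shape = 0.7947444, scale = 0.0081186),
      os  = param_surv("loglogistic", shape = 1.1514328, scale = 0.0011003)),
    standard = list(
      efs = param_surv("loglogistic", shape = 1.2297630, scale = 0.0025608),
      os  = param_surv("loglogistic", shape = 2.214,     scale = 0.00001507)))
  schedule <- list(
    induction_cycles = 3L,     # gemcitabine + cisplatin (+ antiemetics, PICC)
    concurrent_cycles = 3L,    # concurrent cisplatin administrations
    rt_start_cycle = 4L,       # radiotherapy one-off accrues here
    sintilimab_cycles = 12L,   # intervention arm only
    phase_cycles = c(sintilimab = 12L, standard = 7L),  # hospitalization+lab
    followup_every = 1L)       # follow-up test per N cycles in EFS after phase
  settings <- list(cycle_days = 21, discount = 0.05, horizon = 800L,
                   half_cycle = FALSE, mode = "partitioned",
                   wtp = 37710, body_surface_area = 1.72,
                   usd_per_cny = 1 / 7.1088)
  reference_costs <- data.frame(
    name = c("subsequent_chemotherapy", "subsequent_immunotherapy",
             "subsequent_surgery", "second_radiotherapy",
             "subsequent_targeted", "supportive_care"),
    base = c(35.29, 417.47, 4635.85, 5081.44, 558.32, 52.5),
    low  = c(28.23, 333.98, 3708.68, 4065.15, 446.66, 42),
    high = c(42.35, 500.96, 5563.02, 6097.73, 669.98, 63),
    stringsAsFactors = FALSE)
  x <- structure(list(curves = curves, costs = costs, ae_costs = ae_costs,
                      ae_risks = ae_risks, utilities = utilities,
                      schedule = schedule, settings = settings,
                      reference_costs = reference_costs),
                 class = "cea_inputs")
  validate_inputs(x)
  x
}

#' Validate model inputs
#'
#' Checks the structural invariants of a `cea_inputs` object: costs
#' non-negative with `low <= base <= high`, risks and utilities in
#' \eqn{[0, 1]}, a positive integer horizon and a discount rate in
#' \eqn{[0, 1)}. Errors name the offending field.
#'
#' @param x A `cea_inputs` object.
#' @return `x`, invisibly, if valid.
#' @export
validate_inputs <- function(x) {
  if (!inherits(x, "cea_inputs")) stop("not a 'cea_inputs' object",
                                       call. = FALSE)
  for (tab in c("costs", "ae_costs")) {
    d <- x[[tab]]
    bad <- d$base < 0 | d$low > d$base | d$base > d$high
    if (any(bad))
      stop(sprintf("invalid %s row(s): %s (need 0 <= low <= base <= high)",
                   tab, paste(d$name[bad], collapse = ", ")), call. = FALSE)
  }
  for (arm in names(x$ae_risks)) {
    r <- x$ae_risks[[arm]]
    if (any(r < 0 | r > 1))
      stop(sprintf("ae_risks.%s.%s out of [0, 1]", arm,
                   paste(names(r)[r < 0 | r > 1], collapse = ", ")),
           call. = FALSE)
    unknown <- setdiff(names(r), x$ae_costs$name)
    if (length(unknown))
      stop(sprintf("ae_risks.%s names not in ae_costs: %s", arm,
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  u <- x$utilities
  if (any(u$base < 0 | u$base > 1 | u$low > u$base | u$base > u$high))
    stop("utilities must satisfy 0 <= low <= base <= high <= 1",
         call. = FALSE)
  s <- x$settings
  if (s$horizon < 1 || s$horizon != floor(s$horizon))
    stop("settings.horizon must be a positive integer", call. = FALSE)
  if (s$discount < 0 || s$discount >= 1)
    stop("settings.discount must be in [0, 1)", call. = FALSE)
  if (s$wtp <= 0) stop("settings.wtp must be positive", call. = FALSE)
  invisible(x)
}

## ---- parameter wiring for sensitivity analyses -------------------------

#' Sensitivity-analysis parameter table
#'
#' Flattens the wired model parameters into one row per parameter with
#' its base value, range and sampling distribution: every ranged unit
#' cost and adverse-event management cost (Gamma), every arm-specific
#' adverse-event risk (Beta, range +/-20% of the point estimate since no
#' ranges are published), and the two state utilities (Beta). Survival
#' curve parameters are not listed; they are held fixed in the
#' probabilistic analysis by default.
#'
#' @param inputs A `cea_inputs` object.
#' @return Data frame with columns `name`, `base`, `low`, `high`,
#'   `dist` (`"gamma"`/`"beta"`), `role`.
#' @export
param_table <- function(inputs) {
  validate_inputs(inputs)
  ct <- inputs$costs
  rows <- data.frame(name = paste0("cost.", ct$name), base = ct$base,
                     low = ct$low, high = ct$high, dist = "gamma",
                     role = "cost", stringsAsFactors = FALSE)
  used_ae <- unique(unlist(lapply(inputs$ae_risks, names)))
  ac <- inputs$ae_costs[inputs$ae_costs$name %in% used_ae, ]
  rows <- rbind(rows, data.frame(
    name = paste0("ae_cost.", ac$name), base = ac$base, low = ac$low,
    high = ac$high, dist = "gamma", role = "cost",
    stringsAsFactors = FALSE))
  for (arm in names(inputs$ae_risks)) {
    r <- inputs$ae_risks[[arm]]
    rows <- rbind(rows, data.frame(
      name = paste0("risk.", arm, ".", names(r)), base = unname(r),
      low = unname(r) * 0.8, high = pmin(unname(r) * 1.2, 1),
      dist = "beta", role = "probability", stringsAsFactors = FALSE))
  }
  u <- inputs$utilities[inputs$utilities$state != "death", ]
  rows <- rbind(rows, data.frame(
    name = paste0("utility.", u$state), base = u$base, low = u$low,
    high = u$high, dist = "beta", role = "utility",
    stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' Set one wired parameter
#'
#' Addresses a parameter by the dotted name used in [param_table()]
#' (for example `"cost.sintilimab"`, `"ae_cost.leukopenia"`,
#' `"risk.sintilimab.neutropenia"`, `"utility.efs"`) and returns the
#' modified inputs. Unknown names raise an error, so a sensitivity
#' analysis can never silently vary a parameter that is not wired into
#' the model.
#'
#' @param inputs A `cea_inputs` object.
#' @param name Dotted parameter name.
#' @param value New numeric value.
#' @return The modified `cea_inputs` object.
#' @export
set_param <- function(inputs, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  kind <- parts[1]
  set_row <- function(d, nm) {
    i <- which(d$name == nm)
    d$base[i] <- value
    # sampled values may land outside the declared range; keep the
    # low <= base <= high invariant intact
    d$low[i] <- min(d$low[i], value)
    d$high[i] <- max(d$high[i], value)
    d
  }
  if (kind == "cost" && length(parts) == 2 &&
      parts[2] %in% inputs$costs$name) {
    inputs$costs <- set_row(inputs$costs, parts[2])
  } else if (kind == "ae_cost" && length(parts) == 2 &&
             parts[2] %in% inputs$ae_costs$name) {
    inputs$ae_costs <- set_row(inputs$ae_costs, parts[2])
  } else if (kind == "risk" && length(parts) == 3 &&
             parts[2] %in% names(inputs$ae_risks) &&
             parts[3] %in% names(inputs$ae_risks[[parts[2]]])) {
    inputs$ae_risks[[parts[2]]][parts[3]] <- value
  } else if (kind == "utility" && length(parts) == 2 &&
             parts[2] %in% inputs$utilities$state) {
    i <- which(inputs$utilities$state == parts[2])
    inputs$utilities$base[i] <- value
    inputs$utilities$low[i] <- min(inputs$utilities$low[i], value)
    inputs$utilities$high[i] <- max(inputs$utilities$high[i], value)
  } else {
    stop(sprintf("parameter '%s' is not wired into the model", name),
         call. = FALSE)
  }
  inputs
}

## ---- fixture serialization --------------------------------------------

curve_to_list <- function(x)
  list(family = x$family, shape = x$shape, scale = x$scale)

#' Write / read the model inputs as a YAML fixture
#'
#' Serializes a `cea_inputs` object to a human-readable YAML file and
#' back. Numbers are written with 17 significant digits so the
#' round-trip is value-exact.
#'
#' @param inputs A `cea_inputs` object.
#' @param path File path.
#' @return `write_fixture` returns `path` invisibly; `read_fixture`
#'   returns the reconstructed `cea_inputs` object.
#' @export
write_fixture <- function(inputs, path) {
  validate_inputs(inputs)
  ser <- list(
    curves = lapply(inputs$curves, function(arm)
      lapply(arm, curve_to_list)),
    costs = inputs$costs, ae_costs = inputs$ae_costs,
    ae_risks = lapply(inputs$ae_risks, as.list),
    utilities = inputs$utilities,
    schedule = utils::modifyList(inputs$schedule, list(
      phase_cycles = as.list(inputs$schedule$phase_cycles))),
    settings = inputs$settings, reference_costs = inputs$reference_costs)
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  ser <- yaml::read_yaml(path)
  as_df <- function(l) as.data.frame(l, stringsAsFactors = FALSE)
  x <- structure(list(
    curves = lapply(ser$curves, function(arm)
      lapply(arm, function(cv)
        param_surv(cv$family, shape = cv$shape, scale = cv$scale))),
    costs = as_df(ser$costs), ae_costs = as_df(ser$ae_costs),
    ae_risks = lapply(ser$ae_risks, unlist),
    utilities = as_df(ser$utilities),
    schedule = utils::modifyList(ser$schedule, list(
      induction_cycles = as.integer(ser$schedule$induction_cycles),
      concurrent_cycles = as.integer(ser$schedule$concurrent_cycles),
      rt_start_cycle = as.integer(ser$schedule$rt_start_cycle),
      sintilimab_cycles = as.integer(ser$schedule$sintilimab_cycles),
      phase_cycles = vapply(ser$schedule$phase_cycles, as.integer, 1L),
      followup_every = as.integer(ser$schedule$followup_every))),
    settings = utils::modifyList(ser$settings, list(
      horizon = as.integer(ser$settings$horizon))),
    reference_costs = as_df(ser$reference_costs)),
    class = "cea_inputs")
  validate_inputs(x)
  x
}
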