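#' Expected adverse-event management cost
#'
#' Grade >= 3 adverse events with incidence >= 3% are costed once per
#' patient at treatment start as \eqn{\sum_i risk_i \times cost_i}.
#'
#' @param risks Named vector of per-patient event risks.
#' @param costs Named vector of per-event management costs in USD; must
#'   cover every name in `risks`.
#' @return Expected cost in USD (single number).
#' @examples
#' inp <- fixture_inputs()
#' costs <- setNames(inp$ae_costs$base, inp$ae_costs$name)
#' expected_ae_cost(inp$ae_risks$sintilimab, costs)  # 296.88
#' @export
expected_ae_cost <- function(risks, costs) {
  if (is.null(names(risks)) || is.null(names(costs)))
    stop("'risks' and 'costs' must be named vectors", call. = FALSE)
  missing <- setdiff(names(risks), names(costs))
  if (length(missing))
    stop("no management cost for adverse event(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(risks < 0 | risks > 1))
    stop("risks must lie in [0, 1]", call. = FALSE)
  sum(risks * costs[names(risks)])
}

#' Per-cycle cost schedule for one strategy
#'
#' Expands the treatment schedule of one arm into (i) a vector of
#' event-free-state costs per cycle over the horizon, (ii) the constant
#' per-cycle cost of the progressive-disease state, and (iii) the
#' one-off adverse-event cost applied at treatment start. Cycle windows:
#' induction chemotherapy (gemcitabine, cisplatin, antiemetics, one PICC
#' per course) over the first `induction_cycles` cycles; radiotherapy
#' plus preparation as a one-off at `rt_start_cycle`, with
#' `concurrent_cycles` concurrent cisplatin administrations (plus
#' antiemetics) from that cycle; sintilimab over the first
#' `sintilimab_cycles` cycles in the intervention arm; hospitalization
#' and laboratory costs per cycle during the arm's active treatment
#' phase; thereafter a follow-up test every `followup_every` cycles
#' while event-free. The progressive-disease state accrues the arm's
#' aggregate subsequent-therapy cost plus hospitalization and
#' laboratory per cycle.
#'
#' @param inputs A `cea_inputs` object.
#' @param arm `"sintilimab"` or `"standard"`.
#' @param horizon Number of cycles.
#' @return List with `efs_cycle` (numeric vector of length `horizon`),
#'   `pd_cycle` (single number), `ae_oneoff` (single number),
#'   `arm`.
#' @export
treatment_schedule <- function(inputs, arm = c("sintilimab", "standard"),
                               horizon = inputs$settings$horizon) {
  arm <- match.arg(arm)
  validate_inputs(inputs)
  cost <- function(nm) inputs$costs$base[match(nm, inputs$costs$name)]
  sch <- inputs$schedule
  H <- as.integer(horizon)
  efs <- numeric(H)
  ind <- seq_len(min(sch$induction_cycles, H))
  efs[ind] <- efs[ind] + cost("gemcitabine") + cost("cisplatin") +
    cost("antiemetics") + cost("picc")
  conc <- sch$rt_start_cycle + seq_len(sch$concurrent_cycles) - 1L
  conc <- conc[conc <= H]
  efs[conc] <- efs[conc] + cost("concurrent_cisplatin") + cost("antiemetics")
  if (sch$rt_start_cycle <= H)
    efs[sch$rt_start_cycle] <- efs[sch$rt_start_cycle] +
      cost("radiotherapy") + cost("radiotherapy_prep")
  if (arm == "sintilimab") {
    sc <- seq_len(min(sch$sintilimab_cycles, H))
    efs[sc] <- efs[sc] + cost("sintilimab")
  }
  phase <- min(sch$phase_cycles[[arm]], H)
  if (phase >= 1)
    efs[seq_len(phase)] <- efs[seq_len(phase)] +
      cost("hospitalization") + cost("laboratory")
  if (phase < H) {
    post <- (phase + 1):H
    efs[post] <- efs[post] + cost("followup_test") / sch$followup_every
  }
  subs <- if (arm == "sintilimab") "subsequent_sint" else "subsequent_std"
  pd_cycle <- cost(subs) + cost("hospitalization") + cost("laboratory")
  ae_costs <- stats::setNames(inputs$ae_costs$base, inputs$ae_costs$name)
  ae_oneoff <- expected_ae_cost(inputs$ae_risks[[arm]], ae_costs)
  list(efs_cycle = efs, pd_cycle = pd_cycle, ae_oneoff = ae_oneoff,
       arm = arm)
}

#' Accrue discounted costs over a trace
#'
#' Each per-cycle cost is weighted by the occupancy of the state in
#' which it accrues and by the trace's discount weight; the one-off
#' adverse-event cost is applied at cycle 0. The event-free /
#' progressive-disease decomposition is retained.
#'
#' @param trace A [run_trace()] result.
#' @param schedule A [treatment_schedule()] result over the same horizon.
#' @return List with `total`, `efs`, `pd` (discounted USD).
#' @export
accrue_costs <- function(trace, schedule) {
  stopifnot(inherits(trace, "markov_trace"))
  H <- nrow(trace)
  if (length(schedule$efs_cycle) != H)
    stop("schedule horizon does not match trace horizon", call. = FALSE)
  stopifnot(all(trace$occ_efs >= 0), all(trace$occ_pd >= 0))
  efs <- sum(schedule$efs_cycle * trace$occ_efs * trace$discount) +
    schedule$ae_oneoff
  pd <- schedule$pd_cycle * sum(trace$occ_pd * trace$discount)
  list(total = efs + pd, efs = efs, pd = pd)
}

#' Accrue discounted life-years and QALYs over a trace
#'
#' QALYs are state life-years weighted by the state utility:
#' \eqn{QALY_s = LY_s \times u_s}.
#'
#' @param trace A [run_trace()] result.
#' @param utilities Named vector or list with elements `efs` and `pd`
#'   in \eqn{[0, 1]} (death is 0).
#' @return List with `ly`, `qaly` and per-state components `ly_efs`,
#'   `ly_pd`, `qaly_efs`, `qaly_pd`.
#' @export
accrue_qalys <- function(trace, utilities) {
  u_e <- utilities[["efs"]]; u_p <- utilities[["pd"]]
  if (any(c(u_e, u_p) < 0) || any(c(u_e, u_p) > 1))
    stop("utilities must lie in [0, 1]", call. = FALSE)
  ly_e <- state_years(trace, "efs")
  ly_p <- state_years(trace, "pd")
  list(ly = ly_e + ly_p, qaly = ly_e * u_e + ly_p * u_p,
       ly_efs = ly_e, ly_pd = ly_p,
       qaly_efs = ly_e * u_e, qaly_pd = ly_p * u_p)
}

#' Evaluate one strategy
#'
#' Runs the cohort trace for one arm and accrues its discounted costs,
#' life-years and QALYs.
#'
#' @param inputs A `cea_inputs` object.
#' @param arm `"sintilimab"` or `"standard"`.
#' @param trace Optionally a precomputed [run_trace()] for this arm
#'   (used by the probabilistic analysis, where the curves are fixed).
#' @return A `strategy_result`: list with `strategy`, `cost`, `ly`,
#'   `qaly` and the per-state decomposition `by_state`.
#' @export
evaluate_strategy <- function(inputs, arm = c("sintilimab", "standard"),
                              trace = NULL) {
  arm <- match.arg(arm)
  if (is.null(trace)) trace <- arm_trace(inputs, arm)
  sch <- treatment_schedule(inputs, arm, horizon = nrow(trace))
  cost <- accrue_costs(trace, sch)
  u <- stats::setNames(inputs$utilities$base, inputs$utilities$state)
  eff <- accrue_qalys(trace, u)
  structure(list(
    strategy = arm, cost = cost$total, ly = eff$ly, qaly = eff$qaly,
    by_state = data.frame(
      state = c("EFS", "PD"),
      cost = c(cost$efs, cost$pd),
      ly = c(eff$ly_efs, eff$ly_pd),
      qaly = c(eff$qaly_efs, eff$qaly_pd))),
    class = "strategy_result")
}

arm_trace <- function(inputs, arm) {
  s <- inputs$settings
  cv <- inputs$curves[[arm]]
  run_trace(markov_spec(cv$efs, cv$os, horizon = s$horizon,
                        discount = s$discount, cycle_days = s$cycle_days,
                        half_cycle = s$half_cycle, mode = s$mode),
            label = arm)
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy: %s\n", x$strategy))
  cat(sprintf("  cost  $%.2f\n  LY    %.4f\n  QALY  %.4f\n",
              x$cost, x$ly, x$qaly))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental discounted cost, life-years and QALYs of strategy `a`
#' over comparator `b`, with cost per life-year and per QALY. When one
#' strategy is cheaper and at least as effective the ratio is not
#' meaningful and a dominance flag is set instead.
#'
#' @param a,b `strategy_result` objects (`b` is the comparator).
#' @return An `icer_result`: list with `d_cost`, `d_ly`, `d_qaly`,
#'   `icer_ly`, `icer_qaly`, `dominance` (`"none"`, `"dominant"`,
#'   `"dominated"` or `"equivalent"`).
#' @export
icer <- function(a, b) {
  stopifnot(inherits(a, "strategy_result"), inherits(b, "strategy_result"))
  d_cost <- a$cost - b$cost
  d_ly <- a$ly - b$ly
  d_qaly <- a$qaly - b$qaly
  dominance <- if (d_cost == 0 && d_qaly == 0) "equivalent"
    else if (d_cost <= 0 && d_qaly >= 0) "dominant"
    else if (d_cost >= 0 && d_qaly <= 0) "dominated"
    else "none"
  ratio <- function(num, den) if (dominance == "none" && den != 0)
    num / den else NA_real_
  structure(list(d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
                 icer_ly = ratio(d_cost, d_ly),
                 icer_qaly = ratio(d_cost, d_qaly),
                 dominance = dominance,
                 strategies = c(a$strategy, b$strategy)),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$strategies[1], x$strategies[2]))
  cat(sprintf("  dCost  $%.2f\n  dLY    %.4f\n  dQALY  %.4f\n",
              x$d_cost, x$d_ly, x$d_qaly))
  if (x$dominance == "none")
    cat(sprintf("  ICER   $%.2f/LY, $%.2f/QALY\n", x$icer_ly, x$icer_qaly))
  else cat(sprintf("  dominance: %s\n", x$dominance))
  invisible(x)
}
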