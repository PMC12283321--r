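#' Fit the cost-effectiveness model
#'
#' The central constructor: runs the three-state Markov cohort model for
#' both strategies (sintilimab + chemoradiotherapy versus
#' chemoradiotherapy alone), accrues discounted costs, life-years and
#' QALYs, and computes the incremental cost-effectiveness ratios.
#'
#' @param inputs Model inputs, by default the frozen reference fixture
#'   ([fixture_inputs()]).
#' @param horizon,discount,half_cycle,mode Optional overrides of the
#'   corresponding `inputs$settings` entries.
#' @param wtp Willingness-to-pay threshold in USD/QALY used by the
#'   reporting methods (default from the settings: $37,710, three times
#'   China's 2023 per-capita GDP).
#' @return An object of class `cea`: list with `strategies` (named list
#'   of `strategy_result`), `icer` (`icer_result`, intervention vs
#'   comparator), `traces`, `inputs`, `wtp`.
#' @examples
#' \donttest{
#' fit <- cea_model()
#' summary(fit)
#' }
#' @seealso [run_psa()], [one_way_dsa()], [subgroup_scenario()]
#' @export
cea_model <- function(inputs = fixture_inputs(), horizon = NULL,
                      discount = NULL, half_cycle = NULL, mode = NULL,
                      wtp = NULL) {
  validate_inputs(inputs)
  ov <- list(horizon = horizon, discount = discount,
             half_cycle = half_cycle, mode = mode, wtp = wtp)
  inputs$settings <- utils::modifyList(inputs$settings,
                                       Filter(Negate(is.null), ov))
  validate_inputs(inputs)
  arms <- names(inputs$curves)
  traces <- lapply(arms, function(a) arm_trace(inputs, a))
  names(traces) <- arms
  strategies <- lapply(arms, function(a)
    evaluate_strategy(inputs, a, trace = traces[[a]]))
  names(strategies) <- arms
  structure(list(strategies = strategies,
                 icer = icer(strategies$sintilimab, strategies$standard),
                 traces = traces, inputs = inputs,
                 wtp = inputs$settings$wtp),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat("Markov cohort cost-effectiveness model",
      "(sintilimab + chemoradiotherapy vs chemoradiotherapy)\n")
  s <- x$inputs$settings
  cat(sprintf("  %d cycles of %g days (%.1f years), %g%% annual discount, %s occupancy\n",
              s$horizon, s$cycle_days, s$horizon * s$cycle_days / 365.25,
              100 * s$discount, s$mode))
  print(summary(x), row.names = FALSE)
  ic <- x$icer
  if (ic$dominance == "none") {
    cat(sprintf("\nICER: $%.2f per LY, $%.2f per QALY (WTP $%s/QALY)\n",
                ic$icer_ly, ic$icer_qaly, format(x$wtp, big.mark = ",")))
    nmb <- x$wtp * ic$d_qaly - ic$d_cost
    cat(sprintf("Incremental NMB at WTP: $%.2f (%s)\n", nmb,
                if (nmb > 0) "cost-effective" else "not cost-effective"))
  } else {
    cat(sprintf("\nDominance: %s\n", ic$dominance))
  }
  invisible(x)
}

#' Baseline results table
#'
#' One row per strategy and per health state, mirroring the layout of a
#' base-case results table: total discounted cost, life-years and QALYs
#' with the EFS/PD decomposition, plus the incremental ratios on the
#' strategy rows.
#'
#' @param object A `cea` object.
#' @param ... Unused.
#' @return A data frame.
#' @export
summary.cea <- function(object, ...) {
  rows <- list()
  ic <- object$icer
  for (arm in names(object$strategies)) {
    st <- object$strategies[[arm]]
    is_int <- arm == ic$strategies[1]
    rows[[length(rows) + 1]] <- data.frame(
      strategy = arm, state = "total", cost = st$cost, ly = st$ly,
      qaly = st$qaly,
      icer_ly = if (is_int) ic$icer_ly else NA_real_,
      icer_qaly = if (is_int) ic$icer_qaly else NA_real_)
    for (i in seq_len(nrow(st$by_state)))
      rows[[length(rows) + 1]] <- data.frame(
        strategy = arm, state = st$by_state$state[i],
        cost = st$by_state$cost[i], ly = st$by_state$ly[i],
        qaly = st$by_state$qaly[i],
        icer_ly = NA_real_, icer_qaly = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot state occupancy traces
#'
#' Draws the discounted-model state occupancies (EFS, PD, death) over
#' time for both strategies.
#'
#' @param x A `cea` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cea <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$traces)))
  on.exit(graphics::par(old))
  for (arm in names(x$traces)) {
    tr <- x$traces[[arm]]
    graphics::matplot(tr$t_years,
                      cbind(tr$occ_efs, tr$occ_pd, tr$occ_death),
                      type = "l", lty = 1, col = c("forestgreen",
                                                   "orange", "grey30"),
                      xlab = "years", ylab = "state occupancy",
                      main = arm, ylim = c(0, 1), ...)
    graphics::legend("right", c("EFS", "PD", "death"), lty = 1,
                     col = c("forestgreen", "orange", "grey30"),
                     bty = "n")
  }
  invisible(x)
}
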