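#' Run the base-case analysis and write its reports
#'
#' Fits the model on the given inputs and, if `out_dir` is supplied,
#' writes `basecase.csv` (the baseline results table), `basecase.json`
#' (machine-readable strategy results and ICERs) and `manifest.json`
#' (configuration hash, settings and package version, so every results
#' file can be traced to the inputs that produced it).
#'
#' @param inputs A `cea_inputs` object.
#' @param out_dir Output directory (created if needed), or `NULL` to
#'   skip writing.
#' @param ... Setting overrides passed to [cea_model()].
#' @return The fitted `cea` object, invisibly when writing.
#' @export
run_base_case <- function(inputs = fixture_inputs(), out_dir = NULL, ...) {
  fit <- cea_model(inputs, ...)
  if (is.null(out_dir)) return(fit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- summary(fit)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, 2)  # report precision; model is full
  utils::write.csv(tab, file.path(out_dir, "basecase.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    strategies = lapply(fit$strategies, function(s)
      list(cost = s$cost, ly = s$ly, qaly = s$qaly,
           by_state = s$by_state)),
    icer = fit$icer[c("d_cost", "d_ly", "d_qaly", "icer_ly",
                      "icer_qaly", "dominance")]),
    file.path(out_dir, "basecase.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(fit$inputs, out_dir, stage = "base_case")
  invisible(fit)
}

#' Run the full analysis suite
#'
#' Base case, one-way sensitivity analysis (`tornado.csv`),
#' probabilistic sensitivity analysis (`psa_draws.csv`), acceptability
#' curve (`ceac.csv`) and, when subgroup hazard ratios are supplied,
#' subgroup scenarios (`subgroups.csv`). Each stage writes
#' independently; a failing stage is reported by name and does not
#' abort the others. All randomness flows from `seed`.
#'
#' @param inputs A `cea_inputs` object.
#' @param out_dir Output directory.
#' @param seed Integer seed for the probabilistic analysis.
#' @param n_iter Probabilistic draws (default 1000).
#' @param subgroup_hrs Optional named vector of subgroup EFS hazard
#'   ratios; omitted => the subgroup stage is skipped with a notice.
#' @return Named list with the objects produced per stage, invisibly.
#' @export
run_full <- function(inputs = fixture_inputs(), out_dir, seed = 1,
                     n_iter = 1000, subgroup_hrs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
  }
  out$base <- stage("base_case", run_base_case(inputs, out_dir))
  out$tornado <- stage("dsa", {
    tor <- one_way_dsa(inputs)
    utils::write.csv(as.data.frame(tor),
                     file.path(out_dir, "tornado.csv"), row.names = FALSE)
    tor
  })
  out$psa <- stage("psa", {
    psa <- run_psa(inputs, n_iter = n_iter, seed = seed)
    utils::write.csv(psa$draws, file.path(out_dir, "psa_draws.csv"),
                     row.names = FALSE)
    psa
  })
  out$ceac <- stage("ceac", {
    cc <- ceac(out$psa)
    utils::write.csv(as.data.frame(cc), file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
    cc
  })
  if (is.null(subgroup_hrs)) {
    message("no subgroup hazard ratios supplied; subgroup stage skipped")
  } else {
    out$subgroups <- stage("subgroups", {
      rows <- lapply(names(subgroup_hrs), function(nm) {
        fit <- subgroup_scenario(inputs, subgroup_hrs[[nm]], label = nm)
        data.frame(subgroup = nm, hr_efs = subgroup_hrs[[nm]],
                   d_cost = fit$icer$d_cost, d_qaly = fit$icer$d_qaly,
                   icer_qaly = fit$icer$icer_qaly)
      })
      sg <- do.call(rbind, rows)
      utils::write.csv(sg, file.path(out_dir, "subgroups.csv"),
                       row.names = FALSE)
      sg
    })
  }
  write_manifest(inputs, out_dir, stage = "full", seed = seed,
                 n_iter = n_iter)
  invisible(out)
}

write_manifest <- function(inputs, out_dir, stage, seed = NULL,
                           n_iter = NULL) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_fixture(inputs, tmp)
  jsonlite::write_json(list(
    stage = stage,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed, n_iter = n_iter,
    settings = inputs$settings,
    package = "npccea",
    version = as.character(utils::packageVersion("npccea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(NULL)
}
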