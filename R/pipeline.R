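## End-to-end orchestration: simulate or ingest an item panel, standardize,
## fit the longitudinal factor model, extract Bartlett scores, bin by age,
## fit the trajectory model set, and write comparison tables plus a run
## manifest.

#' Pipeline configuration
#'
#' @param input `NULL` for a synthetic run (the generator configs are
#'   used) or a path to a long-format item panel CSV
#' @param growth,measurement,design generator configuration for synthetic
#'   runs
#' @param ref_wave reference wave for item standardization
#' @param age_range modeled age window at first assessment and for bins
#' @param knot knot bin for spline candidates retained in the final fits
#' @param out_dir artifact directory
#' @param seed integer seed for the synthetic stage
#' @param alpha significance criterion for flagging estimates
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(input = NULL, growth = growth_config(),
                            measurement = measurement_config(),
                            design = panel_design(), ref_wave = 2010,
                            age_range = c(50, 85), knot = "70/71",
                            out_dir = "bivtraj-out", seed = 1L,
                            alpha = 0.005) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  design$seed <- as.integer(seed)
  structure(list(input = input, growth = growth, measurement = measurement,
                 design = design, ref_wave = ref_wave,
                 age_range = age_range, knot = knot, out_dir = out_dir,
                 seed = as.integer(seed), alpha = alpha),
            class = "pipeline_config")
}

#' Apply inclusion screening to an item panel
#'
#' Retains persons aged within the configured range at first assessment.
#' Optional boolean screening columns (`dementia`, `depression`) are
#' honored when present (persons flagged `TRUE` are removed); no attempt
#' is made to derive them.
#'
#' @param panel long item panel with `id`, `age_years`
#' @param config a [pipeline_config()]
#' @return the screened panel (attributes `n_removed_age`,
#'   `n_removed_flags`)
#' @export
screen_input <- function(panel, config = pipeline_config()) {
  if (!"age_years" %in% names(panel)) stop("panel lacks an age_years column")
  if (!"id" %in% names(panel)) stop("panel lacks an id column")
  first_age <- tapply(panel$age_years, panel$id, min)
  ok_ids <- names(first_age)[first_age >= config$age_range[1] &
                               first_age <= config$age_range[2]]
  keep <- as.character(panel$id) %in% ok_ids
  n_age <- length(unique(panel$id)) - length(ok_ids)
  panel <- panel[keep, , drop = FALSE]
  n_flag <- 0L
  for (fl in intersect(c("dementia", "depression"), names(panel))) {
    bad_ids <- unique(panel$id[panel[[fl]] %in% TRUE])
    n_flag <- n_flag + length(bad_ids)
    panel <- panel[!panel$id %in% bad_ids, , drop = FALSE]
    panel[[fl]] <- NULL
  }
  if (!nrow(panel))
    stop("screening removed every row; no analyzable input remains")
  attr(panel, "n_removed_age") <- n_age
  attr(panel, "n_removed_flags") <- n_flag
  panel
}

#' Run the two-stage analysis pipeline
#'
#' Simulates (or reads) an item panel, screens it, standardizes items to
#' the reference wave, fits the strong-invariance bivariate longitudinal
#' factor model, extracts Bartlett scores, restructures them into age
#' bins rescaled at the 70/71 bin, fits the univariate model sets and the
#' bivariate candidate models, and writes all artifacts plus a JSON run
#' manifest (seed, case counts, convergence ledger).  Any stage failure
#' aborts with the stage name; artifacts written so far are kept.
#'
#' @param config a [pipeline_config()]
#' @param verbose print per-stage progress
#' @return invisibly, a list with the main in-memory results
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[bivtraj] ", ...)
  stage <- "input"
  res <- list(config = config)
  manifest <- list(seed = config$seed, alpha = config$alpha,
                   package_version = as.character(utils::packageVersion("bivtraj")))
  tryCatch({
    if (is.null(config$input)) {
      say("simulating item panel (n = ", config$design$n_persons, ")")
      sim <- generate_item_panel(config$growth, config$measurement,
                                 config$design)
      panel <- sim$panel[sim$panel$observed, , drop = FALSE]
      utils::write.csv(sim$truth, file.path(out, "truth.csv"),
                       row.names = FALSE)
      dump_config(config$growth, config$measurement, config$design,
                  file.path(out, "generator_config.yaml"))
    } else {
      say("reading item panel from ", config$input)
      panel <- utils::read.csv(config$input)
    }
    stage <- "screening"
    panel <- screen_input(panel, config)
    manifest$n_cases_input <- length(unique(panel$id))
    manifest$n_removed_age <- attr(panel, "n_removed_age")

    stage <- "standardization"
    std <- standardize_items(panel, ref_wave = config$ref_wave)
    utils::write.csv(std$panel, file.path(out, "standardized_items.csv"),
                     row.names = FALSE)
    jsonlite::write_json(std$record, file.path(out, "standardization.json"),
                         digits = NA, dataframe = "rows")

    stage <- "longitudinal factor analysis"
    say("fitting strong-invariance bivariate factor model")
    items <- setdiff(names(std$panel), panel_meta_cols)
    cog_items <- intersect(config$measurement$item[
      config$measurement$process == "COG"], items)
    fnc_items <- intersect(config$measurement$item[
      config$measurement$process == "FNC"], items)
    lfa <- fit_bivariate_lfa(std$panel, cog_items = cog_items,
                             fnc_items = fnc_items, se = "none", h1 = TRUE)
    fit_to_json(lfa, file.path(out, "lfa_fit.json"))
    writeLines(utils::capture.output(print(lfa), print(lfa$std_loadings)),
               file.path(out, "lfa_fit.txt"))
    manifest$lfa <- list(converged = lfa$converged, n_cases = lfa$n_cases,
                         chi2 = lfa$chi2, df = lfa$df)

    stage <- "factor scores"
    scores <- bartlett_scores(lfa, std$panel)
    utils::write.csv(scores, file.path(out, "factor_scores.csv"),
                     row.names = FALSE)

    stage <- "age binning"
    abm <- assign_age_bins(scores, age_range = config$age_range)
    abm <- rescale_at_bin(abm, "70/71")
    utils::write.csv(data.frame(id = abm$ids, abm$data,
                                check.names = FALSE),
                     file.path(out, "age_bin_matrix.csv"), row.names = FALSE)
    manifest$bins <- list(n_persons = length(abm$ids),
                          dropped_low = abm$n_dropped_low,
                          dropped_high = abm$n_dropped_high,
                          averaged = abm$n_averaged)

    stage <- "univariate trajectories"
    uni <- list()
    for (pr in abm$processes) {
      say("fitting univariate trajectory models for ", toupper(pr))
      uni[[pr]] <- fit_univariate_trajectories(abm, pr, h1 = TRUE)
      cmp <- compare_models(uni[[pr]])
      utils::write.csv(cmp, file.path(out, paste0("univariate_", pr,
                                                  "_comparison.csv")),
                       row.names = FALSE)
      writeLines(utils::capture.output(print(cmp)),
                 file.path(out, paste0("univariate_", pr, "_comparison.txt")))
    }

    stage <- "bivariate trajectory"
    biv <- list()
    if (length(abm$processes) == 2) {
      say("fitting bivariate trajectory candidates")
      cand <- list(
        "linear+linear" = trajectory_spec(cog = "linear", fnc = "linear"),
        "spline+linear" = trajectory_spec(cog = "spline", fnc = "linear",
                                          knot = config$knot))
      Yb <- trajectory_fit_data(abm, cand[[1]])
      h1b <- local({
        d <- missing_pattern_data(Yb)
        list(sat = saturated_loglik(d), base = baseline_loglik(d))
      })
      biv <- lapply(cand, function(sp)
        fit_trajectory_model(abm, sp, se = "none", h1 = h1b))
      cmpb <- compare_models(biv)
      utils::write.csv(cmpb, file.path(out, "bivariate_comparison.csv"),
                       row.names = FALSE)
      writeLines(utils::capture.output(print(cmpb)),
                 file.path(out, "bivariate_comparison.txt"))
      best_label <- attr(cmpb, "best")
      best_name <- names(cand)[vapply(biv, function(f)
        identical(f$label, best_label), logical(1))][1]
      say("refitting best bivariate model with robust SEs: ", best_label)
      best <- fit_bivariate_trajectory(abm, cand[[best_name]],
                                       se = "robust", h1 = h1b,
                                       alpha = config$alpha)
      utils::write.csv(best$params, file.path(out, "bivariate_estimates.csv"),
                       row.names = FALSE)
      writeLines(utils::capture.output(print(best), print(best$params),
                                       print(best$cumulative_change)),
                 file.path(out, "bivariate_estimates.txt"))
      fit_to_json(best, file.path(out, "bivariate_fit.json"))
      biv$best <- best
      manifest$best_bivariate <- best_label
    }

    stage <- "manifest"
    ledger <- do.call(rbind, lapply(c(unlist(uni, recursive = FALSE),
                                      biv[names(biv) != "best"]),
                                    function(f)
      data.frame(model = f$label, converged = f$converged,
                 grad_norm = f$grad_norm, n_cases = f$n_cases,
                 stringsAsFactors = FALSE)))
    manifest$convergence_ledger <- ledger
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, dataframe = "rows")
    res$lfa <- lfa; res$scores <- scores; res$bins <- abm
    res$univariate <- uni; res$bivariate <- biv
    say("done; artifacts in ", out)
    invisible(res)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
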