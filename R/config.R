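## Configuration objects for the synthetic panel generator.  The default
## values ARE the study conditions the pipeline targets: the bivariate
## growth configuration carries the published bivariate spline+linear
## estimates, the univariate configurations the published univariate spline
## estimates, and the panel design the HRS-like 2010/2012/2016 wave layout.

#' Latent growth configuration
#'
#' Defines the latent bivariate (or univariate) growth process that the
#' generator draws from: per-person intercepts and slopes in factor-score
#' SD units (slopes per decade, centered at the knot age), their covariance
#' as SDs plus a correlation matrix, and homogeneous occasion residuals
#' with a single within-occasion cross-process residual correlation.
#'
#' The default is the fitted bivariate model for fluid cognition (COG:
#' intercept + pre/post-70 spline slopes) and functional limitation (FNC:
#' intercept + linear slope).
#'
#' @param latent_names growth-coefficient labels; `<PROCESS>_i` for an
#'   intercept, `<PROCESS>_s` for a single linear slope, `<PROCESS>_s1` /
#'   `<PROCESS>_s2` for pre-/post-knot spline slopes
#' @param latent_means coefficient means (SD units; slopes per decade)
#' @param latent_sds coefficient SDs (must be `>= 0`)
#' @param latent_corr correlation matrix (symmetric, unit diagonal, PSD)
#' @param residual_sds named per-process occasion residual SDs
#' @param residual_cross_corr within-occasion cross-process residual
#'   correlation (`|r| <= 1`)
#' @param knot_age knot age in years for spline processes
#' @return object of class `growth_config`
#' @export
growth_config <- function(latent_names = c("COG_i", "COG_s1", "COG_s2",
                                           "FNC_i", "FNC_s"),
                          latent_means = c(0.031, -0.047, -0.230,
                                           0.115, 0.229),
                          latent_sds = sqrt(c(0.777, 0.142, 0.413,
                                              0.769, 0.150)),
                          latent_corr = default_bivariate_corr(),
                          residual_sds = c(COG = sqrt(0.313),
                                           FNC = sqrt(0.475)),
                          residual_cross_corr = 0.007,
                          knot_age = 70) {
  k <- length(latent_names)
  stopifnot(length(latent_means) == k, length(latent_sds) == k,
            all(dim(latent_corr) == k))
  if (any(latent_sds < 0)) stop("latent_sds must be nonnegative")
  if (any(residual_sds < 0)) stop("residual_sds must be nonnegative")
  if (abs(residual_cross_corr) > 1)
    stop("|residual_cross_corr| must be <= 1")
  if (max(abs(latent_corr - t(latent_corr))) > 1e-10)
    stop("latent_corr must be symmetric")
  if (max(abs(diag(latent_corr) - 1)) > 1e-10)
    stop("latent_corr must have a unit diagonal")
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latent_corr is not positive semidefinite (min eigenvalue ",
         format(min(ev), digits = 3), ")")
  processes <- unique(sub("_[^_]+$", "", latent_names))
  if (!all(processes %in% names(residual_sds)))
    stop("residual_sds must be named for processes: ",
         paste(processes, collapse = ", "))
  dimnames(latent_corr) <- list(latent_names, latent_names)
  structure(list(latent_names = latent_names,
                 latent_means = stats::setNames(latent_means, latent_names),
                 latent_sds = stats::setNames(latent_sds, latent_names),
                 latent_corr = latent_corr,
                 residual_sds = residual_sds[processes],
                 residual_cross_corr = residual_cross_corr,
                 knot_age = knot_age, processes = processes),
            class = "growth_config")
}

## published bivariate latent correlation matrix (positive definite)
default_bivariate_corr <- function() {
  nm <- c("COG_i", "COG_s1", "COG_s2", "FNC_i", "FNC_s")
  R <- diag(5)
  dimnames(R) <- list(nm, nm)
  set <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set("COG_i", "COG_s1", 0.445)
  set("COG_i", "COG_s2", -0.564)
  set("COG_s1", "COG_s2", 0.154)
  set("FNC_i", "FNC_s", 0.429)
  set("COG_i", "FNC_i", -0.300)
  set("COG_i", "FNC_s", -0.310)
  set("FNC_i", "COG_s1", -0.090)
  set("FNC_i", "COG_s2", 0.153)
  set("FNC_s", "COG_s1", -0.489)
  set("FNC_s", "COG_s2", 0.196)
  R
}

#' Univariate spline growth configurations
#'
#' Default generating values for a single process with intercept and
#' pre-/post-knot slopes, taken from the fitted univariate spline models
#' (slope means and all variances).  The univariate reports print no
#' intercept means, residual variances, or coefficient correlations; the
#' defaults use a zero intercept mean (scores are standardized at the
#' age-70/71 bin), the bivariate residual variances, and the bivariate
#' within-process correlation pattern.
#'
#' @param process `"COG"` (fluid cognition) or `"FNC"` (functional
#'   limitation)
#' @return a [growth_config()]
#' @export
univariate_growth_config <- function(process = c("COG", "FNC")) {
  process <- match.arg(process)
  if (process == "COG") {
    corr <- matrix(c(1, .445, -.564,
                     .445, 1, .154,
                     -.564, .154, 1), 3, 3)
    growth_config(latent_names = c("COG_i", "COG_s1", "COG_s2"),
                  latent_means = c(0, -0.027, -0.187),
                  latent_sds = sqrt(c(0.521, 0.086, 0.284)),
                  latent_corr = corr,
                  residual_sds = c(COG = sqrt(0.313)),
                  residual_cross_corr = 0)
  } else {
    corr <- matrix(c(1, .429, .429,
                     .429, 1, .154,
                     .429, .154, 1), 3, 3)
    growth_config(latent_names = c("FNC_i", "FNC_s1", "FNC_s2"),
                  latent_means = c(0, 0.112, 0.452),
                  latent_sds = sqrt(c(0.755, 0.096, 1.147)),
                  latent_corr = corr,
                  residual_sds = c(FNC = sqrt(0.475)),
                  residual_cross_corr = 0)
  }
}

#' @export
print.growth_config <- function(x, ...) {
  cat("Growth configuration:", paste(x$latent_names, collapse = ", "),
      sprintf("(knot at age %g)\n", x$knot_age))
  tab <- data.frame(mean = x$latent_means, sd = x$latent_sds)
  print(round(tab, 3))
  cat("residual SDs:", paste(sprintf("%s=%.3f", names(x$residual_sds),
                                     x$residual_sds), collapse = ", "),
      sprintf(" cross-process residual r = %.3f\n", x$residual_cross_corr))
  invisible(x)
}

#' Item measurement configuration
#'
#' Per-item linear measurement parameters used to generate observed item
#' scores from the latent process values: `y = nu + lambda * eta + e`,
#' with censored-count items rounded and clipped to their score range
#' (which produces the positive skew characteristic of the functional
#' limitation self-reports).  Defaults were calibrated by simulation so
#' that the fitted standardized loadings and wave-1 descriptives match the
#' published values (numeracy .85 down to recall .445 for cognition; ADL
#' .82 down to IADL .578 for functional limitation).
#'
#' @param items optional replacement data frame with columns `item`,
#'   `process`, `lambda`, `nu`, `theta`, `type` (`"continuous"` or
#'   `"count"`), `min`, `max`, `marker`
#' @return object of class `measurement_config` (a data frame)
#' @export
measurement_config <- function(items = NULL) {
  if (is.null(items)) items <- default_measurement_items()
  need <- c("item", "process", "lambda", "nu", "theta", "type",
            "min", "max", "marker")
  if (!all(need %in% names(items)))
    stop("measurement config needs columns: ", paste(need, collapse = ", "))
  if (any(items$theta <= 0)) stop("residual SDs must be > 0")
  for (pr in unique(items$process))
    if (sum(items$marker[items$process == pr]) != 1)
      stop("exactly one reference (marker) item required for process ", pr)
  bad <- items$type == "count" & !(is.finite(items$min))
  if (any(bad)) stop("count items need a finite floor: ",
                     paste(items$item[bad], collapse = ", "))
  class(items) <- c("measurement_config", "data.frame")
  items
}

## calibrated defaults: lambda/theta chosen for the published standardized
## loading pattern given the marginal latent SD under the default growth
## configuration; nu of the heavily censored limitation items chosen for the
## published wave-2010 descriptives after floor-censoring and rounding
default_measurement_items <- function() {
  df <- data.frame(
    item    = c("numeracy", "fluency", "serial7", "recall",
                "mobility", "adl", "iadl"),
    process = c("COG", "COG", "COG", "COG", "FNC", "FNC", "FNC"),
    lambda  = c(37.30, 4.30, 1.30, 1.483, 2.60, 1.18, 0.52),
    nu      = c(497.3, 17.4, 3.30, 10.1, 2.40, -0.68, -0.58),
    theta   = c(22.9, 5.68, 1.90, 2.96, 1.55, 0.62, 0.43),
    type    = c("continuous", "count", "count", "count",
                "count", "count", "count"),
    min     = c(-Inf, 0, 0, 0, 0, 0, 0),
    max     = c(Inf, Inf, 5, 20, 11, 6, 5),
    marker  = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  df
}

#' Panel design
#'
#' Sampling design of the accelerated longitudinal panel: person count,
#' wave offsets in years, truncated-normal baseline age distribution,
#' monotone wave retention, and an optional missing-at-random dropout
#' mechanism driven by current functional limitation.
#'
#' Defaults emulate the HRS 2010/2012/2016 analysis panel: baseline age
#' Normal(64.9, 9.6) truncated so all waves can fall in the 50-85 modeling
#' window, cumulative retention 1/.916/.752, and logistic MAR dropout on
#' current FNC.
#'
#' @param n_persons number of persons at baseline
#' @param wave_years wave offsets in years, strictly increasing from 0
#' @param baseline_age_mean,baseline_age_sd baseline age distribution
#' @param baseline_age_range truncation bounds for generated baseline ages
#' @param age_range analysis age window (used downstream for bin filtering)
#' @param retention cumulative per-wave retention probabilities in (0, 1]
#' @param mar_attrition_coef log-odds of dropout per unit of current FNC
#'   (0 = completely at random)
#' @param seed integer RNG seed recorded with the design
#' @return object of class `panel_design`
#' @export
panel_design <- function(n_persons = 14489, wave_years = c(0, 2, 6),
                         baseline_age_mean = 64.9, baseline_age_sd = 9.6,
                         baseline_age_range = c(50, 83),
                         age_range = c(50, 85),
                         retention = c(1, 0.916, 0.752),
                         mar_attrition_coef = 0.3, seed = 1L) {
  stopifnot(n_persons >= 1, length(wave_years) >= 1)
  if (wave_years[1] != 0 || is.unsorted(wave_years, strictly = TRUE))
    stop("wave_years must be strictly increasing and start at 0")
  if (length(retention) != length(wave_years))
    stop("retention must have one entry per wave")
  if (any(retention <= 0) || any(retention > 1))
    stop("retention probabilities must lie in (0, 1]")
  if (is.unsorted(rev(retention)))
    stop("cumulative retention must be non-increasing")
  structure(list(n_persons = as.integer(n_persons), wave_years = wave_years,
                 baseline_age_mean = baseline_age_mean,
                 baseline_age_sd = baseline_age_sd,
                 baseline_age_range = baseline_age_range,
                 age_range = age_range, retention = retention,
                 mar_attrition_coef = mar_attrition_coef,
                 seed = as.integer(seed),
                 wave_labels = 2010 + wave_years),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("Panel design: %d persons, waves %s (years %s)\n",
              x$n_persons, paste(x$wave_labels, collapse = "/"),
              paste(x$wave_years, collapse = "/")))
  cat(sprintf("  baseline age ~ N(%.1f, %.1f) truncated [%g, %g], retention %s, MAR coef %.2f, seed %d\n",
              x$baseline_age_mean, x$baseline_age_sd,
              x$baseline_age_range[1], x$baseline_age_range[2],
              paste(x$retention, collapse = "/"),
              x$mar_attrition_coef, x$seed))
  invisible(x)
}

#' Write or read generator configuration as YAML
#'
#' @param growth a [growth_config()]
#' @param measurement a [measurement_config()] or `NULL`
#' @param design a [panel_design()]
#' @param path file to write (`NULL` returns the YAML string)
#' @return YAML string, invisibly when written to file
#' @export
dump_config <- function(growth = growth_config(),
                        measurement = measurement_config(),
                        design = panel_design(), path = NULL) {
  obj <- list(growth = list(latent_names = growth$latent_names,
                            latent_means = as.numeric(growth$latent_means),
                            latent_sds = as.numeric(growth$latent_sds),
                            latent_corr = unname(apply(growth$latent_corr, 1,
                                                       as.numeric,
                                                       simplify = FALSE)),
                            residual_sds = as.list(growth$residual_sds),
                            residual_cross_corr = growth$residual_cross_corr,
                            knot_age = growth$knot_age),
              measurement = if (!is.null(measurement))
                lapply(seq_len(nrow(measurement)), function(i)
                  lapply(as.list(measurement[i, ]), function(v)
                    if (is.numeric(v) && !is.finite(v))
                      as.character(v) else v)),
              design = unclass(design))
  txt <- yaml::as.yaml(obj)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file written by [dump_config()]
#' @return list with `growth`, `measurement`, `design`
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- obj$growth
  growth <- growth_config(latent_names = g$latent_names,
                          latent_means = unlist(g$latent_means),
                          latent_sds = unlist(g$latent_sds),
                          latent_corr = do.call(rbind, g$latent_corr),
                          residual_sds = unlist(g$residual_sds),
                          residual_cross_corr = g$residual_cross_corr,
                          knot_age = g$knot_age)
  meas <- NULL
  if (!is.null(obj$measurement)) {
    rows <- lapply(obj$measurement, function(r) {
      r$min <- if (is.character(r$min)) as.numeric(r$min) else r$min
      r$max <- if (is.character(r$max)) as.numeric(r$max) else r$max
      as.data.frame(r, stringsAsFactors = FALSE)
    })
    meas <- measurement_config(do.call(rbind, rows))
  }
  d <- obj$design
  design <- panel_design(n_persons = d$n_persons,
                         wave_years = unlist(d$wave_years),
                         baseline_age_mean = d$baseline_age_mean,
                         baseline_age_sd = d$baseline_age_sd,
                         baseline_age_range = unlist(d$baseline_age_range),
                         age_range = unlist(d$age_range),
                         retention = unlist(d$retention),
                         mar_attrition_coef = d$mar_attrition_coef,
                         seed = d$seed)
  list(growth = growth, measurement = meas, design = design)
}
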