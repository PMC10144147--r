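## Synthetic panel generator: person-level growth coefficients, latent
## process values along chronological age, factor-score-level panels
## (stage-2-only testing path) and item-level panels (full pipeline path),
## with monotone and optionally MAR attrition.

#' Draw person-level growth coefficients
#'
#' Samples rows from the multivariate normal with the configuration's
#' means and covariance `diag(sds) %*% corr %*% diag(sds)`.
#'
#' @param config a [growth_config()]
#' @param n number of persons
#' @param rng_seed integer seed (`NULL` to use the current RNG state)
#' @return `n` x k matrix with the configuration's latent names as columns
#' @export
draw_growth_coefficients <- function(config, n, rng_seed = NULL) {
  stopifnot(inherits(config, "growth_config"), n >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  D <- diag(config$latent_sds, length(config$latent_sds))
  Sigma <- D %*% config$latent_corr %*% D
  rmvnorm_draw(n, config$latent_means, Sigma)
}

#' Latent process values at an age
#'
#' Evaluates each process's piecewise-linear (or linear) trajectory at the
#' given age(s), with time scaled in decades and centered at the knot age:
#' `s = (age - knot_age) / 10`; spline processes contribute
#' `i + s1 * min(s, 0) + s2 * max(s, 0)`, linear processes `i + s * slope`.
#'
#' @param coeffs coefficient matrix from [draw_growth_coefficients()] (or a
#'   single named vector)
#' @param age age in years; scalar or one value per row of `coeffs`
#' @param config the [growth_config()] the coefficients were drawn from
#' @return matrix with one column per process (`COG`, `FNC`)
#' @export
latent_value_at_age <- function(coeffs, age, config) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, 1,
                                             dimnames = list(NULL, names(coeffs)))
  s <- (age - config$knot_age) / 10
  out <- matrix(NA_real_, nrow(coeffs), length(config$processes),
                dimnames = list(NULL, config$processes))
  for (pr in config$processes) {
    i_col <- paste0(pr, "_i")
    val <- coeffs[, i_col]
    if (paste0(pr, "_s") %in% colnames(coeffs)) {
      val <- val + coeffs[, paste0(pr, "_s")] * s
    } else {
      val <- val + coeffs[, paste0(pr, "_s1")] * pmin(s, 0) +
        coeffs[, paste0(pr, "_s2")] * pmax(s, 0)
    }
    out[, pr] <- val
  }
  out
}

## baseline ages + per-wave monotone observation flags (MAR on current FNC
## when a FNC process exists and the coefficient is nonzero)
simulate_design_frame <- function(growth, design, truth_fnc) {
  n <- design$n_persons
  W <- length(design$wave_years)
  observed <- matrix(FALSE, n, W)
  observed[, 1] <- stats::runif(n) <= design$retention[1]
  for (w in seq_len(W)[-1]) {
    base_keep <- design$retention[w] / design$retention[w - 1]
    if (base_keep >= 1) {
      keep <- rep(TRUE, n)
    } else if (design$mar_attrition_coef != 0 && !is.null(truth_fnc)) {
      fnc <- truth_fnc[, w]
      p_keep <- stats::plogis(stats::qlogis(base_keep) -
                                design$mar_attrition_coef * (fnc - mean(fnc)))
      keep <- stats::runif(n) <= p_keep
    } else {
      keep <- stats::runif(n) <= base_keep
    }
    observed[, w] <- observed[, w - 1] & keep
  }
  observed
}

## baseline ages: truncated normal, reported in whole years as surveys
## record them (rounding keeps the published mean/SD of the age variable)
draw_baseline_ages <- function(design) {
  round(rtruncnorm_draw(design$n_persons, design$baseline_age_mean,
                        design$baseline_age_sd,
                        design$baseline_age_range[1],
                        design$baseline_age_range[2]))
}

#' Generate a factor-score-level panel
#'
#' Stage-2-only testing path: per retained person-wave the score is the
#' latent trajectory value plus an occasion residual with the configured
#' per-process SDs and within-occasion cross-process correlation.  Ages are
#' baseline age (truncated normal, reported in whole years) plus the exact
#' wave offsets; attrition is monotone and, when `mar_attrition_coef > 0`,
#' missing at random given current functional limitation.
#'
#' @param growth a [growth_config()]
#' @param design a [panel_design()]
#' @return list with `panel` (long data frame: `id`, `wave_year`,
#'   `age_years`, `cog_score` and/or `fnc_score`, `observed`) and `truth`
#'   (per person-wave latent values, flags, and the person's growth
#'   coefficients)
#' @export
generate_score_panel <- function(growth, design) {
  stopifnot(inherits(growth, "growth_config"),
            inherits(design, "panel_design"))
  set.seed(design$seed)
  n <- design$n_persons
  W <- length(design$wave_years)
  coeffs <- draw_growth_coefficients(growth, n)
  base_age <- draw_baseline_ages(design)
  k <- length(growth$processes)
  ages <- outer(base_age, design$wave_years, `+`)
  latent <- array(NA_real_, c(n, W, k),
                  dimnames = list(NULL, NULL, growth$processes))
  for (w in seq_len(W))
    latent[, w, ] <- latent_value_at_age(coeffs, ages[, w], growth)

  ## occasion residuals with the single cross-process correlation
  Rr <- diag(k)
  if (k == 2) Rr[1, 2] <- Rr[2, 1] <- growth$residual_cross_corr
  Dr <- diag(growth$residual_sds, k)
  Sr <- Dr %*% Rr %*% Dr
  scores <- latent
  for (w in seq_len(W))
    scores[, w, ] <- latent[, w, ] +
      rmvnorm_draw(n, rep(0, k), Sr)

  truth_fnc <- if ("FNC" %in% growth$processes)
    latent[, , "FNC", drop = TRUE] else NULL
  observed <- simulate_design_frame(growth, design, truth_fnc)

  score_cols <- paste0(tolower(growth$processes), "_score")
  panel <- data.frame(id = rep(seq_len(n), W),
                      wave_year = rep(design$wave_labels, each = n),
                      age_years = as.vector(ages))
  for (j in seq_len(k)) {
    v <- as.vector(scores[, , j])
    v[!as.vector(observed)] <- NA_real_
    panel[[score_cols[j]]] <- v
  }
  panel$observed <- as.vector(observed)

  truth <- data.frame(id = rep(seq_len(n), W),
                      wave_year = rep(design$wave_labels, each = n),
                      age_years = as.vector(ages))
  for (j in seq_len(k))
    truth[[paste0("true_", tolower(growth$processes[j]))]] <-
      as.vector(latent[, , j])
  truth$observed <- as.vector(observed)
  for (cn in colnames(coeffs)) truth[[cn]] <- rep(coeffs[, cn], W)

  ord <- order(panel$id, panel$wave_year)
  list(panel = panel[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE])
}

#' Generate an item-level panel
#'
#' Full-pipeline testing path: observed item scores per retained
#' person-wave, generated linearly from the latent process values
#' (`y = nu + lambda * eta + e`); censored-count items are rounded and
#' clipped to their score range, which yields the positive skew seen in
#' the functional limitation self-reports.
#'
#' @param growth a [growth_config()]
#' @param meas a [measurement_config()]
#' @param design a [panel_design()]
#' @return list with `panel` (long data frame: `id`, `wave_year`,
#'   `age_years`, one column per item, `observed`) and `truth` as in
#'   [generate_score_panel()]
#' @export
generate_item_panel <- function(growth, meas, design) {
  stopifnot(inherits(growth, "growth_config"),
            inherits(meas, "measurement_config"),
            inherits(design, "panel_design"))
  if (!all(meas$process %in% growth$processes))
    stop("measurement config references processes missing from the growth config")
  set.seed(design$seed)
  n <- design$n_persons
  W <- length(design$wave_years)
  coeffs <- draw_growth_coefficients(growth, n)
  base_age <- draw_baseline_ages(design)
  k <- length(growth$processes)
  ages <- outer(base_age, design$wave_years, `+`)
  ## person-wave factor state = trajectory value + occasion disturbance
  ## (the same residual structure the score-level generator uses)
  Rr <- diag(k)
  if (k == 2) Rr[1, 2] <- Rr[2, 1] <- growth$residual_cross_corr
  Dr <- diag(growth$residual_sds, k)
  Sr <- Dr %*% Rr %*% Dr
  latent <- array(NA_real_, c(n, W, k),
                  dimnames = list(NULL, NULL, growth$processes))
  for (w in seq_len(W))
    latent[, w, ] <- latent_value_at_age(coeffs, ages[, w], growth) +
      rmvnorm_draw(n, rep(0, k), Sr)

  items <- array(NA_real_, c(n, W, nrow(meas)),
                 dimnames = list(NULL, NULL, meas$item))
  for (w in seq_len(W)) for (j in seq_len(nrow(meas))) {
    eta <- latent[, w, meas$process[j]]
    y <- meas$nu[j] + meas$lambda[j] * eta + stats::rnorm(n, 0, meas$theta[j])
    if (meas$type[j] == "count")
      y <- pmin(pmax(round(y), meas$min[j]), meas$max[j])
    items[, w, j] <- y
  }

  truth_fnc <- if ("FNC" %in% growth$processes)
    latent[, , "FNC", drop = TRUE] else NULL
  observed <- simulate_design_frame(growth, design, truth_fnc)

  panel <- data.frame(id = rep(seq_len(n), W),
                      wave_year = rep(design$wave_labels, each = n),
                      age_years = as.vector(ages))
  for (j in seq_len(nrow(meas))) {
    v <- as.vector(items[, , j])
    v[!as.vector(observed)] <- NA_real_
    panel[[meas$item[j]]] <- v
  }
  panel$observed <- as.vector(observed)

  truth <- data.frame(id = rep(seq_len(n), W),
                      wave_year = rep(design$wave_labels, each = n),
                      age_years = as.vector(ages))
  for (j in seq_len(k))
    truth[[paste0("true_", tolower(growth$processes[j]))]] <-
      as.vector(latent[, , j])
  truth$observed <- as.vector(observed)
  for (cn in colnames(coeffs)) truth[[cn]] <- rep(coeffs[, cn], W)

  ord <- order(panel$id, panel$wave_year)
  list(panel = panel[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE])
}

#' Write a generated panel (and truth table) to CSV with a seed sidecar
#'
#' @param sim result of [generate_score_panel()] or [generate_item_panel()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @param design the [panel_design()] used (its seed is recorded)
#' @return invisibly, the paths written
#' @export
write_panel <- function(sim, dir, prefix = "panel", design = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, paste0(prefix, ".csv")),
             truth = file.path(dir, paste0(prefix, "_truth.csv")),
             meta = file.path(dir, paste0(prefix, "_meta.json")))
  utils::write.csv(sim$panel, paths["panel"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  meta <- list(seed = if (!is.null(design)) design$seed else NA,
               n_persons = length(unique(sim$panel$id)),
               waves = sort(unique(sim$panel$wave_year)))
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
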