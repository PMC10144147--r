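## Stage 2: restructure factor scores into 2-year chronological age bins
## (accelerated longitudinal design), rescale at the age-70/71 bin, and fit
## univariate / bivariate latent trajectory models (intercept-only, linear,
## piecewise spline) by FIML.

#' The 18 two-year age bins from 50/51 to 84/85
#'
#' @return data frame with `label`, `lower`, and the decade time code
#'   `code = (lower - 70) / 10`
#' @export
age_bin_table <- function() {
  lower <- seq(50, 84, by = 2)
  data.frame(label = paste(lower, lower + 1, sep = "/"),
             lower = lower, code = (lower - 70) / 10,
             stringsAsFactors = FALSE)
}

#' Place factor scores into two-year age bins
#'
#' Maps `floor(age)` to its bin, drops observations outside ages 50-85
#' with logged counts, and averages the (rare) case of two occasions
#' falling into one bin.  The result is a sparsely observed person x
#' (bin x process) matrix: each person contributes at most one value per
#' bin and at most as many bins as waves.
#'
#' @param scores factor-score panel (columns `id`, `age_years`, and
#'   `cog_score` and/or `fnc_score`)
#' @param age_range modeled age window
#' @return object of class `age_bin_matrix`: list with `data` (wide
#'   matrix, columns `cog_b50 ... fnc_b84`), `bins`, `processes`, `ids`,
#'   drop/averaging counts
#' @export
assign_age_bins <- function(scores, age_range = c(50, 85)) {
  stopifnot(all(c("id", "age_years") %in% names(scores)))
  bins <- age_bin_table()
  procs <- intersect(c("cog", "fnc"), sub("_score$", "",
                                          grep("_score$", names(scores),
                                               value = TRUE)))
  if (!length(procs)) stop("no *_score columns found")
  fa <- floor(scores$age_years)
  low <- fa < age_range[1]
  high <- fa > age_range[2]
  keep <- !(low | high) & !is.na(fa)
  n_low <- sum(low, na.rm = TRUE); n_high <- sum(high, na.rm = TRUE)
  sc <- scores[keep, , drop = FALSE]
  bin_idx <- pmin((floor(sc$age_years) - age_range[1]) %/% 2 + 1, nrow(bins))
  ids <- sort(unique(scores$id))
  n <- length(ids)
  row_of <- match(sc$id, ids)
  nb <- nrow(bins)
  sums <- matrix(0, n, nb * length(procs))
  cnts <- matrix(0L, n, nb * length(procs))
  for (k in seq_along(procs)) {
    v <- sc[[paste0(procs[k], "_score")]]
    ok <- !is.na(v)
    cidx <- (k - 1) * nb + bin_idx[ok]
    flat <- (cidx - 1L) * n + row_of[ok]
    sums[flat] <- sums[flat] + 0  # ensure numeric slot exists
    for (u in seq_along(flat)) {
      sums[flat[u]] <- sums[flat[u]] + v[ok][u]
      cnts[flat[u]] <- cnts[flat[u]] + 1L
    }
  }
  n_avg <- sum(cnts > 1L)
  if (n_avg)
    warning(n_avg, " person-bin cell(s) received two occasions; averaged")
  data <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), NA_real_)
  colnames(data) <- as.vector(vapply(procs, function(pr)
    paste0(pr, "_b", bins$lower), character(nb)))
  rownames(data) <- ids
  structure(list(data = data, bins = bins, processes = procs, ids = ids,
                 n_dropped_low = n_low, n_dropped_high = n_high,
                 n_averaged = n_avg),
            class = "age_bin_matrix")
}

#' @export
print.age_bin_matrix <- function(x, ...) {
  cat("Age-bin matrix:", length(x$ids), "persons,", nrow(x$bins),
      "bins x", length(x$processes), "process(es)\n")
  cat(sprintf("  dropped %d obs below and %d above the %s age window; %d averaged cells\n",
              x$n_dropped_low, x$n_dropped_high, "50-85", x$n_averaged))
  invisible(x)
}

#' Standardize an age-bin matrix at a target bin
#'
#' Rescales each process's columns by the mean and SD of its scores in
#' the target bin (default 70/71), so trajectory estimates read as SD
#' units at age 70.  An affine rescaling common to a process's columns
#' leaves chi-square, TLI and RMSEA of subsequent trajectory models
#' unchanged.
#'
#' @param matrix an [assign_age_bins()] result
#' @param bin target bin label
#' @return the rescaled `age_bin_matrix`, with a `rescale_record`
#'   attribute holding the means/SDs applied
#' @export
rescale_at_bin <- function(matrix, bin = "70/71") {
  stopifnot(inherits(matrix, "age_bin_matrix"))
  b <- match(bin, matrix$bins$label)
  if (is.na(b)) stop("unknown bin: ", bin)
  nb <- nrow(matrix$bins)
  rec <- list()
  for (k in seq_along(matrix$processes)) {
    cols <- (k - 1) * nb + seq_len(nb)
    v <- matrix$data[, cols[b]]
    v <- v[!is.na(v)]
    if (length(v) < 2)
      stop("target bin ", bin, " has fewer than 2 observations for process ",
           matrix$processes[k])
    m <- mean(v); s <- stats::sd(v)
    matrix$data[, cols] <- (matrix$data[, cols] - m) / s
    rec[[matrix$processes[k]]] <- c(mean = m, sd = s)
  }
  attr(matrix, "rescale_record") <- rec
  matrix
}

#' Trajectory model specification
#'
#' @param cog,fnc parameterization per process: `"intercept_only"`,
#'   `"linear"`, `"spline"`, or `NULL` to exclude the process
#' @param knot knot bin for spline parameterizations (one of `"60/61"`,
#'   `"64/65"`, `"70/71"`, `"74/75"`)
#' @return object of class `trajectory_spec`
#' @export
trajectory_spec <- function(cog = "spline", fnc = "linear", knot = "70/71") {
  choices <- c("intercept_only", "linear", "spline")
  if (!is.null(cog)) cog <- match.arg(cog, choices)
  if (!is.null(fnc)) fnc <- match.arg(fnc, choices)
  if (is.null(cog) && is.null(fnc)) stop("at least one process required")
  if (!knot %in% c("60/61", "64/65", "70/71", "74/75"))
    stop("knot bin must be one of 60/61, 64/65, 70/71, 74/75")
  param <- c(cog = cog, fnc = fnc)   # NULLs drop out
  structure(list(param = param, knot = knot,
                 processes = names(param)),
            class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat("Trajectory spec:", spec_label(x), "\n")
  invisible(x)
}

spec_label <- function(spec) {
  paste(vapply(spec$processes, function(pr) {
    pm <- spec$param[[pr]]
    lab <- switch(pm, intercept_only = "intercept-only", linear = "linear",
                  spline = paste0("spline(", spec$knot, ")"))
    paste0(toupper(pr), " ", lab)
  }, character(1)), collapse = " + ")
}

## latent names per process under a parameterization
spec_latents <- function(spec) {
  unlist(lapply(spec$processes, function(pr) {
    P <- toupper(pr)
    switch(spec$param[[pr]],
           intercept_only = paste0(P, "_i"),
           linear = paste0(P, c("_i", "_s")),
           spline = paste0(P, c("_i", "_s1", "_s2")))
  }))
}

#' Build a latent trajectory moment structure
#'
#' Manifests are the observed age bins per process; intercept loadings are
#' 1, linear slope loadings the decade time code `s = (bin_lower - 70)/10`,
#' spline loadings `min(s - k, 0)` and `max(s - k, 0)` around the knot
#' code `k`.  Manifest intercepts are fixed at zero with free latent
#' means; the latent covariance is fully free (log-Cholesky, optionally
#' block-diagonal by process); residual variances are homogeneous per
#' process, with a single within-bin cross-process residual covariance in
#' bivariate models.
#'
#' @param spec a [trajectory_spec()]
#' @param cross_latent if `FALSE`, latent covariances across processes are
#'   fixed to zero (block-diagonal Psi)
#' @return a [moment_structure()]
#' @export
build_trajectory_structure <- function(spec, cross_latent = TRUE) {
  stopifnot(inherits(spec, "trajectory_spec"))
  bins <- age_bin_table()
  nb <- nrow(bins)
  kcode <- (as.numeric(sub("/.*", "", spec$knot)) - 70) / 10
  if (kcode < min(bins$code) || kcode > max(bins$code))
    stop("spline knot bin lies outside the bin range")
  latents <- spec_latents(spec)
  manifest <- as.vector(vapply(spec$processes, function(pr)
    paste0(pr, "_b", bins$lower), character(nb)))
  p <- length(manifest); m <- length(latents)

  Lambda <- matrix(0, p, m, dimnames = list(manifest, latents))
  blocks <- list()
  for (k in seq_along(spec$processes)) {
    pr <- spec$processes[k]; P <- toupper(pr)
    rows <- (k - 1) * nb + seq_len(nb)
    Lambda[rows, paste0(P, "_i")] <- 1
    if (spec$param[[pr]] == "linear")
      Lambda[rows, paste0(P, "_s")] <- bins$code
    if (spec$param[[pr]] == "spline") {
      Lambda[rows, paste0(P, "_s1")] <- pmin(bins$code - kcode, 0)
      Lambda[rows, paste0(P, "_s2")] <- pmax(bins$code - kcode, 0)
    }
    blocks[[k]] <- which(sub("_[^_]+$", "", latents) == P)
  }
  nu <- stats::setNames(numeric(p), manifest)
  alpha <- stats::setNames(numeric(m), latents)
  Psi <- diag(ifelse(grepl("_i$", latents), 0.7, 0.25), m)
  dimnames(Psi) <- list(latents, latents)
  Theta <- diag(0.4, p)
  dimnames(Theta) <- list(manifest, manifest)

  fr <- list(alpha = integer(m), Theta = matrix(0L, p, p))
  par_names <- character(0)
  nxt <- 0L
  new_par <- function(name) { nxt <<- nxt + 1L; par_names[nxt] <<- name; nxt }
  for (j in seq_len(m)) fr$alpha[j] <- new_par(paste0("alpha(", latents[j], ")"))
  for (k in seq_along(spec$processes)) {
    rows <- (k - 1) * nb + seq_len(nb)
    cls <- new_par(paste0("resid_var(", toupper(spec$processes[k]), ")"))
    for (r in rows) fr$Theta[r, r] <- cls
  }
  if (length(spec$processes) == 2) {
    cls <- new_par("resid_cov")
    for (b in seq_len(nb)) {
      fr$Theta[b, nb + b] <- cls
      fr$Theta[nb + b, b] <- cls
    }
  }
  moment_structure(nu, Lambda, alpha, Psi, Theta, fr, psi_mode = "chol",
                   psi_blocks = if (cross_latent) list(seq_len(m)) else blocks,
                   par_names = par_names)
}

## data + pooled-OLS start values for a trajectory fit
trajectory_fit_data <- function(matrix, spec) {
  nb <- nrow(matrix$bins)
  missing_pr <- setdiff(spec$processes, matrix$processes)
  if (length(missing_pr))
    stop("age-bin matrix lacks process(es): ",
         paste(missing_pr, collapse = ", "))
  cols <- unlist(lapply(spec$processes, function(pr)
    paste0(pr, "_b", matrix$bins$lower)))
  Y <- matrix$data[, cols, drop = FALSE]
  keep <- rowSums(!is.na(Y)) > 0
  Y[keep, , drop = FALSE]
}

trajectory_start <- function(ms, spec, Y) {
  bins <- age_bin_table()
  nb <- nrow(bins)
  theta <- ms_pack(ms)
  for (k in seq_along(spec$processes)) {
    rows <- (k - 1) * nb + seq_len(nb)
    lat_cols <- which(sub("_[^_]+$", "", ms$latent_names) ==
                        toupper(spec$processes[k]))
    yk <- Y[, rows, drop = FALSE]
    obs <- which(!is.na(yk), arr.ind = TRUE)
    X <- ms$Lambda[rows, lat_cols, drop = FALSE][obs[, 2], , drop = FALSE]
    cf <- stats::lm.fit(X, yk[obs])
    for (j in seq_along(lat_cols)) {
      nm <- paste0("alpha(", ms$latent_names[lat_cols[j]], ")")
      if (nm %in% names(theta)) theta[nm] <- cf$coefficients[j]
    }
    rv <- paste0("resid_var(", toupper(spec$processes[k]), ")")
    resid_var <- stats::var(cf$residuals)
    if (rv %in% names(theta) && is.finite(resid_var) && resid_var > 0)
      theta[rv] <- log(sqrt(resid_var * 0.6))
  }
  theta
}

#' Fit one latent trajectory model
#'
#' @param matrix an [assign_age_bins()] (optionally rescaled) result
#' @param spec a [trajectory_spec()]
#' @param se,h1,control passed to [fit_sem()]
#' @param cross_latent passed to [build_trajectory_structure()]
#' @return a `sem_fit` with an added `label` and `spec`
#' @export
fit_trajectory_model <- function(matrix, spec, se = "none", h1 = FALSE,
                                 cross_latent = TRUE, control = list()) {
  ms <- build_trajectory_structure(spec, cross_latent = cross_latent)
  Y <- trajectory_fit_data(matrix, spec)
  data <- missing_pattern_data(Y)
  start <- trajectory_start(ms, spec, Y)
  fit <- fit_sem(ms, data, start = start, se = se, h1 = h1,
                 control = control)
  fit$label <- spec_label(spec)
  fit$spec <- spec
  fit
}

#' Fit the univariate trajectory model set for one process
#'
#' Fits the intercept-only, linear, and four spline variants (knots at
#' bins 60/61, 64/65, 70/71, 74/75) to one process, sharing a single
#' saturated/baseline likelihood computation, and reports convergence per
#' model.
#'
#' @param matrix an [assign_age_bins()] result
#' @param process `"cog"` or `"fnc"`
#' @param specs optional list of [trajectory_spec()] overriding the
#'   default model set
#' @param se standard errors for each fit (default none; use
#'   [fit_trajectory_model()] on the selected model for SEs)
#' @param h1 compute chi-square/TLI/RMSEA (shared across models)
#' @param control passed to [fit_sem()]
#' @return named list of `sem_fit` objects
#' @export
fit_univariate_trajectories <- function(matrix, process = c("cog", "fnc"),
                                        specs = NULL, se = "none",
                                        h1 = TRUE, control = list()) {
  process <- match.arg(process)
  one <- function(param, knot = "70/71") {
    if (process == "cog") trajectory_spec(cog = param, fnc = NULL, knot = knot)
    else trajectory_spec(cog = NULL, fnc = param, knot = knot)
  }
  if (is.null(specs)) {
    specs <- c(list(intercept_only = one("intercept_only"),
                    linear = one("linear")),
               stats::setNames(lapply(c("60/61", "64/65", "70/71", "74/75"),
                                      function(kb) one("spline", kb)),
                               paste0("spline_", c("60/61", "64/65",
                                                   "70/71", "74/75"))))
  }
  h1_pre <- FALSE
  if (isTRUE(h1)) {
    Y <- trajectory_fit_data(matrix, specs[[1]])
    data <- missing_pattern_data(Y)
    h1_pre <- list(sat = saturated_loglik(data), base = baseline_loglik(data))
  }
  lapply(specs, function(sp)
    fit_trajectory_model(matrix, sp, se = se, h1 = h1_pre, control = control))
}

#' Fit the bivariate latent trajectory model
#'
#' Default parameterization: spline (knot 70/71) for cognition, linear
#' slope for functional limitation — five correlated latents with
#' homogeneous per-process residual variances and one within-bin
#' cross-process residual covariance.  The result carries a parameter
#' table in the published layout (means, variances, residuals with robust
#' SEs; correlations as standardized estimates).
#'
#' @param matrix an [assign_age_bins()] (typically rescaled) result with
#'   both processes
#' @param spec a bivariate [trajectory_spec()]
#' @param se,h1,control passed to [fit_sem()]
#' @param alpha significance threshold for flagging
#' @return a `sem_fit` with added `params` table
#' @export
fit_bivariate_trajectory <- function(matrix, spec = trajectory_spec(),
                                     se = "robust", h1 = TRUE,
                                     alpha = 0.005, control = list()) {
  if (length(spec$processes) != 2)
    stop("bivariate fit requires both processes in the spec")
  fit <- fit_trajectory_model(matrix, spec, se = se, h1 = h1,
                              control = control)
  if (!is.null(fit$vcov_robust) || !is.null(fit$vcov_naive))
    fit$params <- natural_params(fit, alpha = alpha)
  fit$cumulative_change <- cumulative_change(fit)
  fit
}

#' Cumulative model-implied change over the two age windows
#'
#' Converts per-decade slope means into total change across ages 50-70
#' (2.0 decades) and 70-85 (1.5 decades): for a spline process the
#' pre-knot slope drives the first window and the post-knot slope the
#' second; for a linear process the single slope drives both.
#'
#' @param fit a fitted trajectory model
#' @return data frame with `process`, `window`, `change`
#' @export
cumulative_change <- function(fit) {
  spec <- fit$spec
  if (is.null(spec)) stop("not a trajectory fit")
  out <- NULL
  for (pr in spec$processes) {
    P <- toupper(pr)
    pm <- spec$param[[pr]]
    if (pm == "intercept_only") next
    if (pm == "linear") {
      s <- fit$theta[paste0("alpha(", P, "_s)")]
      ch <- c(s * 2.0, s * 1.5)
    } else {
      ch <- c(fit$theta[paste0("alpha(", P, "_s1)")] * 2.0,
              fit$theta[paste0("alpha(", P, "_s2)")] * 1.5)
    }
    out <- rbind(out, data.frame(process = P,
                                 window = c("50-70", "70-85"),
                                 change = unname(ch)))
  }
  out
}

#' Model comparison table
#'
#' Tabulates chi-square (df), TLI, RMSEA with CI, AIC and convergence for
#' a set of fits on identical data; computes the chi-square difference per
#' df for consecutively nested models (ordered by df) and flags the best
#' model by AIC among converged candidates.
#'
#' @param results (named) list of `sem_fit` objects on the same data
#' @return data frame of class `model_comparison`
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 1)
  cks <- lapply(results, `[[`, "data_checksum")
  if (!all(vapply(cks, function(x) isTRUE(all.equal(x, cks[[1]])),
                  logical(1))))
    stop("models were fitted to different data sets; comparison refused")
  nm <- names(results) %||% paste0("model", seq_along(results))
  lab <- vapply(seq_along(results), function(i)
    results[[i]]$label %||% nm[i], character(1))
  tab <- data.frame(
    model = lab,
    chi2 = vapply(results, function(f) f$chi2 %||% NA_real_, numeric(1)),
    df = vapply(results, function(f) f$df %||% NA_real_, numeric(1)),
    tli = vapply(results, function(f) f$tli %||% NA_real_, numeric(1)),
    rmsea = vapply(results, function(f) f$rmsea %||% NA_real_, numeric(1)),
    rmsea_lo = vapply(results, function(f)
      if (is.null(f$rmsea_ci)) NA_real_ else f$rmsea_ci[1], numeric(1)),
    rmsea_hi = vapply(results, function(f)
      if (is.null(f$rmsea_ci)) NA_real_ else f$rmsea_ci[2], numeric(1)),
    aic = vapply(results, `[[`, numeric(1), "aic"),
    n_params = vapply(results, `[[`, numeric(1), "n_params"),
    converged = vapply(results, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  ## most restrictive (largest df) first; for a nested pair the more
  ## restrictive model has the larger chi2, so both deltas are >= 0
  ord <- order(-tab$df)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_chi2 <- c(NA, tab$chi2[-nrow(tab)] - tab$chi2[-1])
  tab$delta_df <- c(NA, tab$df[-nrow(tab)] - tab$df[-1])
  best <- which(tab$converged & tab$aic == min(tab$aic[tab$converged]))
  attr(tab, "best") <- if (length(best)) tab$model[best[1]] else NA_character_
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  show <- data.frame(
    Model = x$model,
    `Chi2(df)` = sprintf("%.0f (%d)", x$chi2, x$df),
    TLI = sprintf("%.3f", x$tli),
    `RMSEA [95%CI]` = sprintf("%.3f [%.3f, %.3f]", x$rmsea, x$rmsea_lo,
                              x$rmsea_hi),
    AIC = sprintf("%.0f", x$aic),
    conv = ifelse(x$converged, "yes", "NO"),
    check.names = FALSE)
  print(show, row.names = FALSE)
  if (!is.na(attr(x, "best")))
    cat("Best by AIC among converged:", attr(x, "best"), "\n")
  invisible(x)
}
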