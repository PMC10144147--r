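## FIML estimation of a moment structure: quasi-Newton optimization over the
## unconstrained parameterization (raw means/loadings/covariances, log-SD
## variances, log-Cholesky latent covariance blocks), naive and Huber-White
## sandwich standard errors, and likelihood-based fit statistics.

default_fit_control <- function(control = list()) {
  ctrl <- list(grad_tol = 1e-5, rel_tol = 1e-10, iter_max = 2000,
               restarts = 2, hess_step = 1e-4)
  ctrl[names(control)] <- control
  ctrl
}

#' Fit a moment structure by full-information maximum likelihood
#'
#' Maximizes the casewise FIML log-likelihood by `nlminb` with analytic
#' gradients, restarting from the terminal point if the gradient-norm
#' criterion is not met.  Non-convergence is reported, never silently
#' accepted: `converged` requires the scaled gradient norm below tolerance
#' and a positive-definite observed information matrix.
#'
#' @param structure a [moment_structure()]
#' @param data an [missing_pattern_data()] object (columns must match the
#'   structure's manifest variables)
#' @param start optional start values (default: packed from the structure)
#' @param se `"robust"` (Huber-White sandwich, also computes naive),
#'   `"naive"` (inverse observed information) or `"none"`
#' @param h1 `TRUE` to compute the saturated (EM) and baseline
#'   (independence) log-likelihoods and derive chi-square, TLI and RMSEA;
#'   alternatively a precomputed list with elements `sat` and `base`
#'   (useful when several models share one data set); `FALSE` for none
#' @param control list overriding `grad_tol`, `rel_tol`, `iter_max`,
#'   `restarts`
#' @return object of class `sem_fit`
#' @export
fit_sem <- function(structure, data, start = NULL,
                    se = c("robust", "naive", "none"), h1 = FALSE,
                    control = list()) {
  se <- match.arg(se)
  ctrl <- default_fit_control(control)
  stopifnot(inherits(structure, "moment_structure"), inherits(data, "mpd"))
  if (data$p != length(structure$nu))
    stop("data has ", data$p, " variables; structure expects ",
         length(structure$nu))
  q <- structure$n_free
  n <- data$n
  n_mom <- mpd_n_moments(data)
  if (n_mom - q < 0)
    stop("model has ", q, " free parameters but only ", n_mom,
         " sample moments (df would be negative)")
  if (is.null(start)) start <- ms_pack(structure)

  obj <- function(theta) {
    mats <- ms_apply(structure, theta)
    mu <- drop(mats$nu + mats$Lambda %*% mats$alpha)
    Sigma <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda) + mats$Theta
    ll <- fiml_loglik(data, mu, Sigma)
    if (!is.finite(ll)) return(1e10 + sum(theta^2))
    -ll / n
  }
  grd <- function(theta) {
    g <- fiml_grad(structure, theta, data)
    if (anyNA(g)) return(2 * theta)   # infeasible-point penalty gradient
    -g / n
  }

  opt <- stats::nlminb(start, obj, grd,
                       control = list(iter.max = ctrl$iter_max,
                                      eval.max = 4 * ctrl$iter_max,
                                      rel.tol = ctrl$rel_tol))
  tries <- 0
  while (max(abs(grd(opt$par))) > ctrl$grad_tol && tries < ctrl$restarts) {
    tries <- tries + 1
    ## polish with BFGS, then hand back to nlminb if it improved
    pol <- stats::optim(opt$par, obj, grd, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    cand <- if (pol$value <= opt$objective)
      list(par = pol$par, objective = pol$value,
           iterations = opt$iterations, message = "BFGS polish")
    else opt
    opt2 <- stats::nlminb(cand$par, obj, grd,
                          control = list(iter.max = ctrl$iter_max,
                                         eval.max = 4 * ctrl$iter_max,
                                         rel.tol = ctrl$rel_tol))
    if (opt2$objective <= cand$objective) opt <- opt2
    else { opt <- cand; break }
  }
  theta <- opt$par
  names(theta) <- structure$par_names
  loglik <- -opt$objective * n
  grad_norm <- max(abs(grd(theta)))

  fit <- list(structure = structure, theta = theta,
              par_names = structure$par_names,
              loglik = loglik, n_params = q, n_cases = n,
              aic = -2 * loglik + 2 * q,
              grad_norm = grad_norm,
              opt = list(iterations = opt$iterations,
                         message = opt$message, restarts = tries),
              mats = ms_apply(structure, theta))
  class(fit) <- "sem_fit"

  info_pd <- NA
  if (se != "none") {
    H <- num_hess(grd, theta, h = ctrl$hess_step)   # Hessian of -loglik/n
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    info_pd <- all(ev > 0)
    Vn <- tryCatch(solve(H) / n, error = function(e) NULL)
    if (!is.null(Vn)) {
      fit$vcov_naive <- Vn
      fit$se_naive <- sqrt(pmax(diag(Vn), 0))
      names(fit$se_naive) <- structure$par_names
    }
    if (se == "robust") {
      sw <- sandwich_se(structure, data, theta, A = n * H)
      fit$se_robust <- sw$se
      fit$vcov_robust <- sw$vcov
      fit$info_condition <- sw$condition
    }
  }
  fit$info_pd <- info_pd
  fit$converged <- grad_norm < ctrl$grad_tol &&
    (is.na(info_pd) || isTRUE(info_pd))

  if (isTRUE(h1) || is.list(h1)) {
    if (isTRUE(h1))
      h1 <- list(sat = saturated_loglik(data), base = baseline_loglik(data))
    fit$sat_loglik <- as.numeric(h1$sat)
    fit$baseline_loglik <- as.numeric(h1$base)
    fit$chi2 <- max(0, 2 * (fit$sat_loglik - loglik))
    fit$df <- n_mom - q
    fit$chi2_baseline <- max(0, 2 * (fit$sat_loglik - fit$baseline_loglik))
    fit$df_baseline <- n_mom - 2 * data$p
    idx <- fit_indices(fit$chi2, fit$df, fit$chi2_baseline,
                       fit$df_baseline, n)
    fit$tli <- idx$tli
    fit$rmsea <- idx$rmsea
    fit$rmsea_ci <- idx$rmsea_ci
  }
  ## lightweight fingerprint so model comparisons can verify identical data
  fit$data_checksum <- c(n = n, p = data$p,
                         total = sum(vapply(data$patterns,
                                            function(g) g$n * sum(g$ybar),
                                            numeric(1))))
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("FIML fit:", x$n_cases, "cases,", x$n_params, "free parameters\n")
  cat(sprintf("  logLik = %.3f   AIC = %.1f   converged: %s (|grad| = %.2e)\n",
              x$loglik, x$aic, x$converged, x$grad_norm))
  if (!is.null(x$chi2))
    cat(sprintf("  Chi2(%d) = %.1f   TLI = %.3f   RMSEA = %.3f [%.3f, %.3f]\n",
                x$df, x$chi2, x$tli, x$rmsea,
                x$rmsea_ci[1], x$rmsea_ci[2]))
  invisible(x)
}

#' Huber-White sandwich standard errors
#'
#' Robust covariance `A^{-1} B A^{-1}` of the ML estimates, with `A` the
#' negative Hessian of the total log-likelihood (numerical derivative of
#' the analytic gradient) and `B` the sum of casewise score outer products.
#'
#' @param structure a [moment_structure()]
#' @param data an [missing_pattern_data()] object
#' @param theta_hat converged parameter estimates
#' @param A optional precomputed negative Hessian of the total
#'   log-likelihood (q x q)
#' @param B optional replacement for the score outer-product matrix;
#'   supplying `B = A` reproduces the naive covariance exactly
#' @return list with `se`, `vcov`, `A`, `B`, `condition` (condition number
#'   of `A`)
#' @export
sandwich_se <- function(structure, data, theta_hat, A = NULL, B = NULL) {
  n <- data$n
  if (is.null(A)) {
    grd <- function(theta) -fiml_grad(structure, theta, data) / n
    A <- n * num_hess(grd, theta_hat, h = 1e-4)
  }
  if (is.null(B)) {
    S <- fiml_casewise_scores(structure, theta_hat, data)
    B <- crossprod(S)
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  condition <- max(abs(ev)) / max(min(abs(ev)), .Machine$double.eps)
  singular <- condition > 1e12
  if (singular)
    warning("sandwich A-matrix is near-singular (condition number ",
            format(condition, digits = 3),
            "); robust SEs use a pseudo-inverse and should be distrusted")
  Ainv <- if (singular) MASS::ginv(A) else solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- structure$par_names
  list(se = se, vcov = V, A = A, B = B, condition = condition,
       singular = singular)
}

#' Likelihood-based fit indices
#'
#' Tucker-Lewis index, RMSEA with a 95 percent confidence interval obtained
#' by inverting the noncentral chi-square distribution, and the AIC inputs.
#' RMSEA uses the number of analysis cases `n` in the denominator.
#'
#' @param chi2,df model chi-square and degrees of freedom
#' @param chi2_baseline,df_baseline baseline (independence) model chi-square
#'   and degrees of freedom
#' @param n_cases number of analysis cases
#' @param ci_level confidence level for the RMSEA interval
#' @return list with `tli`, `rmsea`, `rmsea_ci`
#' @export
fit_indices <- function(chi2, df, chi2_baseline, df_baseline, n_cases,
                        ci_level = 0.95) {
  stopifnot(df > 0, df_baseline > 0)
  rb <- chi2_baseline / df_baseline
  rm_ <- chi2 / df
  if (rb <= 1) {
    warning("baseline fits no worse than chi2/df = 1; TLI capped at 1")
    tli <- 1
  } else tli <- (rb - rm_) / (rb - 1)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * n_cases))
  a <- (1 - ci_level) / 2
  ncp_for <- function(prob) {
    ## largest ncp with P(X2_df(ncp) <= chi2) >= prob (decreasing in ncp)
    if (stats::pchisq(chi2, df, ncp = 0) < prob) return(0)
    hi <- max(chi2, 1)
    while (stats::pchisq(chi2, df, ncp = hi) > prob) hi <- hi * 2
    stats::uniroot(function(l) stats::pchisq(chi2, df, ncp = l) - prob,
                   c(0, hi), tol = 1e-8)$root
  }
  lam_lo <- ncp_for(1 - a)   # e.g. .975
  lam_hi <- ncp_for(a)       # e.g. .025
  ci <- sqrt(c(lam_lo, lam_hi) / (df * n_cases))
  list(tli = tli, rmsea = rmsea, rmsea_ci = ci)
}

## ---- natural-scale parameter reporting -----------------------------------

## recipe of interpretable quantities as functions of the realized matrices
natural_recipe <- function(ms) {
  ln <- ms$latent_names %||% paste0("eta", seq_len(ncol(ms$Lambda)))
  mn <- ms$manifest_names %||% paste0("y", seq_len(length(ms$nu)))
  rec <- list()
  add <- function(name, type, fn) rec[[length(rec) + 1L]] <<-
    list(name = name, type = type, fn = fn)
  for (j in which(ms$free$alpha > 0))
    local({ jj <- j
      add(paste0("mean(", ln[jj], ")"), "mean",
          function(m) m$alpha[jj]) })
  m <- ncol(ms$Lambda)
  free_psi_cell <- function(i, j) {
    if (ms$psi_mode == "cellwise") return(ms$free$Psi[i, j] > 0)
    ## chol: within-block cells are free
    any(vapply(ms$psi_blocks, function(bl) i %in% bl && j %in% bl, logical(1)))
  }
  for (j in seq_len(m)) if (free_psi_cell(j, j))
    local({ jj <- j
      add(paste0("var(", ln[jj], ")"), "variance",
          function(mm) mm$Psi[jj, jj]) })
  if (m >= 2) for (j in seq_len(m - 1)) for (i in (j + 1):m)
    if (free_psi_cell(i, j))
      local({ ii <- i; jj <- j
        add(paste0("cor(", ln[jj], ",", ln[ii], ")"), "correlation",
            function(mm) mm$Psi[ii, jj] /
              sqrt(mm$Psi[ii, ii] * mm$Psi[jj, jj])) })
  ## residual classes (one entry per distinct Theta equality class)
  seen <- integer(0)
  for (k in seq_len(ms$n_map)) {
    cls <- ms$classes[[k]]
    if (!is.null(cls$Theta) && !(k %in% seen)) {
      seen <- c(seen, k)
      ij <- cls$Theta[1, ]
      if (ij[1] == ij[2]) {
        nm <- if (nrow(cls$Theta) > 1) paste0("resid_var(class", k, ")")
              else paste0("resid_var(", mn[ij[1]], ")")
        local({ i1 <- ij[1]
          add(nm, "variance", function(mm) mm$Theta[i1, i1]) })
      } else {
        local({ i1 <- ij[1]; j1 <- ij[2]
          add("resid_cov", "covariance", function(mm) mm$Theta[i1, j1])
          add("resid_cor", "correlation",
              function(mm) mm$Theta[i1, j1] /
                sqrt(mm$Theta[i1, i1] * mm$Theta[j1, j1])) })
      }
    }
    if (!is.null(cls$Lambda)) {
      ij <- cls$Lambda[1, ]
      local({ i1 <- ij[1]; j1 <- ij[2]; kk <- k
        add(paste0("loading(", mn[i1], "->", ln[j1], ")"), "loading",
            function(mm) mm$Lambda[i1, j1]) })
    }
    if (!is.null(cls$nu)) {
      i1 <- cls$nu[1, 1]
      local({ ii <- i1
        add(paste0("intercept(", mn[ii], ")"), "intercept",
            function(mm) mm$nu[ii]) })
    }
  }
  rec
}

#' Interpretable parameter table with delta-method standard errors
#'
#' Maps the fitted unconstrained parameters to natural quantities (latent
#' means, variances, correlations, residual variances/covariance, free
#' loadings and intercepts) and propagates the naive and robust covariance
#' by the delta method.  Two-sided Wald p-values use the robust standard
#' errors when available.
#'
#' @param fit a [fit_sem()] result
#' @param alpha significance threshold used for the `sig` flag column
#' @return data frame with columns `parameter`, `type`, `estimate`,
#'   `se_naive`, `se_robust`, `z`, `p`, `sig`
#' @export
natural_params <- function(fit, alpha = 0.005) {
  ms <- fit$structure
  rec <- natural_recipe(ms)
  g <- function(theta) {
    mm <- ms_apply(ms, theta)
    vapply(rec, function(r) r$fn(mm), numeric(1))
  }
  est <- g(fit$theta)
  out <- data.frame(parameter = vapply(rec, `[[`, "", "name"),
                    type = vapply(rec, `[[`, "", "type"),
                    estimate = est, stringsAsFactors = FALSE)
  J <- NULL
  if (!is.null(fit$vcov_naive) || !is.null(fit$vcov_robust)) {
    q <- length(fit$theta)
    J <- matrix(0, length(est), q)
    for (i in seq_len(q)) {
      h <- 1e-6 * (1 + abs(fit$theta[i]))
      tp <- fit$theta; tp[i] <- tp[i] + h
      tm <- fit$theta; tm[i] <- tm[i] - h
      J[, i] <- (g(tp) - g(tm)) / (2 * h)
    }
  }
  if (!is.null(fit$vcov_naive) && !is.null(J))
    out$se_naive <- sqrt(pmax(diag(J %*% fit$vcov_naive %*% t(J)), 0))
  if (!is.null(fit$vcov_robust) && !is.null(J)) {
    out$se_robust <- sqrt(pmax(diag(J %*% fit$vcov_robust %*% t(J)), 0))
    out$z <- out$estimate / out$se_robust
    out$p <- 2 * stats::pnorm(-abs(out$z))
    out$sig <- stars_at(out$p, alpha)
  }
  rownames(out) <- NULL
  out
}

## ---- JSON (de)serialization ----------------------------------------------

#' Serialize a moment structure to JSON
#'
#' @param ms a [moment_structure()]
#' @param path optional file to write to
#' @return JSON string (invisibly, if `path` given)
#' @export
ms_to_json <- function(ms, path = NULL) {
  obj <- list(nu = ms$nu, Lambda = ms$Lambda, alpha = ms$alpha,
              Psi = ms$Psi, Theta = ms$Theta,
              free = ms$free, psi_mode = ms$psi_mode,
              psi_blocks = ms$psi_blocks,
              par_names = ms$par_names[seq_len(ms$n_map)],
              manifest_names = ms$manifest_names,
              latent_names = ms$latent_names)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Rebuild a moment structure from JSON
#'
#' @param json JSON string or path to a file written by [ms_to_json()]
#' @return a [moment_structure()]
#' @export
ms_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  dressed <- function(M, nm) {
    M <- as.matrix(M)
    dimnames(M) <- list(nm$r, nm$c)
    M
  }
  Lambda <- dressed(obj$Lambda, list(r = obj$manifest_names,
                                     c = obj$latent_names))
  Psi <- dressed(obj$Psi, list(r = obj$latent_names, c = obj$latent_names))
  Theta <- dressed(obj$Theta, list(r = obj$manifest_names,
                                   c = obj$manifest_names))
  free <- lapply(obj$free, function(x)
    if (is.matrix(x) || is.data.frame(x)) {
      x <- as.matrix(x); storage.mode(x) <- "integer"; x
    } else as.integer(x))
  nu <- stats::setNames(obj$nu, obj$manifest_names)
  blocks <- if (is.null(obj$psi_blocks)) NULL else
    lapply(if (is.list(obj$psi_blocks)) obj$psi_blocks
           else asplit(obj$psi_blocks, 1), as.integer)
  moment_structure(nu, Lambda, stats::setNames(obj$alpha, obj$latent_names),
                   Psi, Theta, free, psi_mode = obj$psi_mode,
                   psi_blocks = blocks, par_names = obj$par_names)
}

#' Serialize the scalar results of a fit to JSON
#'
#' @param fit a [fit_sem()] result
#' @param path optional file to write to
#' @return JSON string
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(loglik = fit$loglik, n_params = fit$n_params,
              n_cases = fit$n_cases, aic = fit$aic,
              converged = fit$converged, grad_norm = fit$grad_norm,
              chi2 = fit$chi2, df = fit$df, tli = fit$tli,
              rmsea = fit$rmsea, rmsea_ci = fit$rmsea_ci,
              estimates = as.list(stats::setNames(as.numeric(fit$theta),
                                                  fit$par_names)),
              se_robust = if (!is.null(fit$se_robust))
                as.list(stats::setNames(as.numeric(fit$se_robust),
                                        fit$par_names)))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
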