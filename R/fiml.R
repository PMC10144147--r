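## Casewise full-information maximum likelihood for multivariate normal data
## with arbitrary missingness.  Cases are grouped by missing-data pattern so
## each pattern's sub-covariance is factorized once per evaluation.

#' Group observations by missing-data pattern
#'
#' Prepares a data matrix for FIML evaluation: rows are grouped by their
#' pattern of observed variables and pattern-level sufficient statistics
#' (case count, mean vector, ML covariance of the observed block) are
#' precomputed.  Rows with no observed values and columns never observed
#' are excluded with logged counts.
#'
#' @param Y numeric matrix or data frame, `NA` = missing
#' @param ids optional case identifiers (kept per pattern)
#' @return object of class `mpd` with elements `patterns` (list of
#'   `obs` index set, `n`, `ybar`, `S`, `Y`, `rows`), `p`, `n`,
#'   `var_names`, `n_dropped_cases`, `dropped_vars`
#' @export
missing_pattern_data <- function(Y, ids = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) colnames(Y) <- paste0("V", seq_len(ncol(Y)))
  obs <- !is.na(Y)
  dropped_vars <- colnames(Y)[colSums(obs) == 0]
  if (length(dropped_vars)) {
    keep <- colSums(obs) > 0
    Y <- Y[, keep, drop = FALSE]
    obs <- obs[, keep, drop = FALSE]
  }
  all_miss <- rowSums(obs) == 0
  n_dropped <- sum(all_miss)
  if (n_dropped) {
    Y <- Y[!all_miss, , drop = FALSE]
    obs <- obs[!all_miss, , drop = FALSE]
    if (!is.null(ids)) ids <- ids[!all_miss]
  }
  key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  patterns <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    o <- which(obs[rows[1], ])
    Yo <- Y[rows, o, drop = FALSE]
    n <- length(rows)
    ybar <- colMeans(Yo)
    C <- sweep(Yo, 2, ybar)
    list(obs = o, n = n, ybar = ybar, S = crossprod(C) / n, Y = Yo,
         rows = rows, ids = if (!is.null(ids)) ids[rows] else NULL)
  })
  structure(list(patterns = unname(patterns), p = ncol(Y), n = nrow(Y),
                 var_names = colnames(Y), n_dropped_cases = n_dropped,
                 dropped_vars = dropped_vars),
            class = "mpd")
}

#' @export
print.mpd <- function(x, ...) {
  cat("FIML data:", x$n, "cases,", x$p, "variables,",
      length(x$patterns), "missing-data patterns\n")
  if (x$n_dropped_cases)
    cat("  (", x$n_dropped_cases, "all-missing cases excluded )\n")
  invisible(x)
}

## number of distinct first- and second-order sample moments
mpd_n_moments <- function(data) data$p + data$p * (data$p + 1) / 2

#' Casewise FIML log-likelihood at given moments
#'
#' Sum over cases of the log multivariate normal density of each case's
#' observed sub-vector under the corresponding sub-vector/sub-matrix of
#' `mu` and `Sigma`.
#'
#' @param data an [missing_pattern_data()] object
#' @param mu mean vector (length `data$p`)
#' @param Sigma covariance matrix
#' @param casewise if `TRUE` also return per-case contributions (aligned
#'   with the retained case order of `data`)
#' @return the scalar log-likelihood (`-Inf` with attribute
#'   `infeasible = TRUE` if some observed sub-matrix is not positive
#'   definite); with `casewise = TRUE`, a list `loglik`, `casewise`
#' @export
fiml_loglik <- function(data, mu, Sigma, casewise = FALSE) {
  stopifnot(inherits(data, "mpd"))
  ll <- 0
  cw <- if (casewise) numeric(data$n) else NULL
  for (pat in data$patterns) {
    o <- pat$obs
    ci <- chol_inverse(Sigma[o, o, drop = FALSE])
    if (is.null(ci)) {
      out <- -Inf; attr(out, "infeasible") <- TRUE
      return(if (casewise) list(loglik = out, casewise = NULL) else out)
    }
    d <- pat$ybar - mu[o]
    po <- length(o)
    if (casewise) {
      C <- sweep(pat$Y, 2, mu[o])
      quad <- rowSums((C %*% ci$inv) * C)
      contrib <- -0.5 * (po * log(2 * pi) + ci$logdet + quad)
      cw[pat$rows] <- contrib
      ll <- ll + sum(contrib)
    } else {
      trace <- sum(ci$inv * pat$S)
      quad <- drop(t(d) %*% ci$inv %*% d)
      ll <- ll + -0.5 * pat$n * (po * log(2 * pi) + ci$logdet + trace + quad)
    }
  }
  if (casewise) list(loglik = ll, casewise = cw) else ll
}

## gradient of the total FIML log-likelihood with respect to the free
## parameters of `ms`, via aggregated d(loglik)/d(mu), d(loglik)/d(Sigma)
fiml_grad <- function(ms, theta, data, mats = ms_apply(ms, theta)) {
  p <- data$p
  mu <- drop(mats$nu + mats$Lambda %*% mats$alpha)
  Sigma <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda) + mats$Theta
  gmu <- numeric(p)
  G <- matrix(0, p, p)
  for (pat in data$patterns) {
    o <- pat$obs
    ci <- chol_inverse(Sigma[o, o, drop = FALSE])
    if (is.null(ci)) return(rep(NA_real_, ms$n_free))
    W <- ci$inv
    d <- pat$ybar - mu[o]
    Wd <- drop(W %*% d)
    gmu[o] <- gmu[o] + pat$n * Wd
    M <- W %*% (pat$S + tcrossprod(d)) %*% W - W
    G[o, o] <- G[o, o] + 0.5 * pat$n * M
  }
  derivs <- ms_dmoments(ms, theta, mats)
  vapply(derivs, function(dk) {
    g <- 0
    if (!is.null(dk$dmu)) g <- g + sum(gmu * dk$dmu)
    if (!is.null(dk$dSigma)) g <- g + sum(G * dk$dSigma)
    g
  }, numeric(1))
}

## n x q matrix of casewise score vectors (gradients of per-case loglik)
fiml_casewise_scores <- function(ms, theta, data, mats = ms_apply(ms, theta)) {
  mu <- drop(mats$nu + mats$Lambda %*% mats$alpha)
  Sigma <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda) + mats$Theta
  derivs <- ms_dmoments(ms, theta, mats)
  q <- ms$n_free
  S <- matrix(0, data$n, q)
  for (pat in data$patterns) {
    o <- pat$obs
    W <- chol_inverse(Sigma[o, o, drop = FALSE])$inv
    C <- sweep(pat$Y, 2, mu[o])
    U <- C %*% W
    for (k in seq_len(q)) {
      dk <- derivs[[k]]
      val <- 0
      if (!is.null(dk$dmu)) val <- val + drop(U %*% dk$dmu[o])
      if (!is.null(dk$dSigma)) {
        D <- dk$dSigma[o, o, drop = FALSE]
        val <- val + 0.5 * (rowSums((U %*% D) * U) - sum(W * D))
      }
      S[pat$rows, k] <- S[pat$rows, k] + val
    }
  }
  colnames(S) <- ms$par_names
  S
}

#' Saturated (unrestricted) FIML log-likelihood via EM
#'
#' Maximizes the multivariate-normal log-likelihood over unrestricted
#' `(mu, Sigma)` with missing data by the standard EM algorithm on
#' pattern-level sufficient statistics.  The value anchors the likelihood
#' ratio chi-square of every fitted model.
#'
#' @param data an [missing_pattern_data()] object
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter iteration cap
#' @return the maximized log-likelihood (numeric scalar) with attributes
#'   `mu`, `Sigma`, `iterations`, `converged`
#' @export
saturated_loglik <- function(data, tol = 1e-9, max_iter = 5000) {
  p <- data$p; n <- data$n
  ## run the EM on internally standardized columns: numerically better
  ## conditioned, and the EM path becomes exactly equivariant under
  ## per-column affine rescaling of the input (the log-Jacobian is added
  ## back at the end)
  cnt0 <- numeric(p); m1 <- numeric(p); m2 <- numeric(p)
  for (pat in data$patterns) {
    o <- pat$obs
    cnt0[o] <- cnt0[o] + pat$n
    m1[o] <- m1[o] + pat$n * pat$ybar
    m2[o] <- m2[o] + pat$n * (diag(pat$S) + pat$ybar^2)
  }
  cm <- m1 / cnt0
  cs <- sqrt(pmax(m2 / cnt0 - cm^2, 0))
  cs[!is.finite(cs) | cs <= 0] <- 1
  if (max(abs(cm)) > 1e-10 || max(abs(cs - 1)) > 1e-10) {
    std <- data
    std$patterns <- lapply(data$patterns, function(pat) {
      o <- pat$obs
      pat$ybar <- (pat$ybar - cm[o]) / cs[o]
      pat$S <- pat$S / tcrossprod(cs[o])
      pat$Y <- NULL
      pat
    })
    inner <- saturated_loglik(std, tol = tol, max_iter = max_iter)
    ll <- as.numeric(inner) - sum(cnt0 * log(cs))
    mu <- cm + cs * attr(inner, "mu")
    Sigma <- attr(inner, "Sigma") * tcrossprod(cs)
    names(mu) <- data$var_names
    dimnames(Sigma) <- list(data$var_names, data$var_names)
    return(structure(ll, mu = mu, Sigma = Sigma,
                     iterations = attr(inner, "iterations"),
                     converged = attr(inner, "converged"),
                     ridged = attr(inner, "ridged")))
  }
  ## available-case initialization: diagonal Sigma
  mu <- numeric(p); v <- numeric(p)
  cnt <- numeric(p); s1 <- numeric(p); s2 <- numeric(p)
  for (pat in data$patterns) {
    o <- pat$obs
    cnt[o] <- cnt[o] + pat$n
    s1[o] <- s1[o] + pat$n * pat$ybar
    s2[o] <- s2[o] + pat$n * (diag(pat$S) + pat$ybar^2)
  }
  mu <- s1 / cnt
  v <- s2 / cnt - mu^2
  ## columns observed fewer than twice carry no variance information:
  ## start them at the average spread of the informative columns
  weak <- cnt < 2 | v <= 1e-8
  if (all(weak)) stop("no variable has two or more observations")
  v[weak] <- mean(v[!weak])
  ## pairwise-complete covariance start (shrunk toward its diagonal until
  ## positive definite) cuts the EM iteration count substantially
  cnt2 <- matrix(0, p, p)
  sxy <- matrix(0, p, p)
  sx <- matrix(0, p, p)
  sy <- matrix(0, p, p)
  for (pat in data$patterns) {
    o <- pat$obs
    cnt2[o, o] <- cnt2[o, o] + pat$n
    M2 <- pat$n * (pat$S + tcrossprod(pat$ybar))
    sxy[o, o] <- sxy[o, o] + M2
    sx[o, o] <- sx[o, o] + pat$n * matrix(pat$ybar, length(o), length(o))
    sy[o, o] <- sy[o, o] + pat$n * matrix(pat$ybar, length(o), length(o),
                                          byrow = TRUE)
  }
  Sigma <- matrix(0, p, p)
  ok <- cnt2 >= 2
  Sigma[ok] <- (sxy[ok] - sx[ok] * sy[ok] / cnt2[ok]) / cnt2[ok]
  diag(Sigma) <- v
  w <- 1
  while (is.null(tryCatch(chol(Sigma), error = function(e) NULL)) &&
         w > 1e-4) {
    w <- w / 2
    off <- Sigma - diag(diag(Sigma))
    Sigma <- diag(v, p) + w * off
  }
  if (w <= 1e-4) Sigma <- diag(v, p)
  complete <- length(data$patterns) == 1 &&
    length(data$patterns[[1]]$obs) == p

  em_step <- function(mu, Sigma) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (pat in data$patterns) {
      o <- pat$obs; mi <- setdiff(seq_len(p), o)
      ng <- pat$n
      d <- pat$ybar - mu[o]
      T1[o] <- T1[o] + ng * pat$ybar
      T2[o, o] <- T2[o, o] + ng * (pat$S + tcrossprod(pat$ybar))
      if (length(mi)) {
        Soo <- Sigma[o, o, drop = FALSE]
        ci <- chol_inverse(Soo)
        if (is.null(ci))   # ill-conditioned corner: ridge and push on
          ci <- chol_inverse(Soo + diag(1e-8 + 1e-8 * mean(diag(Soo)),
                                        length(o)))
        W <- ci$inv
        B <- Sigma[mi, o, drop = FALSE] %*% W
        em <- mu[mi] + drop(B %*% d)            # mean of E[y_mis] over cases
        T1[mi] <- T1[mi] + ng * em
        ## cross moment sum_i y_o E[y_m]'
        Com <- ng * tcrossprod(pat$ybar, mu[mi]) +
          ng * (pat$S + tcrossprod(pat$ybar) - tcrossprod(pat$ybar, mu[o])) %*% t(B)
        T2[o, mi] <- T2[o, mi] + Com
        T2[mi, o] <- T2[mi, o] + t(Com)
        ## sum_i E[y_m]E[y_m]' + n * conditional covariance
        Sdd <- pat$S + tcrossprod(d)
        Bd <- drop(B %*% d)
        Emm <- ng * (tcrossprod(mu[mi]) + tcrossprod(mu[mi], Bd) +
                       tcrossprod(Bd, mu[mi]) + B %*% Sdd %*% t(B))
        Cc <- Sigma[mi, mi, drop = FALSE] - B %*% Sigma[o, mi, drop = FALSE]
        T2[mi, mi] <- T2[mi, mi] + Emm + ng * Cc
      }
    }
    mu_new <- T1 / n
    Sigma_new <- T2 / n - tcrossprod(mu_new)
    list(mu = mu_new, Sigma = (Sigma_new + t(Sigma_new)) / 2)
  }

  pack <- function(st) c(st$mu, st$Sigma[upper.tri(st$Sigma, diag = TRUE)])
  unpack <- function(v) {
    mu_ <- v[seq_len(p)]
    S_ <- matrix(0, p, p)
    S_[upper.tri(S_, diag = TRUE)] <- v[-seq_len(p)]
    S_ <- S_ + t(S_) - diag(diag(S_))
    list(mu = mu_, Sigma = S_)
  }
  ## with very sparse columns the saturated likelihood can be unbounded
  ## (a variance observed once drifts to zero); a small floor keeps the
  ## EM defined and is recorded on the result
  var_floor <- 1e-6 * mean(v)
  ridged <- FALSE
  regularize <- function(st) {
    d0 <- diag(st$Sigma)
    if (any(d0 < var_floor)) {
      ridged <<- TRUE
      diag(st$Sigma) <- pmax(d0, var_floor)
    }
    eps <- var_floor
    while (is.null(tryCatch(chol(st$Sigma), error = function(e) NULL)) &&
           eps < 1e6 * var_floor) {
      ridged <<- TRUE
      st$Sigma <- st$Sigma + diag(eps, p)
      eps <- eps * 10
    }
    st
  }
  feasible_ll <- function(st) {
    if (is.null(tryCatch(chol(st$Sigma), error = function(e) NULL)))
      return(-Inf)
    fiml_loglik(data, st$mu, st$Sigma)
  }

  st <- list(mu = mu, Sigma = Sigma)
  ll_old <- -Inf; iter <- 0; converged <- FALSE
  repeat {
    ## SQUAREM-style accelerated cycle: two EM steps plus an extrapolation,
    ## falling back to the plain second step when infeasible or worse
    st1 <- regularize(em_step(st$mu, st$Sigma)); iter <- iter + 1
    st2 <- regularize(em_step(st1$mu, st1$Sigma)); iter <- iter + 1
    t0 <- pack(st); t1 <- pack(st1); t2 <- pack(st2)
    r <- t1 - t0; v <- t2 - t1 - r
    nv <- sqrt(sum(v^2))
    st_new <- st2
    if (nv > 1e-12) {
      a <- -sqrt(sum(r^2)) / nv
      a <- min(a, -1)
      cand <- unpack(t0 - 2 * a * r + a^2 * v)
      if (feasible_ll(cand) >= feasible_ll(st2)) {
        st_new <- regularize(em_step(cand$mu, cand$Sigma)) # stabilizing step
        iter <- iter + 1
      }
    }
    st <- st_new
    ll <- feasible_ll(st)
    if (!is.finite(ll)) stop("saturated EM reached a non-PD covariance")
    if (complete || abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  mu <- st$mu; Sigma <- st$Sigma
  names(mu) <- data$var_names
  dimnames(Sigma) <- list(data$var_names, data$var_names)
  structure(ll, mu = mu, Sigma = Sigma, iterations = iter,
            converged = converged, ridged = ridged)
}

#' Baseline (independence) model log-likelihood
#'
#' FIML log-likelihood of the independence model (free means and variances,
#' all covariances zero).  With a diagonal covariance the casewise likelihood
#' factors over variables, so each variable's ML solution is its observed-case
#' mean and ML variance; no iteration is needed.  Used as the TLI baseline.
#'
#' @param data an [missing_pattern_data()] object
#' @return log-likelihood with attributes `mu`, `sigma2`, `n_params`
#' @export
baseline_loglik <- function(data) {
  p <- data$p
  cnt <- numeric(p); s1 <- numeric(p); s2 <- numeric(p)
  for (pat in data$patterns) {
    o <- pat$obs
    cnt[o] <- cnt[o] + pat$n
    s1[o] <- s1[o] + pat$n * pat$ybar
    s2[o] <- s2[o] + pat$n * (diag(pat$S) + pat$ybar^2)
  }
  mu <- s1 / cnt
  v <- s2 / cnt - mu^2
  ll <- sum(-0.5 * cnt * (log(2 * pi) + log(v) + 1))
  structure(ll, mu = mu, sigma2 = v, n_params = 2 * p)
}
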