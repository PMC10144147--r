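## Linear latent-variable moment structure
##
## Every model in the package (longitudinal factor model, univariate and
## bivariate latent trajectory models, the baseline independence model) is an
## instance of the same structure: manifest intercepts nu, loadings Lambda,
## latent means alpha, latent covariance Psi, residual covariance Theta, with
##   mu    = nu + Lambda alpha
##   Sigma = Lambda Psi Lambda' + Theta.
## Free parameters are identified by integer maps over the matrix cells; cells
## sharing an index form an equality class (one free parameter, many cells).
## Variance cells are optimized on the log-SD scale and a fully (or block-)
## free Psi on the log-Cholesky scale, so the optimizer is unconstrained.

#' Construct a linear latent-variable moment structure
#'
#' @param nu numeric vector of manifest intercepts (length p); fixed values,
#'   free cells hold start values
#' @param Lambda p x m loading matrix (values double as start values)
#' @param alpha latent mean vector (length m)
#' @param Psi m x m latent covariance matrix (symmetric)
#' @param Theta p x p manifest residual covariance matrix (symmetric)
#' @param free list with integer maps `nu`, `Lambda`, `alpha`, `Psi`, `Theta`
#'   of the same shapes; 0 = fixed, a positive integer is a free-parameter
#'   index, repeated indices form an equality class.  `Psi` map is ignored
#'   when `psi_mode = "chol"`.
#' @param psi_mode `"chol"` parameterizes Psi by an unconstrained
#'   log-Cholesky factor per block (guaranteeing positive semidefiniteness);
#'   `"cellwise"` frees individual Psi cells via the map (diagonal cells on
#'   the log-SD scale).
#' @param psi_blocks list of integer vectors partitioning the latent indices
#'   for `psi_mode = "chol"`; covariances across blocks are fixed at zero.
#'   Default: one block containing all latents.
#' @param par_names optional names for the mapped free parameters
#'   (length `max(map indices)`); Cholesky parameters are named automatically.
#' @return an object of class `moment_structure`
#' @export
moment_structure <- function(nu, Lambda, alpha, Psi, Theta, free,
                             psi_mode = c("chol", "cellwise"),
                             psi_blocks = NULL, par_names = NULL) {
  psi_mode <- match.arg(psi_mode)
  Lambda <- as.matrix(Lambda)
  p <- length(nu); m <- ncol(Lambda)
  stopifnot(nrow(Lambda) == p, length(alpha) == m,
            all(dim(Psi) == m), all(dim(Theta) == p))
  if (max(abs(Psi - t(Psi))) > 1e-10) stop("Psi must be symmetric")
  if (max(abs(Theta - t(Theta))) > 1e-10) stop("Theta must be symmetric")
  free$nu <- free$nu %||% integer(p)
  free$alpha <- free$alpha %||% integer(m)
  free$Lambda <- free$Lambda %||% matrix(0L, p, m)
  free$Psi <- free$Psi %||% matrix(0L, m, m)
  free$Theta <- free$Theta %||% matrix(0L, p, p)
  if (psi_mode == "cellwise" && max(abs(free$Psi - t(free$Psi))) > 0)
    stop("free$Psi map must be symmetric")
  if (max(abs(free$Theta - t(free$Theta))) > 0)
    stop("free$Theta map must be symmetric")
  if (psi_mode == "chol") {
    if (is.null(psi_blocks)) psi_blocks <- list(seq_len(m))
    if (!setequal(unlist(psi_blocks), seq_len(m)) ||
        anyDuplicated(unlist(psi_blocks)))
      stop("psi_blocks must partition the latent indices")
    free$Psi <- matrix(0L, m, m)
  } else psi_blocks <- NULL

  K <- max(0L, unlist(free))
  ## per-class cell lists and parameter scales
  classes <- vector("list", K)
  scales <- character(K)
  slots <- c("nu", "Lambda", "alpha", "Psi", "Theta")
  for (k in seq_len(K)) {
    cls <- list()
    variance_cell <- FALSE; other_cell <- FALSE
    for (s in slots) {
      mp <- free[[s]]
      if (is.matrix(mp)) {
        idx <- which(mp == k, arr.ind = TRUE)
        if (s %in% c("Psi", "Theta") && nrow(idx))
          idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]  # upper triangle
      } else {
        w <- which(mp == k)
        idx <- if (length(w)) cbind(w, 1L) else NULL
      }
      if (!is.null(idx) && nrow(idx)) {
        cls[[s]] <- idx
        if (s %in% c("Psi", "Theta")) {
          if (any(idx[, 1] == idx[, 2])) variance_cell <- TRUE
          if (any(idx[, 1] != idx[, 2])) other_cell <- TRUE
        } else other_cell <- TRUE
      }
    }
    if (!length(cls)) stop("free-parameter index ", k, " maps to no cell")
    if (variance_cell && other_cell)
      stop("equality class ", k, " mixes variance and non-variance cells")
    classes[[k]] <- cls
    scales[k] <- if (variance_cell) "logsd" else "raw"
  }
  ## Cholesky parameter bookkeeping
  chol_index <- NULL
  if (psi_mode == "chol") {
    rows <- list()
    for (b in seq_along(psi_blocks)) {
      bl <- psi_blocks[[b]]
      mb <- length(bl)
      for (j in seq_len(mb)) for (i in j:mb)
        rows[[length(rows) + 1L]] <- c(block = b, i = i, j = j)
    }
    chol_index <- do.call(rbind, rows)
  }
  q <- K + if (is.null(chol_index)) 0L else nrow(chol_index)
  if (is.null(par_names))
    par_names <- if (K) paste0("par", seq_len(K)) else character(0)
  if (length(par_names) != K) stop("par_names must have length ", K)
  all_names <- par_names
  if (!is.null(chol_index)) {
    lt <- unlist(lapply(psi_blocks, function(bl) {
      nm <- rownames(Psi)[bl] %||% paste0("eta", bl)
      out <- character(0)
      for (j in seq_along(bl)) for (i in j:length(bl))
        out <- c(out, paste0("psiL[", nm[i], ",", nm[j], "]"))
      out
    }))
    all_names <- c(all_names, lt)
  }
  structure(list(nu = nu, Lambda = Lambda, alpha = alpha, Psi = Psi,
                 Theta = Theta, free = free, psi_mode = psi_mode,
                 psi_blocks = psi_blocks, chol_index = chol_index,
                 classes = classes, scales = scales, n_map = K, n_free = q,
                 par_names = all_names,
                 manifest_names = names(nu) %||% rownames(Lambda),
                 latent_names = colnames(Lambda)),
            class = "moment_structure")
}

#' @export
print.moment_structure <- function(x, ...) {
  cat("Moment structure:", length(x$nu), "manifest,",
      ncol(x$Lambda), "latent,", x$n_free, "free parameters",
      sprintf("(Psi: %s)\n", x$psi_mode))
  invisible(x)
}

## pack: extract start/current parameter vector from the stored matrices
ms_pack <- function(ms) {
  theta <- numeric(ms$n_free)
  for (k in seq_len(ms$n_map)) {
    cls <- ms$classes[[k]]
    s <- names(cls)[1]
    ij <- cls[[s]][1, ]
    val <- if (s %in% c("nu", "alpha")) ms[[s]][ij[1]] else ms[[s]][ij[1], ij[2]]
    theta[k] <- if (ms$scales[k] == "logsd") log(sqrt(val)) else val
  }
  if (!is.null(ms$chol_index)) {
    off <- ms$n_map
    for (b in seq_along(ms$psi_blocks)) {
      bl <- ms$psi_blocks[[b]]
      L <- t(chol(ms$Psi[bl, bl, drop = FALSE]))
      for (r in which(ms$chol_index[, "block"] == b)) {
        i <- ms$chol_index[r, "i"]; j <- ms$chol_index[r, "j"]
        theta[off + r] <- if (i == j) log(L[i, j]) else L[i, j]
      }
    }
  }
  names(theta) <- ms$par_names
  theta
}

## apply theta, returning the realized matrices (and Cholesky factors)
ms_apply <- function(ms, theta) {
  nu <- ms$nu; Lambda <- ms$Lambda; alpha <- ms$alpha
  Psi <- ms$Psi; Theta <- ms$Theta
  for (k in seq_len(ms$n_map)) {
    cls <- ms$classes[[k]]
    for (s in names(cls)) {
      idx <- cls[[s]]
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        v <- theta[k]
        if (s == "nu") nu[i] <- v
        else if (s == "alpha") alpha[i] <- v
        else if (s == "Lambda") Lambda[i, j] <- v
        else if (s == "Psi") {
          val <- if (i == j) exp(2 * v) else v
          Psi[i, j] <- val; Psi[j, i] <- val
        } else {
          val <- if (i == j) exp(2 * v) else v
          Theta[i, j] <- val; Theta[j, i] <- val
        }
      }
    }
  }
  Lfac <- NULL
  if (!is.null(ms$chol_index)) {
    m <- ncol(Lambda)
    Psi <- matrix(0, m, m, dimnames = dimnames(ms$Psi))
    Lfac <- vector("list", length(ms$psi_blocks))
    off <- ms$n_map
    for (b in seq_along(ms$psi_blocks)) {
      bl <- ms$psi_blocks[[b]]
      mb <- length(bl)
      L <- matrix(0, mb, mb)
      for (r in which(ms$chol_index[, "block"] == b)) {
        i <- ms$chol_index[r, "i"]; j <- ms$chol_index[r, "j"]
        L[i, j] <- if (i == j) exp(theta[off + r]) else theta[off + r]
      }
      Lfac[[b]] <- L
      Psi[bl, bl] <- L %*% t(L)
    }
  }
  list(nu = nu, Lambda = Lambda, alpha = alpha, Psi = Psi, Theta = Theta,
       L = Lfac)
}

#' Model-implied mean vector and covariance matrix
#'
#' Applies a free-parameter vector to the structure and returns
#' `mu = nu + Lambda alpha` and `Sigma = Lambda Psi Lambda' + Theta`.
#'
#' @param structure a [moment_structure()]
#' @param theta free-parameter vector (default: values packed from the
#'   structure's stored matrices)
#' @return list with `mu`, `Sigma`, and a logical `pd` flag for whether
#'   Sigma admits a Cholesky factorization
#' @export
implied_moments <- function(structure, theta = ms_pack(structure)) {
  if (length(theta) != structure$n_free)
    stop("theta has length ", length(theta), ", expected ", structure$n_free)
  mats <- ms_apply(structure, theta)
  mu <- drop(mats$nu + mats$Lambda %*% mats$alpha)
  Sigma <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda) + mats$Theta
  Sigma <- (Sigma + t(Sigma)) / 2
  names(mu) <- structure$manifest_names
  dimnames(Sigma) <- list(structure$manifest_names, structure$manifest_names)
  pd <- !is.null(tryCatch(chol(Sigma), error = function(e) NULL))
  list(mu = mu, Sigma = Sigma, pd = pd)
}

## per-parameter derivative structures d(mu)/d(theta_k), d(Sigma)/d(theta_k)
## evaluated at the realized matrices `mats`
ms_dmoments <- function(ms, theta, mats = ms_apply(ms, theta)) {
  p <- length(ms$nu); m <- ncol(ms$Lambda)
  out <- vector("list", ms$n_free)
  LamPsi <- mats$Lambda %*% mats$Psi
  for (k in seq_len(ms$n_map)) {
    cls <- ms$classes[[k]]
    dmu <- NULL; dSigma <- NULL
    for (s in names(cls)) {
      idx <- cls[[s]]
      if (s == "nu") {
        if (is.null(dmu)) dmu <- numeric(p)
        dmu[idx[, 1]] <- dmu[idx[, 1]] + 1
      } else if (s == "alpha") {
        if (is.null(dmu)) dmu <- numeric(p)
        for (r in seq_len(nrow(idx)))
          dmu <- dmu + mats$Lambda[, idx[r, 1]]
      } else if (s == "Lambda") {
        if (is.null(dmu)) dmu <- numeric(p)
        M <- matrix(0, p, m)
        for (r in seq_len(nrow(idx))) {
          i <- idx[r, 1]; j <- idx[r, 2]
          dmu[i] <- dmu[i] + mats$alpha[j]
          M[i, j] <- M[i, j] + 1
        }
        A <- M %*% t(LamPsi)
        dSigma <- (if (is.null(dSigma)) 0 else dSigma) + A + t(A)
      } else if (s == "Psi") {
        dPsi <- matrix(0, m, m)
        for (r in seq_len(nrow(idx))) {
          i <- idx[r, 1]; j <- idx[r, 2]
          if (i == j) dPsi[i, i] <- dPsi[i, i] + 2 * exp(2 * theta[k])
          else { dPsi[i, j] <- dPsi[i, j] + 1; dPsi[j, i] <- dPsi[j, i] + 1 }
        }
        dSigma <- (if (is.null(dSigma)) 0 else dSigma) +
          mats$Lambda %*% dPsi %*% t(mats$Lambda)
      } else { # Theta
        if (is.null(dSigma)) dSigma <- matrix(0, p, p)
        for (r in seq_len(nrow(idx))) {
          i <- idx[r, 1]; j <- idx[r, 2]
          if (i == j) dSigma[i, i] <- dSigma[i, i] + 2 * exp(2 * theta[k])
          else { dSigma[i, j] <- dSigma[i, j] + 1; dSigma[j, i] <- dSigma[j, i] + 1 }
        }
      }
    }
    out[[k]] <- list(dmu = dmu, dSigma = dSigma)
  }
  if (!is.null(ms$chol_index)) {
    off <- ms$n_map
    for (r in seq_len(nrow(ms$chol_index))) {
      b <- ms$chol_index[r, "block"]
      i <- ms$chol_index[r, "i"]; j <- ms$chol_index[r, "j"]
      bl <- ms$psi_blocks[[b]]
      L <- mats$L[[b]]
      dL <- matrix(0, length(bl), length(bl))
      dL[i, j] <- if (i == j) L[i, j] else 1  # log scale on the diagonal
      dPsi_b <- dL %*% t(L) + L %*% t(dL)
      Lam_b <- mats$Lambda[, bl, drop = FALSE]
      out[[off + r]] <- list(dmu = NULL,
                             dSigma = Lam_b %*% dPsi_b %*% t(Lam_b))
    }
  }
  out
}
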