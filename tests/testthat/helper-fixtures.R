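## shared fixtures: small identified structures and simulators built in code

## one-factor model, p indicators, marker scaling (loading 1 fixed),
## intercepts fixed 0, latent mean free
one_factor_structure <- function(lam = c(1, 0.8, 0.6, 0.9), resid = 0.5,
                                 alpha = 0.5) {
  p <- length(lam)
  nm <- paste0("y", seq_len(p))
  free_L <- matrix(0L, p, 1)
  free_L[-1, 1] <- seq_len(p - 1)
  k <- p - 1
  nu_free <- integer(p)
  moment_structure(
    nu = stats::setNames(numeric(p), nm),
    Lambda = matrix(lam, p, 1, dimnames = list(nm, "f")),
    alpha = c(f = alpha),
    Psi = matrix(1, 1, 1, dimnames = list("f", "f")),
    Theta = diag(resid, p),
    free = list(Lambda = free_L, alpha = k + 1L,
                Theta = diag(seq_len(p) + k + 1L)),
    psi_mode = "chol",
    par_names = c(paste0("l", 2:p), "alpha",
                  paste0("theta", seq_len(p))))
}

simulate_one_factor <- function(n, lam = c(1, 0.8, 0.6, 0.9), resid = 0.5,
                                alpha = 0.5, miss = 0, seed = 1) {
  set.seed(seed)
  eta <- stats::rnorm(n, alpha, 1)
  Y <- outer(eta, lam) + matrix(stats::rnorm(n * length(lam), 0, sqrt(resid)),
                                n, length(lam))
  colnames(Y) <- paste0("y", seq_along(lam))
  if (miss > 0) Y[matrix(stats::runif(length(Y)) < miss, nrow(Y))] <- NA
  Y
}

## linear growth structure on 3 complete occasions (decade codes 0, .2, .6):
## latent intercept + slope, free means, free 2x2 covariance, one residual
linear_growth_structure <- function() {
  codes <- c(0, 0.2, 0.6)
  nm <- paste0("t", seq_along(codes))
  Lambda <- cbind(i = 1, s = codes)
  rownames(Lambda) <- nm
  Theta_free <- matrix(0L, 3, 3)
  diag(Theta_free) <- 3L          # one homogeneous residual class
  moment_structure(
    nu = stats::setNames(numeric(3), nm),
    Lambda = Lambda,
    alpha = c(i = 0.5, s = -0.2),
    Psi = matrix(c(0.5, 0.05, 0.05, 0.1), 2, 2,
                 dimnames = list(c("i", "s"), c("i", "s"))),
    Theta = diag(0.09, 3),
    free = list(alpha = c(1L, 2L), Theta = Theta_free),
    psi_mode = "chol",
    par_names = c("alpha(i)", "alpha(s)", "resid"))
}

simulate_linear_growth <- function(n, seed) {
  set.seed(seed)
  b <- MASS::mvrnorm(n, c(0.5, -0.2),
                     matrix(c(0.5, 0.05, 0.05, 0.1), 2, 2))
  codes <- c(0, 0.2, 0.6)
  Y <- b[, 1] + outer(b[, 2], codes) +
    matrix(stats::rnorm(3 * n, 0, 0.3), n, 3)
  colnames(Y) <- paste0("t", 1:3)
  Y
}

## trivariate normal log-density by an explicit formula (independent path
## from the package's Cholesky-based evaluation)
dmvnorm_log_direct <- function(y, mu, Sigma) {
  d <- y - mu
  -0.5 * (length(y) * log(2 * pi) + log(det(Sigma)) +
            drop(t(d) %*% solve(Sigma) %*% d))
}

## all-continuous measurement configuration whose marker loading is 1, so
## the factor metric equals the generating latent metric exactly
continuous_measurement <- function() {
  measurement_config(data.frame(
    item = c("c1", "c2", "c3", "c4", "f1", "f2", "f3"),
    process = c("COG", "COG", "COG", "COG", "FNC", "FNC", "FNC"),
    lambda = c(1, 0.8, 0.7, 0.6, 1, 0.9, 0.6),
    nu = c(0, 0, 0, 0, 0, 0, 0),
    theta = c(0.5, 0.6, 0.7, 0.8, 0.5, 0.6, 0.7),
    type = "continuous", min = -Inf, max = Inf,
    marker = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE))
}

## quick accessors
est_of <- function(fit, name) unname(fit$theta[name])
nat_of <- function(np, name) np$estimate[np$parameter == name]
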