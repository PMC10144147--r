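#' Central-difference gradient
#'
#' Plain central-difference numerical gradient, used as an independent
#' oracle for the analytic FIML derivatives and as a fallback when a
#' structure has no analytic gradient.
#'
#' @param f scalar function of a numeric vector
#' @param x point at which to differentiate
#' @param h step size (scaled per coordinate by `1 + |x_i|`)
#' @return numeric gradient vector
#' @export
num_grad <- function(f, x, h = 1e-5) {
  q <- length(x)
  g <- numeric(q)
  for (i in seq_len(q)) {
    hi <- h * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

#' Central-difference Hessian
#'
#' Numerical Hessian obtained by central differences of a gradient
#' function (analytic if available), symmetrized.
#'
#' @param gr gradient function of a numeric vector
#' @param x point at which to differentiate
#' @param h step size (scaled per coordinate)
#' @return symmetric `length(x)` x `length(x)` matrix
#' @export
num_hess <- function(gr, x, h = 1e-5) {
  q <- length(x)
  H <- matrix(0, q, q)
  for (i in seq_len(q)) {
    hi <- h * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    H[, i] <- (gr(xp) - gr(xm)) / (2 * hi)
  }
  (H + t(H)) / 2
}

## symmetric PD solve via Cholesky; returns NULL on failure instead of erroring
chol_inverse <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  list(inv = chol2inv(R), logdet = 2 * sum(log(diag(R))))
}

## draw from N(mu, Sigma); thin wrapper so all simulation goes through one door
rmvnorm_draw <- function(n, mu, Sigma) {
  k <- length(mu)
  if (all(Sigma == 0)) {
    return(matrix(mu, n, k, byrow = TRUE, dimnames = list(NULL, names(mu))))
  }
  out <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  if (n == 1) out <- matrix(out, 1, k)
  colnames(out) <- names(mu)
  out
}

## truncated-normal draws by inverse-CDF (exact, vectorized)
rtruncnorm_draw <- function(n, mean, sd, lower, upper) {
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  u <- stats::runif(n, a, b)
  mean + sd * stats::qnorm(u)
}

## sample skewness (b1), used by the generator's calibration checks
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stars_at <- function(p, alpha = 0.005) ifelse(!is.na(p) & p < alpha, "*", "")
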