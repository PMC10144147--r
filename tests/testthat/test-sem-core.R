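## FIML engine: implied moments, casewise likelihood, gradients, fitting,
## saturated EM, robust standard errors, and fit indices.

test_that("implied moments follow the linear factor algebra", {
  ## identity loading, standard-normal latents, no residuals
  ms <- moment_structure(nu = numeric(2), Lambda = diag(2),
                         alpha = numeric(2), Psi = diag(2),
                         Theta = matrix(0, 2, 2), free = list(),
                         psi_mode = "cellwise")
  im <- implied_moments(ms, numeric(0))
  expect_equal(unname(im$mu), c(0, 0))
  expect_equal(unname(im$Sigma), diag(2))

  ## one factor, Lambda = (1,1)', alpha = 2, Theta = .5 I
  ms2 <- moment_structure(nu = numeric(2), Lambda = matrix(1, 2, 1),
                          alpha = 2, Psi = matrix(1, 1, 1),
                          Theta = diag(0.5, 2), free = list(),
                          psi_mode = "cellwise")
  im2 <- implied_moments(ms2, numeric(0))
  expect_equal(unname(im2$mu), c(2, 2))
  expect_equal(unname(im2$Sigma), matrix(c(1.5, 1, 1, 1.5), 2, 2))
})

test_that("implied moments match a large simulation from the same system", {
  set.seed(31)
  lam <- c(1, 0.7, 0.4)
  ms <- moment_structure(nu = c(0.3, -0.1, 0.2),
                         Lambda = matrix(lam, 3, 1), alpha = 1.2,
                         Psi = matrix(0.8, 1, 1), Theta = diag(c(.4, .3, .5)),
                         free = list(), psi_mode = "cellwise")
  im <- implied_moments(ms, numeric(0))
  n <- 2e5
  eta <- rnorm(n, 1.2, sqrt(0.8))
  Y <- cbind(0.3, -0.1, 0.2)[rep(1, n), ] + outer(eta, lam) +
    matrix(rnorm(3 * n), n, 3) %*% diag(sqrt(c(.4, .3, .5)))
  expect_equal(unname(im$mu), unname(colMeans(Y)), tolerance = 0.02)
  expect_equal(unname(im$Sigma), unname(cov(Y)), tolerance = 0.02)
})

test_that("FIML reduces to complete-data ML and handles single variables", {
  set.seed(7)
  Y <- simulate_one_factor(200)
  d <- missing_pattern_data(Y)
  mu <- colMeans(Y) + 0.1
  Sigma <- cov(Y) + diag(0.05, 4)
  ll <- fiml_loglik(d, mu, Sigma)
  direct <- sum(apply(Y, 1, dmvnorm_log_direct, mu = mu, Sigma = Sigma))
  expect_equal(ll, direct, tolerance = 1e-10)

  ## univariate pattern at its mean with unit variance: -log(2*pi)/2
  d1 <- missing_pattern_data(matrix(0, 1, 1))
  expect_equal(fiml_loglik(d1, 0, matrix(1, 1, 1)), -0.5 * log(2 * pi))
})

test_that("a partially observed case equals the integrated density", {
  set.seed(11)
  A <- matrix(rnorm(9), 3)
  Sigma <- crossprod(A) + diag(0.5, 3)
  mu <- c(0.4, -0.2, 1)
  y <- c(0.9, NA, 1.7)
  y2 <- c(0, 0.5, 1)                  # complete companion case
  Y <- rbind(y, y2)
  colnames(Y) <- paste0("v", 1:3)
  d <- missing_pattern_data(Y)
  ll <- fiml_loglik(d, mu, Sigma) - dmvnorm_log_direct(y2, mu, Sigma)
  marg <- stats::integrate(function(t)
    vapply(t, function(ti)
      exp(dmvnorm_log_direct(c(y[1], ti, y[3]), mu, Sigma)), numeric(1)),
    -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(ll, log(marg), tolerance = 1e-6)
})

test_that("analytic gradients and scores match central differences on a toy", {
  set.seed(5)
  ms <- one_factor_structure()
  Y <- simulate_one_factor(5, miss = 0.2, seed = 5)
  Y[1, 1] <- NA  # make sure several patterns exist
  d <- missing_pattern_data(Y)
  th <- ms_pack(ms) + 0.05
  f <- function(t) {
    m <- implied_moments(ms, t)
    fiml_loglik(d, m$mu, m$Sigma)
  }
  ga <- bivtraj:::fiml_grad(ms, th, d)
  gn <- num_grad(f, th)
  expect_equal(ga, gn, tolerance = 1e-4)

  ## casewise scores sum to the total gradient and match per-case numerics
  S <- bivtraj:::fiml_casewise_scores(ms, th, d)
  expect_equal(unname(colSums(S)), unname(ga), tolerance = 1e-8)
  fi <- function(t, i) {
    m <- implied_moments(ms, t)
    fiml_loglik(d, m$mu, m$Sigma, casewise = TRUE)$casewise[i]
  }
  for (i in seq_len(nrow(S)))
    expect_equal(unname(S[i, ]), num_grad(function(t) fi(t, i), th),
                 tolerance = 1e-4)

  ## Hessian (numerical of analytic gradient) vs pure numerics
  H1 <- num_hess(function(t) bivtraj:::fiml_grad(ms, t, d), th)
  H2 <- num_hess(function(t) num_grad(f, t), th, h = 1e-4)
  expect_equal(H1, H2, tolerance = 1e-4)
})

test_that("equality classes move all mapped cells identically", {
  ms <- build_lfa_structure(c("a", "b"), c("c", "d"), n_waves = 3)
  th <- ms_pack(ms)
  k <- which(ms$par_names == "lambda(b)")
  m0 <- bivtraj:::ms_apply(ms, th)
  th2 <- th
  th2[k] <- th[k] + 0.3
  m1 <- bivtraj:::ms_apply(ms, th2)
  moved <- which(abs(m1$Lambda - m0$Lambda) > 0)
  expect_length(moved, 3)                       # one cell per wave
  expect_true(all(abs(m1$Lambda[moved] - m0$Lambda[moved] - 0.3) < 1e-12))
})

test_that("the saturated model on complete data is the closed-form ML fit", {
  set.seed(13)
  Y <- simulate_one_factor(300)
  d <- missing_pattern_data(Y)
  sat <- saturated_loglik(d)
  n <- nrow(Y)
  S <- cov(Y) * (n - 1) / n
  ll_closed <- -n / 2 * (ncol(Y) * log(2 * pi) + log(det(S)) + ncol(Y))
  expect_equal(as.numeric(sat), ll_closed, tolerance = 1e-8)
  expect_equal(unname(attr(sat, "mu")), unname(colMeans(Y)), tolerance = 1e-8)

  ## a free-(mu, Sigma) structural model reaches the same optimum
  p <- ncol(Y)
  msat <- moment_structure(
    nu = stats::setNames(numeric(p), colnames(Y)),
    Lambda = diag(p), alpha = numeric(p), Psi = diag(p),
    Theta = matrix(0, p, p),
    free = list(nu = seq_len(p)), psi_mode = "chol")
  fit <- fit_sem(msat, d, se = "none")
  expect_true(fit$converged)
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-6)
  mats <- fit$mats
  expect_equal(unname(mats$nu), unname(colMeans(Y)), tolerance = 1e-5)
  expect_equal(unname(mats$Psi), unname(S), tolerance = 1e-4)
})

test_that("saturated EM recovers generating moments under MCAR deletion", {
  set.seed(17)
  n <- 20000
  Sigma <- matrix(c(1, 0.6, 0.6, 2), 2, 2)
  Y <- MASS::mvrnorm(n, c(1, -1), Sigma)
  colnames(Y) <- c("a", "b")
  Y[runif(n) < 0.3, 1] <- NA
  Y[runif(n) < 0.3, 2] <- NA
  d <- missing_pattern_data(Y)
  sat <- saturated_loglik(d)
  expect_true(attr(sat, "converged"))
  expect_equal(unname(attr(sat, "mu")), c(1, -1), tolerance = 0.03)
  expect_equal(unname(attr(sat, "Sigma")), unname(Sigma), tolerance = 0.06)
})

test_that("parameter recovery and likelihood ordering on a known factor model", {
  ms <- one_factor_structure()
  Y <- simulate_one_factor(5000, miss = 0.1, seed = 23)
  d <- missing_pattern_data(Y)
  fit <- fit_sem(ms, d, se = "naive", h1 = TRUE)
  expect_true(fit$converged)
  truth <- c(0.8, 0.6, 0.9, 0.5, rep(log(sqrt(0.5)), 4), 0)
  est <- fit$theta[c("l2", "l3", "l4", "alpha")]
  se <- fit$se_naive[c("l2", "l3", "l4", "alpha")]
  expect_true(all(abs(est - truth[1:4]) < 3 * se + 1e-8))
  ## model chi2 against the saturated fit is nonnegative, df as counted
  expect_gte(fit$chi2, 0)
  expect_equal(fit$df, (4 + 10) - fit$n_params)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
})

test_that("a model with more parameters than moments is refused", {
  ms <- one_factor_structure(lam = c(1, 0.8, 0.6))  # 3 indicators: 8 params
  ms$n_free <- ms$n_free  # 7 map + 1 chol = 8 < 9 ok; add free nu to break
  ms2 <- one_factor_structure(lam = c(1, 0.8, 0.6))
  ms2$free$nu <- c(7L, 8L, 9L)
  ms2 <- moment_structure(ms2$nu, ms2$Lambda, ms2$alpha, ms2$Psi, ms2$Theta,
                          ms2$free, psi_mode = "chol",
                          par_names = c(paste0("l", 2:3), "alpha",
                                        paste0("theta", 1:3),
                                        paste0("nu", 1:3)))
  Y <- simulate_one_factor(50, lam = c(1, .8, .6), seed = 3)
  expect_error(fit_sem(ms2, missing_pattern_data(Y)), "sample moments")
})

test_that("sandwich equals naive when B is forced to A, and is PSD otherwise", {
  ms <- one_factor_structure()
  Y <- simulate_one_factor(400, miss = 0.15, seed = 29)
  d <- missing_pattern_data(Y)
  fit <- fit_sem(ms, d, se = "robust")
  sw <- sandwich_se(ms, d, fit$theta)
  forced <- sandwich_se(ms, d, fit$theta, A = sw$A, B = sw$A)
  naive <- sqrt(diag(solve(sw$A)))
  expect_equal(unname(forced$se), unname(naive), tolerance = 1e-10)
  expect_true(all(eigen(sw$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("standardized loadings are invariant to marker vs unit-variance scaling", {
  lam <- c(1, 0.8, 0.6, 0.9)
  Y <- simulate_one_factor(2000, lam = lam, seed = 37)
  d <- missing_pattern_data(Y)
  marker <- one_factor_structure()
  fit_m <- fit_sem(marker, d, se = "none")
  p <- 4
  unit <- moment_structure(
    nu = stats::setNames(numeric(p), colnames(Y)),
    Lambda = matrix(0.7, p, 1, dimnames = list(colnames(Y), "f")),
    alpha = c(f = 0.5), Psi = matrix(1, 1, 1), Theta = diag(0.5, p),
    free = list(Lambda = matrix(seq_len(p), p, 1), alpha = p + 1L,
                Theta = diag(seq_len(p) + p + 1L)),
    psi_mode = "cellwise",
    par_names = c(paste0("l", 1:p), "alpha", paste0("theta", 1:p)))
  fit_u <- fit_sem(unit, d, se = "none")
  std <- function(fit) {
    m <- fit$mats
    Sg <- m$Lambda %*% m$Psi %*% t(m$Lambda) + m$Theta
    drop(m$Lambda) * sqrt(drop(m$Psi)) / sqrt(diag(Sg))
  }
  expect_true(fit_m$converged && fit_u$converged)
  expect_equal(std(fit_m), std(fit_u), tolerance = 1e-4)
})

test_that("fit indices follow their definitions and pin the RMSEA n convention", {
  idx <- fit_indices(100, 100, 500, 120, 1000)
  expect_equal(idx$rmsea, 0)
  idx2 <- fit_indices(300, 100, 360, 120, 1000)     # equal chi2/df ratios
  expect_equal(idx2$tli, 0)
  ## published univariate spline row: chi2 = 670, df = 179 at the analysis n
  idx3 <- fit_indices(670, 179, 5000, 189, 14489)
  expect_equal(round(idx3$rmsea, 3), 0.014)
  ## the CI endpoints invert the noncentral chi-square at .975/.025
  expect_equal(stats::pchisq(670, 179, ncp = idx3$rmsea_ci[1]^2 * 179 * 14489),
               0.975, tolerance = 1e-6)
  expect_equal(stats::pchisq(670, 179, ncp = idx3$rmsea_ci[2]^2 * 179 * 14489),
               0.025, tolerance = 1e-6)
  expect_warning(fit_indices(50, 100, 80, 120, 1000), "capped")
})

test_that("robust Wald intervals attain nominal coverage in a correctly specified model", {
  ms <- linear_growth_structure()
  true_slope <- -0.2
  hits <- 0
  R <- 500
  for (r in seq_len(R)) {
    Y <- simulate_linear_growth(200, seed = 5000 + r)
    d <- missing_pattern_data(Y)
    fit <- fit_sem(ms, d, se = "robust")
    est <- fit$theta["alpha(s)"]
    se <- fit$se_robust["alpha(s)"]
    if (abs(est - true_slope) <= qnorm(0.975) * se) hits <- hits + 1
  }
  coverage <- hits / R
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("structures round-trip through JSON", {
  ms <- build_lfa_structure(c("a", "b"), c("c", "d"), n_waves = 2)
  js <- ms_to_json(ms)
  ms2 <- ms_from_json(js)
  expect_equal(ms2$n_free, ms$n_free)
  expect_equal(ms_pack(ms2), ms_pack(ms))
  im1 <- implied_moments(ms)
  im2 <- implied_moments(ms2)
  expect_equal(im1$Sigma, im2$Sigma)
})
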