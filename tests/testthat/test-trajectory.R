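## Stage 2: age binning, rescaling, trajectory structures, univariate and
## bivariate fits, and model comparison.

make_scores <- function(n = 1500, seed = 51, config = growth_config(),
                        retention = c(1, 1, 1)) {
  des <- panel_design(n_persons = n, retention = retention,
                      mar_attrition_coef = 0, seed = seed)
  generate_score_panel(config, des)
}

test_that("age binning maps edges correctly and yields 18 bins", {
  bins <- age_bin_table()
  expect_equal(nrow(bins), (84 - 50) / 2 + 1)
  expect_equal(bins$code[bins$label == "70/71"], 0)

  sc <- data.frame(id = 1:6,
                   age_years = c(50.0, 51.9, 85.9, 49.9, 86.0, 70.5),
                   cog_score = 1:6)
  abm <- assign_age_bins(sc)
  expect_equal(ncol(abm$data), 18)
  expect_equal(abm$n_dropped_low, 1)
  expect_equal(abm$n_dropped_high, 1)
  expect_equal(unname(abm$data[c("1", "2"), "cog_b50"]), c(1, 2))
  expect_equal(unname(abm$data["3", "cog_b84"]), 3)
  expect_equal(unname(abm$data["6", "cog_b70"]), 6)
  expect_true(all(is.na(abm$data[c("4", "5"), ])))

  ## two occasions in one bin are averaged with a warning
  sc2 <- data.frame(id = c(1, 1), age_years = c(70.2, 71.4),
                    cog_score = c(1, 3))
  expect_warning(abm2 <- assign_age_bins(sc2), "averaged")
  expect_equal(unname(abm2$data[1, "cog_b70"]), 2)
})

test_that("trajectory structures carry the decade time codes", {
  sp <- trajectory_spec(cog = "spline", fnc = "linear")
  ms <- build_trajectory_structure(sp)
  L <- ms$Lambda
  ## knot bin: pure intercept for the spline process
  expect_equal(unname(L["cog_b70", c("COG_i", "COG_s1", "COG_s2")]),
               c(1, 0, 0))
  ## two decades pre-knot at bin 50/51
  expect_equal(unname(L["cog_b50", c("COG_s1", "COG_s2")]), c(-2, 0))
  expect_equal(unname(L["fnc_b50", "FNC_s"]), -2)
  expect_equal(unname(L["fnc_b84", "FNC_s"]), 1.4)
  ## cross-process residual covariance shared across all 18 bins
  expect_equal(sum(ms$free$Theta[cbind(1:18, 19:36)] ==
                     ms$free$Theta[1, 19]), 18)
  expect_error(trajectory_spec(knot = "80/81"), "knot")
})

test_that("noise-free spline regression recovers generating slope means exactly", {
  cfg <- growth_config()
  co <- matrix(cfg$latent_means, 1, dimnames = list(NULL, cfg$latent_names))
  ages <- seq(50, 85, by = 0.5)
  vals <- t(vapply(ages, function(a) latent_value_at_age(co, a, cfg)[1, ],
                   numeric(2)))
  s <- (ages - 70) / 10
  fit <- stats::lm(vals[, "COG"] ~ I(pmin(s, 0)) + I(pmax(s, 0)))
  expect_equal(unname(stats::coef(fit)), c(0.031, -0.047, -0.230),
               tolerance = 1e-10)
})

test_that("rescaling at the 70/71 bin standardizes scores but not fit statistics", {
  sim <- make_scores(n = 900, seed = 52)
  abm <- assign_age_bins(sim$panel)
  res <- rescale_at_bin(abm, "70/71")
  v <- res$data[, "cog_b70"]
  expect_equal(mean(v, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(stats::sd(v, na.rm = TRUE), 1, tolerance = 1e-12)

  sp <- trajectory_spec(cog = "spline", fnc = NULL)
  f_raw <- fit_trajectory_model(abm, sp, h1 = TRUE)
  f_res <- fit_trajectory_model(res, sp, h1 = TRUE)
  expect_equal(f_raw$chi2, f_res$chi2, tolerance = 1e-6)
  expect_equal(f_raw$df, f_res$df)
  expect_equal(f_raw$tli, f_res$tli, tolerance = 1e-6)
  expect_equal(f_raw$rmsea, f_res$rmsea, tolerance = 1e-6)
  ## slope estimates scale by one over the target-bin SD
  sdc <- attr(res, "rescale_record")$cog["sd"]
  expect_equal(est_of(f_res, "alpha(COG_s1)"),
               est_of(f_raw, "alpha(COG_s1)") / sdc,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("univariate model set is fit, compared, and nested sanely", {
  sim <- make_scores(n = 1500, seed = 53, config = univariate_growth_config("COG"))
  abm <- assign_age_bins(sim$panel)
  fits <- fit_univariate_trajectories(abm, "cog", h1 = TRUE)
  expect_named(fits, c("intercept_only", "linear", "spline_60/61",
                       "spline_64/65", "spline_70/71", "spline_74/75"))
  cmp <- compare_models(fits)
  ## AIC reproducible from loglik and parameter count
  for (f in fits) expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params)
  ## nested pairs: intercept-only vs linear vs spline(70/71)
  sub <- compare_models(fits[c("intercept_only", "linear", "spline_70/71")])
  expect_true(all(sub$delta_chi2[-1] >= -1e-6))
  expect_true(all(sub$delta_df[-1] > 0))
  ## data generated with a pronounced post-knot steepening prefers the
  ## spline over the linear and intercept-only models
  aic <- stats::setNames(cmp$aic, cmp$model)
  expect_lt(aic["COG spline(70/71)"], aic["COG linear"])
  expect_lt(aic["COG linear"], aic["COG intercept-only"])

  ## comparing fits from different data refuses
  sim2 <- make_scores(n = 400, seed = 99,
                      config = univariate_growth_config("COG"))
  other <- fit_trajectory_model(assign_age_bins(sim2$panel),
                                trajectory_spec(cog = "spline", fnc = NULL))
  expect_error(compare_models(list(fits$linear, other)), "different data")
})

test_that("single-slope data make the spline collapse onto the linear model", {
  cfg <- growth_config(latent_names = c("COG_i", "COG_s"),
                       latent_means = c(0, -0.15),
                       latent_sds = sqrt(c(0.5, 0.1)),
                       latent_corr = matrix(c(1, .3, .3, 1), 2),
                       residual_sds = c(COG = sqrt(0.3)),
                       residual_cross_corr = 0)
  sim <- make_scores(n = 4000, seed = 54, config = cfg)
  abm <- assign_age_bins(sim$panel)
  lin <- fit_trajectory_model(abm, trajectory_spec(cog = "linear", fnc = NULL))
  spl <- fit_trajectory_model(abm, trajectory_spec(cog = "spline", fnc = NULL))
  ## no knot in the truth: both slope means agree and AIC gives the spline
  ## no more than its parameter-count advantage
  expect_lt(abs(est_of(spl, "alpha(COG_s1)") -
                  est_of(spl, "alpha(COG_s2)")), 0.05)
  expect_lt(abs(lin$aic - spl$aic), 2 * (spl$n_params - lin$n_params) + 4)
})

test_that("bivariate fit separates into univariate blocks without cross links", {
  sim <- make_scores(n = 2000, seed = 55)
  abm <- assign_age_bins(sim$panel)
  biv0 <- fit_trajectory_model(abm, trajectory_spec(), cross_latent = FALSE)
  unic <- fit_trajectory_model(abm, trajectory_spec(cog = "spline", fnc = NULL))
  for (nm in c("alpha(COG_i)", "alpha(COG_s1)", "alpha(COG_s2)"))
    expect_lt(abs(est_of(biv0, nm) - est_of(unic, nm)), 0.01)

  ## nesting: the spline+linear model can only improve on linear+linear
  biv_ll <- fit_trajectory_model(abm, trajectory_spec(cog = "linear",
                                                      fnc = "linear"))
  biv_sl <- fit_trajectory_model(abm, trajectory_spec())
  expect_gte(biv_sl$loglik, biv_ll$loglik - 1e-4)

  ## full bivariate fit reports the published parameter layout
  fit <- fit_bivariate_trajectory(abm, se = "robust", h1 = FALSE)
  expect_true(fit$converged)
  expect_s3_class(fit$params, "data.frame")
  expect_setequal(
    fit$params$type,
    c("mean", "variance", "correlation", "covariance"))
  expect_equal(sum(fit$params$type == "correlation"), 10 + 1)
  ## cumulative-change arithmetic: slope means times decade spans
  cc <- fit$cumulative_change
  expect_equal(cc$change[cc$process == "COG" & cc$window == "50-70"],
               est_of(fit, "alpha(COG_s1)") * 2, ignore_attr = TRUE)
  expect_equal(cc$change[cc$process == "FNC" & cc$window == "70-85"],
               est_of(fit, "alpha(FNC_s)") * 1.5, ignore_attr = TRUE)
})
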