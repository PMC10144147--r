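## Stage 1: item standardization, invariance structures, factor-model
## recovery, and Bartlett scoring.

test_that("standardization centers the reference wave and preserves drift", {
  ## fixed panel: 2016 fluency is the 2010 distribution shifted down 0.7
  base <- c(10, 13, 16, 19, 22, 24.4)     # mean 17.4-ish after scaling
  base <- (base - mean(base)) / sd(base) * 7.1 + 17.4
  panel <- data.frame(id = rep(1:6, 2),
                      wave_year = rep(c(2010, 2016), each = 6),
                      age_years = 60,
                      fluency = c(base, base - 0.7))
  std <- standardize_items(panel, ref_wave = 2010)
  z10 <- std$panel$fluency[std$panel$wave_year == 2010]
  expect_equal(mean(z10), 0, tolerance = 1e-12)
  expect_equal(sd(z10), 1, tolerance = 1e-12)
  ## later-wave standardized mean is raw drift over the reference SD
  z16 <- std$panel$fluency[std$panel$wave_year == 2016]
  expect_equal(mean(z16), -0.7 / 7.1, tolerance = 1e-12)
  expect_equal(round(mean(z16), 3), -0.099)

  ## adding a constant to every wave changes nothing after standardization
  shifted <- panel
  shifted$fluency <- shifted$fluency + 5
  std2 <- standardize_items(shifted, ref_wave = 2010)
  expect_equal(std2$panel$fluency, std$panel$fluency, tolerance = 1e-12)

  ## zero-variance items are refused by name
  flat <- panel
  flat$fluency[flat$wave_year == 2010] <- 3
  expect_error(standardize_items(flat, 2010), "fluency")
})

test_that("invariance levels differ by the expected parameter count and nest", {
  cog <- c("numeracy", "fluency", "serial7", "recall")
  fnc <- c("mobility", "adl", "iadl")
  strong <- build_lfa_structure(cog, fnc, n_waves = 3)
  config <- build_lfa_structure(cog, fnc, n_waves = 3,
                                invariance = "configural")
  ## freeing loadings+intercepts per wave while dropping the free latent
  ## means: 2 * (items - markers) * (waves - 1) more parameters
  expect_equal(config$n_free - strong$n_free, 2 * (7 - 2) * (3 - 1))

  des <- panel_design(n_persons = 800, retention = c(1, 1, 1),
                      mar_attrition_coef = 0, seed = 21)
  sim <- generate_item_panel(growth_config(), measurement_config(), des)
  std <- standardize_items(sim$panel)
  f_s <- fit_bivariate_lfa(std$panel, structure = strong, se = "none",
                           h1 = FALSE)
  f_c <- fit_bivariate_lfa(std$panel, structure = config, se = "none",
                           h1 = FALSE)
  expect_gte(f_c$loglik, f_s$loglik - 1e-4)
})

test_that("the fitted factor model recovers the generating loading pattern", {
  des <- panel_design(n_persons = 20000, retention = c(1, 1, 1),
                      mar_attrition_coef = 0, seed = 22)
  sim <- generate_item_panel(growth_config(), measurement_config(), des)
  std <- standardize_items(sim$panel)
  lfa <- fit_bivariate_lfa(std$panel, se = "none", h1 = TRUE)
  expect_true(lfa$converged)
  ## published pattern the defaults are calibrated to reproduce
  target <- c(numeracy = 0.850, fluency = 0.59, serial7 = 0.52,
              recall = 0.445, mobility = 0.775, adl = 0.820, iadl = 0.578)
  got <- stats::setNames(lfa$std_loadings$std_loading, lfa$std_loadings$item)
  expect_lt(max(abs(got[names(target)] - target)), 0.05)
  ## df bookkeeping: moments minus free parameters under the constraint set
  expect_equal(lfa$df, (21 + 21 * 22 / 2) - lfa$n_params)
  expect_equal(lfa$n_params, 58)
  ## strong invariance holds exactly in the fitted matrices
  L <- lfa$mats$Lambda
  expect_equal(L[1:7, 1:2], L[8:14, 3:4], ignore_attr = TRUE)
  expect_equal(lfa$mats$nu[1:7], lfa$mats$nu[8:14], ignore_attr = TRUE)
})

test_that("breaking longitudinal linkage destroys cross-wave correlations", {
  des <- panel_design(n_persons = 3000, retention = c(1, 1, 1),
                      mar_attrition_coef = 0, seed = 23)
  sim <- generate_item_panel(growth_config(), measurement_config(), des)
  std <- standardize_items(sim$panel)
  lfa <- fit_bivariate_lfa(std$panel, se = "none", h1 = FALSE)
  psi_cor <- stats::cov2cor(lfa$mats$Psi)
  expect_gt(psi_cor["COG@2010", "COG@2016"], 0.4)

  scram <- std$panel
  set.seed(1)
  for (w in c(2012, 2016)) {
    sel <- scram$wave_year == w
    scram$id[sel] <- sample(scram$id[sel])
  }
  lfa2 <- fit_bivariate_lfa(scram, se = "none", h1 = FALSE)
  psi_cor2 <- stats::cov2cor(lfa2$mats$Psi)
  expect_lt(abs(psi_cor2["COG@2010", "COG@2016"]), 0.15)
  expect_lt(abs(psi_cor2["FNC@2010", "FNC@2016"]), 0.15)
})

test_that("Bartlett scores are exact without noise and match hand algebra", {
  ## hand example: one factor, Lambda (1,1)', Theta = I, y = (1,3)
  info <- 2                      # Lambda' Theta^-1 Lambda
  score <- (1 / info) * (1 * 1 + 1 * 3)
  expect_equal(score, 2)

  ## noise-free items reproduce the latent state exactly through the
  ## full build -> fit -> score path
  des <- panel_design(n_persons = 500, retention = c(1, 1, 1),
                      mar_attrition_coef = 0, seed = 24)
  meas <- continuous_measurement()
  meas$theta[] <- 1e-4           # effectively noise-free
  sim <- generate_item_panel(growth_config(), meas, des)
  lfa <- fit_bivariate_lfa(sim$panel, cog_items = paste0("c", 1:4),
                           fnc_items = paste0("f", 1:3),
                           se = "none", h1 = FALSE)
  ## residual variances sit at their boundary here, so the fit may flag
  ## itself non-converged; scoring is still exact
  sc <- suppressWarnings(bartlett_scores(lfa, sim$panel))
  m <- merge(sc, sim$truth, by = c("id", "wave_year"))
  ## scores equal the latent state up to the marker-identification constant
  ## (wave-1 latent means are fixed at zero, so the wave-1 factor mean is
  ## absorbed into the item intercepts)
  expect_lt(stats::sd(m$cog_score - m$true_cog), 1e-2)
  expect_lt(stats::sd(m$fnc_score - m$true_fnc), 1e-2)
})

test_that("Bartlett scores are conditionally unbiased at scale", {
  des <- panel_design(n_persons = 20000, retention = c(1, 1, 1),
                      mar_attrition_coef = 0, seed = 25)
  sim <- generate_item_panel(growth_config(), continuous_measurement(), des)
  lfa <- fit_bivariate_lfa(sim$panel, cog_items = paste0("c", 1:4),
                           fnc_items = paste0("f", 1:3),
                           se = "none", h1 = FALSE)
  sc <- bartlett_scores(lfa, sim$panel)
  m <- merge(sc, sim$truth, by = c("id", "wave_year"))
  slope_c <- stats::coef(stats::lm(cog_score ~ true_cog, m))[2]
  slope_f <- stats::coef(stats::lm(fnc_score ~ true_fnc, m))[2]
  expect_equal(unname(slope_c), 1, tolerance = 0.03)
  expect_equal(unname(slope_f), 1, tolerance = 0.03)
  ## score = truth + estimation noise whose variance matches the stored
  ## error covariance
  err <- attr(sc, "score_error_cov")
  full <- err[[grep(":1111111$", names(err))[1]]]
  expect_equal(var(m$cog_score - m$true_cog), full["COG", "COG"],
               tolerance = 0.03)

  ## score extraction is invariant to panel row order
  perm <- sample(nrow(sim$panel))
  sc2 <- bartlett_scores(lfa, sim$panel[perm, ])
  sc2 <- sc2[order(sc2$id, sc2$wave_year), ]
  sc1 <- sc[order(sc$id, sc$wave_year), ]
  expect_equal(sc1$cog_score, sc2$cog_score)

  ## a wave with no observed indicators for a factor yields NA, not zero
  pan <- sim$panel
  sel <- pan$wave_year == 2012 & pan$id <= 10
  pan[sel, paste0("f", 1:3)] <- NA
  sc3 <- bartlett_scores(lfa, pan)
  expect_true(all(is.na(sc3$fnc_score[sc3$wave_year == 2012 & sc3$id <= 10])))
  expect_false(anyNA(sc3$cog_score[sc3$wave_year == 2012 & sc3$id <= 10]))
})
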