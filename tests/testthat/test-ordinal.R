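test_that("intercept-only fit reproduces weighted cumulative shares in closed form", {
  d <- toy_ordinal_data()
  fit <- frailty_po(y ~ 1, data = d, weights = d$w)
  sw <- sum(d$w)
  cum1 <- sum(d$w[d$y == "robust"]) / sw
  cum2 <- sum(d$w[d$y != "frail"]) / sw
  expect_equal(plogis(fit$zeta[[1]]), cum1, tolerance = 1e-7)
  expect_equal(plogis(fit$zeta[[2]]), cum2, tolerance = 1e-7)
})

test_that("estimates are invariant to rescaling all weights", {
  d <- toy_ordinal_data()
  f1 <- frailty_po(y ~ x, data = d, weights = d$w)
  f2 <- frailty_po(y ~ x, data = d, weights = 2 * d$w)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  expect_equal(f1$zeta, f2$zeta, tolerance = 1e-7)
  expect_equal(f2$logLik, 2 * f1$logLik, tolerance = 1e-8)
  # unit weights equal the unweighted fit exactly
  f3 <- frailty_po(y ~ x, data = d, weights = rep(1, 20))
  f4 <- frailty_po(y ~ x, data = d, weights = NULL)
  expect_equal(c(coef(f3), f3$zeta), c(coef(f4), f4$zeta), tolerance = 1e-10)
})

test_that("toy weighted MLE matches an independent grid maximisation", {
  d <- toy_ordinal_data()
  fit <- frailty_po(y ~ x, data = d, weights = d$w)
  ref <- toy_grid_mle(d)
  expect_equal(unname(coef(fit)), ref[1], tolerance = 1e-4)
  expect_equal(unname(fit$zeta), ref[2:3], tolerance = 1e-4)
})

test_that("fit agrees with MASS::polr on survey-sized data", {
  skip_if_not_installed("MASS")
  sv <- generate_survey(small_config(n = 1500L, item_missing_rate = 0,
                                     seed = 23))
  sc <- score_survey(sv$survey)
  fit <- frailty_po(data = sc)
  dd <- sc
  dd$age_band <- factor(dd$age_band, levels = age_bands())
  dd$sex <- factor(dd$sex, levels = c("male", "female"))
  dd$imd_quintile <- factor(dd$imd_quintile, levels = 1:5)
  # polr warns about non-integer binomial weights in its start-value glm
  ref <- suppressWarnings(
    MASS::polr(frailty_cat ~ age_band + sex + imd_quintile, data = dd,
               weights = dd$weight))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-3)
  expect_equal(unname(fit$zeta), unname(ref$zeta), tolerance = 1e-3)
})

test_that("fits reject empty categories and report convergence", {
  d <- toy_ordinal_data()
  d2 <- d[d$y != "frail", ]
  expect_error(frailty_po(y ~ x, data = d2, weights = d2$w),
               "no observations")
  fit <- frailty_po(y ~ x, data = d, weights = d$w)
  expect_true(fit$converged)
  expect_lte(fit$grad_norm, 1e-8)
  expect_lt(fit$zeta[1], fit$zeta[2])
  expect_lte(fit$logLik, 0)
  V <- vcov(fit)
  expect_equal(V, t(V))
  expect_true(all(diag(V) >= 0))
})

test_that("Rubin pooling follows the textbook formulas", {
  d <- toy_ordinal_data()
  fit <- frailty_po(y ~ x, data = d, weights = d$w)
  # m identical fits: point unchanged, between-variance zero
  pl <- pool_rubin(list(fit, fit, fit))
  expect_equal(pl$point, c(coef(fit), fit$zeta))
  expect_equal(max(abs(pl$between)), 0)
  expect_equal(pl$cov, vcov(fit), tolerance = 1e-12)
  # m = 1: pooled quantities equal the single fit's
  p1 <- pool_rubin(list(fit))
  expect_equal(p1$point, c(coef(fit), fit$zeta))
  expect_equal(p1$cov, vcov(fit))
  # scalar hand computation: estimates 1 and 2, variances 0.5 each
  mk <- function(est) structure(list(coefficients = c(a = est),
                                     zeta = numeric(0),
                                     vcov = matrix(0.5, 1, 1,
                                                   dimnames = list("a", "a"))),
                                class = "frailty_po")
  p2 <- pool_rubin(list(mk(1), mk(2)))
  expect_equal(unname(p2$point), 1.5)
  expect_equal(as.numeric(p2$cov), 0.5 + 1.5 * 0.5)
})

test_that("stratum predictions are coherent probabilities", {
  sv <- generate_survey(small_config(n = 1500L, item_missing_rate = 0,
                                     seed = 24))
  fit <- frailty_po(data = score_survey(sv$survey))
  ps <- predict_strata(fit)
  expect_equal(nrow(ps), 90L)
  P <- as.matrix(ps[, c("p_robust", "p_prefrail", "p_frail")])
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P >= 0))
  # reference stratum: p_robust = expit(theta_1)
  ref <- ps[ps$age_band == "50-54" & ps$sex == "male" & ps$imd_quintile == 1, ]
  expect_equal(ref$p_robust, plogis(fit$zeta[[1]]), tolerance = 1e-12)
  # proportional-odds monotonicity: p_robust decreasing in x'beta
  X <- model.matrix(~ age_band + sex + imd_quintile,
                    transform(stratum_grid(),
                              age_band = factor(age_band, levels = age_bands()),
                              sex = factor(sex, levels = c("male", "female")),
                              imd_quintile = factor(imd_quintile, 1:5)))[, -1]
  eta <- drop(X %*% coef(fit))
  expect_false(is.unsorted(rev(ps$p_robust[order(eta)])))
})

test_that("reference relabelling changes coefficients but not probabilities", {
  sv <- generate_survey(small_config(n = 1200L, item_missing_rate = 0,
                                     seed = 26))
  sc <- score_survey(sv$survey)
  f1 <- frailty_po(data = sc)
  sc2 <- sc
  sc2$sex <- factor(sc2$sex, levels = c("female", "male"))
  f2 <- frailty_po(data = sc2)
  expect_equal(unname(coef(f2)["sexmale"]), -unname(coef(f1)["sexfemale"]),
               tolerance = 1e-6)
  p1 <- predict(f1, stratum_grid())
  g2 <- stratum_grid()
  g2$sex <- factor(g2$sex, levels = c("female", "male"))
  p2 <- predict(f2, g2)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("likelihood-ratio test is zero for identical models and detects strong interactions", {
  sv <- generate_survey(small_config(n = 1500L, item_missing_rate = 0,
                                     seed = 27))
  sc <- score_survey(sv$survey)
  f0 <- frailty_po(data = sc)
  same <- lrt_interaction(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  f1 <- frailty_po(frailty_cat ~ age_band + sex + imd_quintile + age_band:sex,
                   data = sc)
  lrt <- lrt_interaction(f0, f1)
  expect_equal(lrt$df, 8L)  # eight added age-by-sex indicators
  expect_gte(lrt$p_value, 0)
  expect_error(lrt_interaction(f1, f0), "not nested")

  # power: data simulated with a large true age-by-sex effect on frailty
  hits <- 0L
  for (r in 1:8) {
    cfg <- generator_config(n_respondents = 4000L, item_missing_rate = 0,
                            nonresponse_target = 0, seed = 300 + r,
                            gamma_sex = 0)
    svr <- generate_survey(cfg)
    scr <- score_survey(svr$survey)
    old <- (scr$age_band %in% c("75-79", "80-84", "85-89", "90+"))
    fem <- scr$sex == "female"
    # impose the interaction by swapping outcomes towards frail for old women
    idx <- which(old & fem & scr$frailty_cat == "robust")
    flip <- idx[seq_len(floor(length(idx) * 0.6))]
    scr$frailty_cat[flip] <- "frail"
    n0 <- frailty_po(data = scr)
    n1 <- frailty_po(frailty_cat ~ age_band + sex + imd_quintile +
                       age_band:sex, data = scr)
    if (lrt_interaction(n0, n1)$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("coefficient draws respect ordering and degenerate covariance", {
  sv <- generate_survey(small_config(n = 1200L, item_missing_rate = 0,
                                     seed = 28))
  fit <- frailty_po(data = score_survey(sv$survey))
  dr <- draw_coefs(fit, 250L, seed = 5)
  expect_equal(dim(dr), c(250L, length(coef(fit)) + 2L))
  th <- dr[, grep("\\|", colnames(dr))]
  expect_true(all(th[, 1] < th[, 2]))
  expect_lt(max(abs(colMeans(dr) - c(coef(fit), fit$zeta))), 0.2)
  # zero covariance: every draw is the point estimate
  fit0 <- fit
  fit0$vcov <- matrix(0, nrow(vcov(fit)), ncol(vcov(fit)),
                      dimnames = dimnames(vcov(fit)))
  dr0 <- draw_coefs(fit0, 120L, seed = 6)
  expect_equal(unname(dr0[1, ]), unname(c(coef(fit), fit$zeta)))
  expect_equal(max(apply(dr0, 2, sd)), 0)
})
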