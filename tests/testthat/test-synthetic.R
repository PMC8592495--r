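test_that("config validation rejects bad parameters", {
  expect_error(generator_config(alpha = NaN), "finite")
  expect_error(generator_config(sigma_u = -1), "sigma_u")
  expect_error(generator_config(n_areas = 3), "n_areas")
  expect_error(generator_config(nonresponse_target = 1), "\\[0, 1\\)")
  expect_error(generator_config(gamma_age = 1:3), "length 9")
})

test_that("homogeneous degenerate config gives exactly the baseline deficit probability", {
  cfg <- generator_config(sigma_u = 0, gamma_age = rep(0, 9), gamma_sex = 0,
                          gamma_imd = rep(0, 5), alpha = logit(0.2),
                          n_respondents = 200, seed = 3)
  tr <- stratum_truth(cfg)
  # every stratum identical, equal to the closed-form binomial tails at p = 0.2
  k1 <- floor(0.24 * 30); k2 <- floor(0.36 * 30)
  expect_equal(tr$p_robust, rep(pbinom(k1, 30, 0.2), 90), tolerance = 1e-12)
  expect_equal(tr$p_frail, rep(pbinom(k2, 30, 0.2, lower.tail = FALSE), 90),
               tolerance = 1e-12)
  # realised item means close to 0.2 (iid Bernoulli across all cells)
  sv <- generate_survey(cfg)
  dm <- as.matrix(sv$truth$complete_survey[, sprintf("deficit_%03d", 1:30)])
  expect_lt(abs(mean(dm) - 0.2), 0.02)
})

test_that("no non-response and no missingness give unit weights and complete data", {
  cfg <- small_config(nonresponse_target = 0, item_missing_rate = 0)
  sv <- generate_survey(cfg)
  expect_equal(sv$survey$weight, rep(1, nrow(sv$survey)))
  expect_false(anyNA(sv$survey))
  expect_equal(nrow(sv$survey), cfg$n_respondents)
})

test_that("non-response calibration hits the target rate", {
  cfg <- generator_config(seed = 12)   # default: 8355 drawn, target 0.176
  sv <- generate_survey(cfg)
  expect_lt(abs(sv$truth$nonresponse_realized - 0.176), 0.02)

  # independent simulation of the propensity model: same covariate laws,
  # own calibration of the intercept via uniroot
  set.seed(404)
  n <- 2e5
  band <- sample.int(9, n, replace = TRUE, prob = cfg$age_dist)
  q <- sample.int(5, n, replace = TRUE)
  eta <- cfg$nr_slope_age * (band - 1) + cfg$nr_slope_imd * (q - 1)
  c0 <- uniroot(function(c) mean(plogis(c + eta)) - (1 - 0.176),
                c(-20, 20), tol = 1e-10)$root
  expect_lt(abs(mean(plogis(c0 + eta)) - 0.824), 1e-6)
  # the generator's realised rate is consistent with this oracle rate
  expect_lt(abs(sv$truth$nonresponse_realized - (1 - mean(plogis(c0 + eta)))),
            0.02)
})

test_that("generation is reproducible and weights average one", {
  cfg <- small_config(seed = 55)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  expect_identical(a$survey, b$survey)
  expect_equal(mean(a$survey$weight), 1, tolerance = 1e-12)
})

test_that("area tables have permutation ranks and conserve population", {
  ar5 <- generate_areas(generator_config(n_areas = 5, seed = 8))
  ranks <- unique(ar5$areas[, c("area_id", "imd_rank")])$imd_rank
  expect_setequal(ranks, 1:5)

  # uniform uptake 1 -> total doses equal total over-50 population
  arf <- generate_areas(generator_config(n_areas = 12, seed = 9,
                                         dose_uptake = rep(1, 9)))
  expect_equal(sum(arf$doses$doses), sum(arf$areas$population))
})

test_that("risk-factor counts correlate with deprivation in the configured direction", {
  ar <- generate_areas(generator_config(seed = 21)) # rf_dep_log_rr > 0
  pop <- tapply(ar$areas$population, ar$areas$area_id, sum)
  tot <- tapply(ar$risk_factors$count, ar$risk_factors$area_id, sum)
  rk <- unique(ar$areas[, c("area_id", "imd_rank")])
  per_cap <- as.numeric(tot[rk$area_id]) / as.numeric(pop[rk$area_id])
  # rank 1 = most deprived, which carries the highest prevalence
  expect_lt(cor(rk$imd_rank, per_cap, method = "spearman"), 0)
})

test_that("Monte-Carlo oracle matches closed forms and the analytic truth", {
  # flat configuration: oracle category shares equal exact binomial tails
  cfg <- generator_config(sigma_u = 0, gamma_age = rep(0, 9), gamma_sex = 0,
                          gamma_imd = rep(0, 5), alpha = logit(0.5), seed = 71)
  orc <- oracle_stratum_probs(cfg, n_mc = 2e4)
  expect_equal(rowSums(orc[, c("p_robust", "p_prefrail", "p_frail")]),
               rep(1, 90), tolerance = 1e-12)
  ref <- orc[orc$age_band == "50-54" & orc$sex == "male" &
               orc$imd_quintile == 1, ]
  # frail iff count/30 > 0.36, i.e. count >= 11: exact binomial tail
  exact_frail <- 1 - pbinom(10, 30, 0.5)
  expect_equal(exact_frail, 0.950631, tolerance = 1e-6)
  expect_lt(abs(ref$p_frail - exact_frail), 0.01)

  # effects set to zero make all cells equal within Monte-Carlo error
  expect_lt(max(orc$p_frail) - min(orc$p_frail), 0.025)

  # and with effects on, the oracle tracks the analytic integral
  cfg2 <- small_config(seed = 31)
  orc2 <- oracle_stratum_probs(cfg2, n_mc = 2e4)
  tr2 <- stratum_truth(cfg2)
  expect_lt(max(abs(as.matrix(orc2[, 4:6]) - as.matrix(tr2[, 4:6]))), 0.02)
})
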