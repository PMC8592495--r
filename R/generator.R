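#' Configuration for the synthetic survey and area generator
#'
#' The generator emulates the shape of a national ageing survey linked to
#' area population, vaccination and risk-factor tables: respondents aged 50+
#' in nine five-year age bands, a deprivation- and age-graded deficit
#' process, survey non-response with inverse-probability weights, and an
#' age-proportional (frailty-blind) first-dose allocation across areas.
#'
#' Each respondent i draws a latent propensity u_i ~ Normal(0, sigma_u^2);
#' given u_i the per-item deficit probability is
#' `expit(alpha + gamma_age[a_i] + gamma_sex * female_i + gamma_imd[q_i] + u_i)`
#' and the `n_deficits` items are iid Bernoulli. Non-response follows a
#' logistic propensity in age band and deprivation quintile, calibrated so
#' the expected non-response rate equals `nonresponse_target`; supplied
#' weights are the inverse true response propensities rescaled to mean 1
#' over responders. Item missingness is missing-at-random with a rate that
#' depends on age band only.
#'
#' @param n_respondents Individuals drawn into the sample (before
#'   non-response). Default 8355.
#' @param n_areas Number of areas (default 135). Must be >= 5.
#' @param n_deficits Number of binary deficit items (default 30).
#' @param alpha Baseline per-item deficit log-odds for the reference
#'   respondent (age 50-54, male, least-deprived quintile, u = 0).
#' @param gamma_age Length-9 vector of age-band effects on the deficit
#'   log-odds, reference band 50-54 first; defaults are monotone
#'   non-decreasing.
#' @param gamma_sex Additive log-odds effect for female respondents.
#' @param gamma_imd Length-5 vector of deprivation-quintile effects
#'   (quintile 1 = most deprived); defaults decrease with affluence.
#' @param sigma_u Standard deviation (>= 0) of the latent respondent
#'   propensity.
#' @param nonresponse_target Expected non-response proportion in [0, 1)
#'   (default 0.176).
#' @param item_missing_rate Average per-cell missingness proportion in
#'   [0, 1) among responders (default 0.05); realised rates grade with age.
#' @param dose_uptake Length-9 vector of per-age-band first-dose uptake
#'   proportions used by the frailty-blind allocation.
#' @param age_dist Length-9 sampling distribution over age bands.
#' @param nr_slope_age,nr_slope_imd Log-odds slopes of the response
#'   propensity per age-band step and per quintile step towards affluence.
#' @param rf_dep_log_rr Per-quintile-step log rate ratio tying risk-factor
#'   prevalence to deprivation (positive = more disease where deprived).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_respondents = 8355L,
                             n_areas = 135L,
                             n_deficits = 30L,
                             alpha = logit(0.08),
                             gamma_age = seq(0, 1.6, length.out = 9L),
                             gamma_sex = 0.15,
                             gamma_imd = c(0.6, 0.45, 0.3, 0.15, 0),
                             sigma_u = 0.8,
                             nonresponse_target = 0.176,
                             item_missing_rate = 0.05,
                             dose_uptake = c(0.30, 0.40, 0.55, 0.75, 0.88,
                                             0.92, 0.94, 0.95, 0.93),
                             age_dist = c(0.17, 0.16, 0.15, 0.13, 0.12,
                                          0.11, 0.10, 0.045, 0.015),
                             nr_slope_age = -0.08,
                             nr_slope_imd = 0.10,
                             rf_dep_log_rr = 0.12,
                             seed = 1L) {
  cfg <- list(n_respondents = as.integer(n_respondents),
              n_areas = as.integer(n_areas),
              n_deficits = as.integer(n_deficits),
              alpha = alpha, gamma_age = gamma_age, gamma_sex = gamma_sex,
              gamma_imd = gamma_imd, sigma_u = sigma_u,
              nonresponse_target = nonresponse_target,
              item_missing_rate = item_missing_rate,
              dose_uptake = dose_uptake, age_dist = age_dist,
              nr_slope_age = nr_slope_age, nr_slope_imd = nr_slope_imd,
              rf_dep_log_rr = rf_dep_log_rr,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  num_fields <- c("alpha", "gamma_age", "gamma_sex", "gamma_imd", "sigma_u",
                  "nonresponse_target", "item_missing_rate", "dose_uptake",
                  "age_dist", "nr_slope_age", "nr_slope_imd", "rf_dep_log_rr")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stopf("generator config: '%s' must be finite numeric", f)
  }
  if (length(cfg$gamma_age) != 9L) stopf("gamma_age must have length 9")
  if (length(cfg$gamma_imd) != 5L) stopf("gamma_imd must have length 5")
  if (length(cfg$dose_uptake) != 9L) stopf("dose_uptake must have length 9")
  if (length(cfg$age_dist) != 9L) stopf("age_dist must have length 9")
  if (any(cfg$age_dist < 0) || sum(cfg$age_dist) <= 0)
    stopf("age_dist must be a non-negative distribution")
  if (cfg$n_deficits < 1L) stopf("n_deficits must be >= 1")
  if (cfg$n_areas < 5L) stopf("n_areas must be >= 5")
  if (cfg$n_respondents < 1L) stopf("n_respondents must be >= 1")
  if (cfg$sigma_u < 0) stopf("sigma_u must be >= 0")
  check_proportion(cfg$nonresponse_target, "nonresponse_target")
  check_proportion(cfg$item_missing_rate, "item_missing_rate")
  if (any(cfg$dose_uptake < 0 | cfg$dose_uptake > 1))
    stopf("dose_uptake entries must lie in [0, 1]")
  invisible(cfg)
}

# Per-respondent deficit linear predictor (excluding u).
deficit_lp <- function(cfg, band_idx, female, quintile) {
  cfg$alpha + cfg$gamma_age[band_idx] + cfg$gamma_sex * female +
    cfg$gamma_imd[quintile]
}

# Age-graded item missingness rates, mean item_missing_rate across bands.
missing_rate_by_band <- function(cfg) {
  cfg$item_missing_rate * (0.5 + (seq_len(9L) - 1) / 8)
}

# Response propensity on the logit scale, before calibration.
nr_linear <- function(cfg, band_idx, quintile) {
  cfg$nr_slope_age * (band_idx - 1) + cfg$nr_slope_imd * (quintile - 1)
}

# Calibrate the response-propensity intercept so that the expected response
# rate over the drawn covariates equals 1 - nonresponse_target.
calibrate_response_intercept <- function(cfg, eta) {
  target <- 1 - cfg$nonresponse_target
  if (cfg$nonresponse_target == 0) return(Inf)
  f <- function(c0) mean(expit(c0 + eta)) - target
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-12)$root
}

#' Generate synthetic survey microdata with known truth
#'
#' Draws `n_respondents` individuals (age band, sex, IMD quintile), their
#' latent propensities and deficit items, then applies non-response and
#' age-graded item missingness. The returned survey contains the responders
#' only, with inverse-propensity weights rescaled to mean 1.
#'
#' @param config A [generator_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{survey}{data.frame of responders: `id`, `age_band`, `sex`,
#'       `imd_quintile`, `weight`, and one 0/1 column per deficit item
#'       (`NA` where missing).}
#'     \item{truth}{a `simulation_truth` list: the config, the analytic
#'       stratum probability table ([stratum_truth()]), the complete
#'       pre-missingness responder table, the realised non-response
#'       fraction, and the full sample before non-response.}
#'   }
#' @export
generate_survey <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  n <- cfg$n_respondents
  D <- cfg$n_deficits
  set.seed(derive_seed(cfg$seed, 1L))

  band_idx <- sample.int(9L, n, replace = TRUE,
                         prob = cfg$age_dist / sum(cfg$age_dist))
  female <- stats::rbinom(n, 1L, 0.5)
  quintile <- sample.int(5L, n, replace = TRUE)
  u <- if (cfg$sigma_u > 0) stats::rnorm(n, 0, cfg$sigma_u) else numeric(n)
  pi_i <- expit(deficit_lp(cfg, band_idx, female, quintile) + u)

  deficits <- matrix(stats::rbinom(n * D, 1L, rep(pi_i, D)), nrow = n)
  colnames(deficits) <- sprintf("deficit_%03d", seq_len(D))

  eta_nr <- nr_linear(cfg, band_idx, quintile)
  c0 <- calibrate_response_intercept(cfg, eta_nr)
  p_resp <- if (is.infinite(c0)) rep(1, n) else expit(c0 + eta_nr)
  responded <- stats::runif(n) < p_resp

  full <- data.frame(id = sprintf("R%06d", seq_len(n)),
                     age_band = age_bands()[band_idx],
                     sex = sex_levels()[2L - female],
                     imd_quintile = quintile,
                     response_propensity = p_resp,
                     stringsAsFactors = FALSE)
  full <- cbind(full, as.data.frame(deficits))

  survey <- full[responded, , drop = FALSE]
  w <- 1 / survey$response_propensity
  survey$weight <- w / mean(w)
  survey$response_propensity <- NULL
  survey <- survey[, c("id", "age_band", "sex", "imd_quintile", "weight",
                       colnames(deficits))]
  rownames(survey) <- NULL
  complete_survey <- survey

  # age-graded MAR missingness among responders
  if (cfg$item_missing_rate > 0 && nrow(survey) > 0) {
    rates <- missing_rate_by_band(cfg)
    r_i <- rates[match(survey$age_band, age_bands())]
    miss <- matrix(stats::runif(nrow(survey) * D), nrow = nrow(survey)) <
      matrix(r_i, nrow(survey), D)
    dm <- as.matrix(survey[, colnames(deficits)])
    dm[miss] <- NA_integer_
    survey[, colnames(deficits)] <- dm
  }

  truth <- structure(list(
    config = cfg,
    stratum_probs = stratum_truth(cfg),
    complete_survey = complete_survey,
    full_sample = full,
    nonresponse_realized = 1 - mean(responded)
  ), class = "simulation_truth")

  list(survey = survey, truth = truth)
}

# Binomial deficit-count thresholds implied by score cut-points.
count_cuts <- function(D, cuts) {
  c(k_robust = floor(cuts$robust_max * D + 1e-9),
    k_prefrail = floor(cuts$prefrail_max * D + 1e-9))
}

#' Analytic stratum category probabilities under the generator
#'
#' Integrates the generative model exactly (Gaussian quadrature over the
#' latent propensity, binomial category tails given the propensity) to give
#' the true probability of robust / pre-frail / frail in each of the 90
#' (age band, sex, IMD quintile) strata. This is the generator's own
#' expectation; [oracle_stratum_probs()] is the independent Monte-Carlo
#' route to the same table.
#'
#' @param config A [generator_config()].
#' @param cuts Category [cut_points()].
#' @return A stratum probability table: `age_band`, `sex`, `imd_quintile`,
#'   `p_robust`, `p_prefrail`, `p_frail` (90 rows; each row sums to 1).
#' @export
stratum_truth <- function(config = generator_config(), cuts = cut_points()) {
  cfg <- validate_generator_config(config)
  D <- cfg$n_deficits
  ks <- count_cuts(D, cuts)
  g <- stratum_grid()
  band_idx <- match(g$age_band, age_bands())
  female <- as.integer(g$sex == "female")
  lp <- deficit_lp(cfg, band_idx, female, g$imd_quintile)

  tail_prob <- function(lp_j, k) {
    if (cfg$sigma_u == 0) return(stats::pbinom(k, D, expit(lp_j)))
    f <- function(u) stats::pbinom(k, D, expit(lp_j + u)) *
      stats::dnorm(u, 0, cfg$sigma_u)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10,
                     abs.tol = 1e-12)$value
  }
  c1 <- vapply(lp, tail_prob, 0, k = ks[["k_robust"]])
  c2 <- vapply(lp, tail_prob, 0, k = ks[["k_prefrail"]])
  data.frame(g, p_robust = c1, p_prefrail = c2 - c1, p_frail = 1 - c2)
}

#' Monte-Carlo oracle for stratum category probabilities
#'
#' Brute-force reference: simulates `n_mc` respondents per stratum from the
#' generative model, scores them with the frailty index and cut-points, and
#' returns the empirical category proportions. Used as ground truth in
#' parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @param n_mc Simulated respondents per stratum (>= 1e4).
#' @param cuts Category [cut_points()].
#' @return A stratum probability table as in [stratum_truth()].
#' @export
oracle_stratum_probs <- function(config = generator_config(), n_mc = 1e5,
                                 cuts = cut_points()) {
  cfg <- validate_generator_config(config)
  if (n_mc < 1e4) stopf("n_mc must be >= 1e4")
  D <- cfg$n_deficits
  set.seed(derive_seed(cfg$seed, 2L))
  g <- stratum_grid()
  band_idx <- match(g$age_band, age_bands())
  female <- as.integer(g$sex == "female")
  lp <- deficit_lp(cfg, band_idx, female, g$imd_quintile)
  lv <- frailty_levels()
  out <- matrix(0, nrow(g), 3L, dimnames = list(NULL, lv))
  for (j in seq_len(nrow(g))) {
    u <- if (cfg$sigma_u > 0) stats::rnorm(n_mc, 0, cfg$sigma_u) else
      numeric(n_mc)
    cnt <- stats::rbinom(n_mc, D, expit(lp[j] + u))
    cat_j <- frailty_categorize(cnt / D, cuts)
    out[j, ] <- tabulate(cat_j, 3L) / n_mc
  }
  data.frame(g, p_robust = out[, 1L], p_prefrail = out[, 2L],
             p_frail = out[, 3L])
}

#' Generate synthetic area, vaccination and risk-factor tables
#'
#' Areas receive an IMD rank (a permutation of 1..n_areas, 1 = most
#' deprived), log-normally distributed age-sex population counts, first
#' doses allocated proportional to population times per-age-band uptake
#' (frailty-blind, emulating an age-based roll-out), and risk-factor
#' diagnosis counts with deprivation-correlated prevalence.
#'
#' @param config A [generator_config()].
#' @return A list with data.frames `areas` (`area_id`, `name`, `imd_rank`,
#'   `imd_quintile`, `age_band`, `sex`, `population`; 18 rows per area),
#'   `doses` (`area_id`, `doses`) and `risk_factors` (`area_id`, `factor`,
#'   `count`, long format).
#' @export
generate_areas <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  nA <- cfg$n_areas
  set.seed(derive_seed(cfg$seed, 3L))

  area_id <- sprintf("A%03d", seq_len(nA))
  imd_rank <- sample.int(nA)
  quintile <- imd_rank_to_quintile(imd_rank, nA)

  # area size ~ log-normal; cells follow the age distribution with noise
  size <- stats::rlnorm(nA, meanlog = log(6e4), sdlog = 0.35)
  age_p <- cfg$age_dist / sum(cfg$age_dist)
  cells <- expand.grid(sex = sex_levels(), age_band = age_bands(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", nA)
  for (c_i in seq_len(nA)) {
    mu <- size[c_i] * 0.5 * age_p[match(cells$age_band, age_bands())]
    pop <- round(mu * stats::rlnorm(nrow(cells), 0, 0.08))
    rows[[c_i]] <- data.frame(area_id = area_id[c_i], name = area_id[c_i],
                              imd_rank = imd_rank[c_i],
                              imd_quintile = quintile[c_i],
                              age_band = cells$age_band, sex = cells$sex,
                              population = pop, stringsAsFactors = FALSE)
  }
  areas <- do.call(rbind, rows)
  rownames(areas) <- NULL

  # frailty-blind dose allocation: population x per-band uptake
  upt <- cfg$dose_uptake[match(areas$age_band, age_bands())]
  dose_by_area <- tapply(areas$population * upt, areas$area_id, sum)
  doses <- data.frame(area_id = names(dose_by_area),
                      doses = round(as.numeric(dose_by_area)),
                      stringsAsFactors = FALSE)
  doses <- doses[match(area_id, doses$area_id), ]
  rownames(doses) <- NULL

  # deprivation-correlated risk-factor prevalence among the 50+ population
  base_prev <- c(atrial_fibrillation = 0.04, chronic_kidney_disease = 0.09,
                 diabetes = 0.12, learning_disabilities = 0.01,
                 obesity = 0.20, smoking_current = 0.12,
                 smoking_former = 0.30)
  pop50 <- tapply(areas$population, areas$area_id, sum)[area_id]
  rf <- expand.grid(area_id = area_id, factor = names(base_prev),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  q_a <- quintile[match(rf$area_id, area_id)]
  prev <- base_prev[rf$factor] * exp(cfg$rf_dep_log_rr * (3 - q_a)) *
    stats::rlnorm(nrow(rf), 0, 0.05)
  rf$count <- round(as.numeric(pop50[rf$area_id]) * prev)
  rf <- rf[order(rf$area_id, rf$factor), ]
  rownames(rf) <- NULL

  list(areas = areas, doses = doses, risk_factors = rf)
}

#' Default risk-factor names
#'
#' The seven primary-care risk factors carried by the synthetic generator:
#' atrial fibrillation, chronic kidney disease, diabetes, learning
#' disabilities, obesity, and smoking status split into current and former.
#'
#' @return Character vector of factor identifiers.
#' @export
risk_factor_names <- function() {
  c("atrial_fibrillation", "chronic_kidney_disease", "diabetes",
    "learning_disabilities", "obesity", "smoking_current", "smoking_former")
}
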