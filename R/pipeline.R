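# End-to-end orchestration: impute -> score -> fit -> pool -> predict ->
# post-stratify -> bootstrap -> ratios -> heatmap, with every intermediate
# artifact written to disk and all randomness derived from one seed.

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or in-memory
#' data frames.
#'
#' @param survey,areas,doses,risks Input tables or CSV paths.
#' @param schema A `deficit_schema`, or path to a YAML/JSON schema file.
#' @param cuts Category [cut_points()].
#' @param mice A [mice_config()]; its seed is overridden by `seed`.
#' @param B Bootstrap draws for area intervals (>= 100).
#' @param seed Master integer seed; every stage uses a derived sub-stream.
#' @param factors Risk-factor names for the diagnosis denominators.
#' @param out_dir Output directory; `NULL` skips writing artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(survey, areas, doses, risks,
                            schema = default_deficit_schema(),
                            cuts = cut_points(),
                            mice = mice_config(),
                            B = 1000L, seed = 1L,
                            factors = risk_factor_names(),
                            out_dir = NULL) {
  if (B < 100L) stopf("B must be >= 100")
  structure(list(survey = survey, areas = areas, doses = doses,
                 risks = risks, schema = schema, cuts = cuts, mice = mice,
                 B = as.integer(B), seed = as.integer(seed),
                 factors = factors, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full frailty-equity pipeline
#'
#' Executes impute, score, fit, Rubin-pool, stratum prediction,
#' post-stratification, bootstrap, equity ratios and the quintile heatmap,
#' writing every intermediate artifact to `out_dir` when set. Identical
#' configuration and seed give identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress?
#' @return List of class `pipeline_result`: completed surveys (`imputations`),
#'   per-imputation fits, `pooled` fit, `stratum_probs`, `area_estimates`,
#'   `ratios` (all denominator kinds, row-bound), `extreme` (factors for the
#'   frail and frail+pre-frail denominators and the over-50 point factor),
#'   `heatmap`, and a `log` with seeds, row counts and convergence
#'   diagnostics.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  survey <- stage("read_survey", resolve_input(cfg$survey, read_survey))
  areas <- stage("read_areas", resolve_input(cfg$areas, read_areas))
  doses <- stage("read_doses", resolve_input(cfg$doses, read_doses))
  risks <- stage("read_risks", resolve_input(cfg$risks, read_risk_factors))
  schema <- stage("read_schema",
                  resolve_input(cfg$schema, read_deficit_schema))

  mice_cfg <- cfg$mice
  mice_cfg$seed <- derive_seed(cfg$seed, 11L)
  say("imputing (m = %d) ...", mice_cfg$m)
  imputations <- stage("impute", mice_impute(survey, schema, mice_cfg))

  say("scoring and fitting %d imputations ...", length(imputations))
  fits <- stage("fit", lapply(imputations, function(tab) {
    frailty_po(data = score_survey(tab, schema, cfg$cuts))
  }))
  pooled <- stage("pool", pool_rubin(fits))
  probs <- stage("predict", predict_strata(pooled))

  say("post-stratifying onto %d areas ...", length(unique(areas$area_id)))
  est <- stage("bootstrap",
               bootstrap_area_cis(pooled, areas, B = cfg$B,
                                  seed = derive_seed(cfg$seed, 12L)))
  pt <- est$estimates

  say("computing equity ratios ...")
  den_frail <- data.frame(area_id = pt$area_id, frail = pt$frail)
  den_both <- data.frame(area_id = pt$area_id,
                         frail_plus_prefrail = pt$frail + pt$pre_frail)
  den_o50 <- data.frame(area_id = pt$area_id, over50 = pt$population_50plus)
  draws_frail <- est$draws$frail
  draws_both <- est$draws$frail + est$draws$pre_frail

  r_frail <- dose_ratio_table(doses, den_frail, "frail", draws_frail)
  r_both <- dose_ratio_table(doses, den_both, "frail_plus_prefrail",
                             draws_both)
  r_o50 <- dose_ratio_table(doses, den_o50, "over50")
  r_total <- total_risk_diagnoses_ratio(doses, risks, cfg$factors)
  r_fac <- do.call(rbind, lapply(cfg$factors, function(f) {
    sub <- risks[risks$factor == f, c("area_id", "count")]
    names(sub)[2L] <- f
    dose_ratio_table(doses, sub, f, denominator_kind = paste0("per_", f))
  }))
  ratios <- rbind(r_frail, r_both, r_o50, r_total, r_fac)

  dose_vec <- doses$doses[match(colnames(draws_frail), doses$area_id)]
  rd_frail <- sweep(1 / draws_frail, 2L, dose_vec, `*`)
  rd_both <- sweep(1 / draws_both, 2L, dose_vec, `*`)
  extreme <- list(
    frail = extreme_factor(r_frail, rd_frail),
    frail_plus_prefrail = extreme_factor(r_both, rd_both),
    over50 = extreme_factor(r_o50)
  )

  metrics <- list()
  for (f in cfg$factors) {
    rr <- r_fac[r_fac$denominator_kind == paste0("per_", f), ]
    metrics[[f]] <- stats::setNames(rr$ratio, rr$area_id)
  }
  metrics$frail <- stats::setNames(r_frail$ratio, r_frail$area_id)
  metrics$pre_frail <- stats::setNames(
    doses$doses[match(pt$area_id, doses$area_id)] / pt$pre_frail, pt$area_id)
  metrics$over50 <- stats::setNames(r_o50$ratio, r_o50$area_id)
  depr <- stats::setNames(pt$imd_quintile, pt$area_id)
  heat <- stage("heatmap", heatmap_table(metrics, depr, order_by = "over50"))

  log <- list(
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("frailmap")),
    seed = cfg$seed,
    seeds = list(mice = mice_cfg$seed, bootstrap = derive_seed(cfg$seed, 12L)),
    n_respondents = nrow(survey),
    n_missing_cells = sum(is.na(survey[, schema_names(schema)])),
    m = mice_cfg$m, B = cfg$B,
    n_areas = length(unique(areas$area_id)),
    fit = list(logLik = pooled$template$logLik,
               grad_norm = pooled$template$grad_norm,
               converged = all(vapply(fits, `[[`, TRUE, "converged")))
  )

  res <- structure(list(imputations = imputations, fits = fits,
                        pooled = pooled, stratum_probs = probs,
                        area_estimates = est, ratios = ratios,
                        extreme = extreme, heatmap = heat, log = log),
                   class = "pipeline_result")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(imputations))
      write_table_csv(imputations[[k]],
                      file.path(cfg$out_dir, sprintf("survey_imp_%d.csv", k)))
    write_table_csv(probs, file.path(cfg$out_dir, "stratum_probs.csv"))
    est_long <- stats::reshape(
      pt, direction = "long",
      varying = list(c("robust", "pre_frail", "frail"),
                     c("robust_lo", "pre_frail_lo", "frail_lo"),
                     c("robust_hi", "pre_frail_hi", "frail_hi")),
      v.names = c("expected", "ci_lo", "ci_hi"),
      times = c("robust", "pre_frail", "frail"), timevar = "category",
      idvar = "area_id",
      drop = c("imd_rank", "imd_quintile", "population_50plus"))
    rownames(est_long) <- NULL
    write_table_csv(est_long, file.path(cfg$out_dir, "area_estimates.csv"))
    write_table_csv(ratios, file.path(cfg$out_dir, "ratios.csv"))
    write_table_csv(heat$table, file.path(cfg$out_dir, "heatmap.csv"))
    jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  say("done.")
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Frailty-equity pipeline result\n")
  cat(sprintf("  %d respondents, %d imputations, %d areas, B = %d\n",
              x$log$n_respondents, x$log$m, x$log$n_areas, x$log$B))
  cat(sprintf("  doses per frail person: extreme factor %.1f (%.1f-%.1f)\n",
              x$extreme$frail$factor, x$extreme$frail$ci_lo,
              x$extreme$frail$ci_hi))
  invisible(x)
}
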