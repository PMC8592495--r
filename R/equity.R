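# Dose-per-denominator equity ratios, extreme-ratio factors, risk-factor
# ratios and quintile heatmap tables.

#' Dose-per-denominator equity ratio
#'
#' The ratio of first vaccine doses administered to the size of an at-risk
#' denominator (e.g. the estimated frail population). When bootstrap draws
#' of the denominator are supplied, the interval is formed from the
#' percentiles of `doses / draw` with the dose count held fixed; fixed
#' denominators (e.g. the over-50 population) carry no interval.
#'
#' @param doses Non-negative dose count.
#' @param denominator_point Positive denominator point estimate.
#' @param denominator_draws Optional vector of positive bootstrap draws of
#'   the denominator.
#' @param denominator_kind Label recorded with the ratio.
#' @param area_id Optional area identifier.
#' @param level Confidence level for the percentile interval.
#' @return A one-row data.frame: `area_id`, `denominator_kind`, `doses`,
#'   `denominator`, `ratio`, `ci_lo`, `ci_hi` (NA when no draws).
#' @export
dose_ratio <- function(doses, denominator_point, denominator_draws = NULL,
                       denominator_kind = "frail", area_id = NA_character_,
                       level = 0.95) {
  if (doses < 0) stopf("doses must be >= 0")
  if (!is.finite(denominator_point) || denominator_point <= 0)
    stopf("denominator must be > 0")
  ratio <- doses / denominator_point
  ci <- c(NA_real_, NA_real_)
  if (!is.null(denominator_draws)) {
    if (any(!is.finite(denominator_draws) | denominator_draws <= 0))
      stopf("all denominator draws must be > 0")
    rd <- doses / denominator_draws
    alpha <- (1 - level) / 2
    ci <- stats::quantile(rd, c(alpha, 1 - alpha), names = FALSE)
  }
  data.frame(area_id = area_id, denominator_kind = denominator_kind,
             doses = doses, denominator = denominator_point, ratio = ratio,
             ci_lo = ci[1L], ci_hi = ci[2L], stringsAsFactors = FALSE)
}

#' Equity ratios for every area
#'
#' Convenience wrapper applying [dose_ratio()] area by area against a
#' common denominator column, optionally with per-area bootstrap draws.
#'
#' @param doses Data frame `area_id`, `doses`.
#' @param denominators Data frame `area_id` plus a column named by
#'   `denominator_col`.
#' @param denominator_col Name of the denominator column.
#' @param draws Optional B x n_areas matrix of denominator draws with
#'   column names matching `area_id`.
#' @param denominator_kind Label recorded with the ratios.
#' @param level Confidence level.
#' @return Data frame of one [dose_ratio()] row per area.
#' @export
dose_ratio_table <- function(doses, denominators, denominator_col,
                             draws = NULL, denominator_kind = denominator_col,
                             level = 0.95) {
  idx <- match(doses$area_id, denominators$area_id)
  if (anyNA(idx))
    stopf("area '%s' has no denominator", doses$area_id[which(is.na(idx))[1L]])
  out <- lapply(seq_len(nrow(doses)), function(i) {
    a <- doses$area_id[i]
    dr <- if (!is.null(draws)) draws[, a] else NULL
    dose_ratio(doses$doses[i], denominators[[denominator_col]][idx[i]],
               denominator_draws = dr, denominator_kind = denominator_kind,
               area_id = a, level = level)
  })
  do.call(rbind, out)
}

#' Extreme-ratio factor between the best- and worst-served areas
#'
#' The maximum area ratio divided by the minimum. With joint bootstrap
#' draws the factor is recomputed per draw (the arg-max and arg-min areas
#' are free to vary across draws) and a percentile interval reported.
#' `display` carries the 1-decimal presentation value; full precision is
#' retained in `factor`.
#'
#' @param records Data frame of per-area ratios (as from
#'   [dose_ratio_table()]).
#' @param ratio_draws Optional B x n_areas matrix of per-draw ratios,
#'   columns named by area.
#' @param level Confidence level.
#' @return List of class `extreme_factor`: `factor`, `display`,
#'   `max_area`, `min_area`, `ci_lo`, `ci_hi`.
#' @export
extreme_factor <- function(records, ratio_draws = NULL, level = 0.95) {
  if (nrow(records) < 2L) stopf("need ratios from at least two areas")
  if (any(records$ratio <= 0)) stopf("all ratios must be > 0")
  i_max <- which.max(records$ratio)
  i_min <- which.min(records$ratio)
  fac <- records$ratio[i_max] / records$ratio[i_min]
  ci <- c(NA_real_, NA_real_)
  if (!is.null(ratio_draws)) {
    fac_b <- apply(ratio_draws, 1L, function(r) max(r) / min(r))
    alpha <- (1 - level) / 2
    ci <- stats::quantile(fac_b, c(alpha, 1 - alpha), names = FALSE)
  }
  structure(list(factor = fac, display = round(fac, 1L),
                 max_area = records$area_id[i_max],
                 min_area = records$area_id[i_min],
                 ci_lo = ci[1L], ci_hi = ci[2L]),
            class = "extreme_factor")
}

#' @export
print.extreme_factor <- function(x, ...) {
  ci <- if (is.na(x$ci_lo)) "" else
    sprintf(" (%.1f-%.1f)", x$ci_lo, x$ci_hi)
  cat(sprintf("Extreme-ratio factor: %.1f%s  [max %s / min %s]\n",
              x$display, ci, x$max_area, x$min_area))
  invisible(x)
}

#' Doses per total risk-factor diagnosis
#'
#' Per-area ratio of first doses to the summed diagnosed counts over the
#' configured factor set. A person with several risk factors is counted
#' once per diagnosis in the denominator.
#'
#' @param doses Data frame `area_id`, `doses`.
#' @param risks Long data frame `area_id`, `factor`, `count`.
#' @param factors Factor names to include (default: all seven generator
#'   factors, excluding frailty categories).
#' @return Data frame of one ratio row per area
#'   (`denominator_kind = "total_risk_diagnoses"`).
#' @export
total_risk_diagnoses_ratio <- function(doses, risks,
                                       factors = risk_factor_names()) {
  if (length(factors) == 0L) stopf("the factor set must not be empty")
  sub <- risks[risks$factor %in% factors, , drop = FALSE]
  tot <- tapply(sub$count, sub$area_id, sum)
  idx <- match(doses$area_id, names(tot))
  if (anyNA(idx))
    stopf("area '%s' is absent from the risk-factor table",
          doses$area_id[which(is.na(idx))[1L]])
  out <- lapply(seq_len(nrow(doses)), function(i) {
    dose_ratio(doses$doses[i], as.numeric(tot[idx[i]]),
               denominator_kind = "total_risk_diagnoses",
               area_id = doses$area_id[i])
  })
  do.call(rbind, out)
}

#' Assign areas to quintiles of a metric
#'
#' Areas are ranked by advantage and split into five groups of as-equal-as
#' possible size (sizes differ by at most one; larger groups go to the
#' earlier, less-advantaged quintiles). Quintile 5 is the most advantaged;
#' ties are broken by area id.
#'
#' @param values Named numeric vector (names = area ids) or unnamed with
#'   `ids` supplied.
#' @param larger_is_advantaged Does a larger value mean more advantaged?
#' @param ids Area ids when `values` is unnamed.
#' @return Named integer vector of quintiles 1..5, in input order.
#' @export
assign_quintiles <- function(values, larger_is_advantaged = TRUE,
                             ids = names(values)) {
  n <- length(values)
  if (n < 5L) stopf("need at least five areas")
  if (any(!is.finite(values))) stopf("values must be finite (no NaN/NA)")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sizes <- rep(n %/% 5L, 5L)
  extra <- n %% 5L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  adv <- if (larger_is_advantaged) values else -values
  ord <- order(adv, ids)          # least advantaged first; ties by id
  q <- rep(seq_len(5L), times = sizes)
  out <- integer(n)
  out[ord] <- q
  names(out) <- ids
  out
}

#' Quintile heatmap table across metrics
#'
#' One row per area, one quintile column per metric (each computed with
#' [assign_quintiles()]), plus the area's deprivation quintile. Also
#' returns the ten best and ten worst areas by the ordering metric,
#' mirroring a top/bottom heatmap presentation.
#'
#' @param metrics Named list of per-area numeric vectors (names = area
#'   ids); every metric must cover the same area set.
#' @param deprivation Named integer vector of deprivation quintiles per
#'   area (1 = most deprived).
#' @param order_by Name of the metric used to order rows and select the
#'   top/bottom subsets (default: first metric).
#' @return List of class `quintile_heatmap`: `table` (full wide table,
#'   most advantaged first), `top10`, `bottom10`.
#' @export
heatmap_table <- function(metrics, deprivation,
                          order_by = names(metrics)[1L]) {
  if (length(metrics) == 0L) stopf("need at least one metric")
  ids <- sort(names(metrics[[1L]]))
  for (mname in names(metrics)) {
    if (!setequal(names(metrics[[mname]]), ids))
      stopf("metric '%s' covers a different area set", mname)
  }
  if (!setequal(names(deprivation), ids))
    stopf("deprivation quintiles cover a different area set")
  tab <- data.frame(area_id = ids, stringsAsFactors = FALSE)
  for (mname in sort(names(metrics))) {
    q <- assign_quintiles(metrics[[mname]][ids])
    tab[[paste0("q_", mname)]] <- as.integer(q)
  }
  tab$imd_quintile <- as.integer(deprivation[ids])
  ord_vals <- metrics[[order_by]][ids]
  tab <- tab[order(-ord_vals, ids), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 top10 = utils::head(tab, 10L),
                 bottom10 = utils::tail(tab, 10L),
                 order_by = order_by),
            class = "quintile_heatmap")
}

#' @export
print.quintile_heatmap <- function(x, ...) {
  cat(sprintf("Quintile heatmap over %d areas (ordered by %s)\n",
              nrow(x$table), x$order_by))
  print(utils::head(x$table))
  if (nrow(x$table) > 6L) cat("...\n")
  invisible(x)
}
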