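# Post-stratification of stratum probabilities onto area population tables,
# and parametric-bootstrap uncertainty for the resulting category counts.

#' Deprivation quintile from an IMD rank
#'
#' `quintile = ceiling(5 * rank / n_areas)`; rank 1 (most deprived) maps to
#' quintile 1.
#'
#' @param rank Integer rank(s) in 1..n_areas.
#' @param n_areas Number of ranked areas.
#' @return Integer quintile(s) in 1..5.
#' @export
imd_rank_to_quintile <- function(rank, n_areas) {
  if (any(rank < 1L | rank > n_areas)) stopf("rank out of range 1..%d", n_areas)
  as.integer(ceiling(5 * rank / n_areas))
}

validate_area_table <- function(areas) {
  need <- c("area_id", "imd_rank", "imd_quintile", "age_band", "sex",
            "population")
  miss <- setdiff(need, names(areas))
  if (length(miss))
    stopf("area table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(areas$population < 0)) stopf("population counts must be >= 0")
  ranks <- unique(areas[, c("area_id", "imd_rank")])
  if (!setequal(ranks$imd_rank, seq_len(nrow(ranks))))
    stopf("imd_rank values must form a permutation of 1..n_areas")
  invisible(areas)
}

# population matrix: one row per area, one column per stratum of
# stratum_grid(), using each area's deprivation quintile
area_stratum_matrix <- function(areas) {
  validate_area_table(areas)
  g <- stratum_grid()
  gk <- stratum_key(g$age_band, g$sex, g$imd_quintile)
  ids <- unique(areas$area_id)
  M <- matrix(0, length(ids), nrow(g), dimnames = list(ids, gk))
  ak <- stratum_key(areas$age_band, areas$sex, areas$imd_quintile)
  col <- match(ak, gk)
  if (anyNA(col)) stopf("unknown age band or sex label in area table")
  row <- match(areas$area_id, ids)
  for (i in seq_len(nrow(areas)))
    M[row[i], col[i]] <- M[row[i], col[i]] + areas$population[i]
  M
}

probs_matrix <- function(probs) {
  g <- stratum_grid()
  gk <- stratum_key(g$age_band, g$sex, g$imd_quintile)
  pk <- stratum_key(probs$age_band, probs$sex, probs$imd_quintile)
  idx <- match(gk, pk)
  if (anyNA(idx))
    stopf("stratum probability table is missing stratum %s",
          gk[which(is.na(idx))[1L]])
  P <- as.matrix(probs[idx, c("p_robust", "p_prefrail", "p_frail")])
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stopf("stratum probabilities must be non-negative and sum to 1")
  P
}

#' Post-stratify stratum probabilities onto area populations
#'
#' Expected category counts per area:
#' \eqn{E[N_{c,k}] = \sum_{a,s} N_{c,a,s}\, p_k(a, s, q(c))}, where the
#' area's deprivation quintile selects the probability row. Deterministic;
#' counts in each area sum exactly to its 50+ population.
#'
#' @param probs Stratum probability table (see [predict_strata()]).
#' @param areas Long-format area table (`area_id`, `imd_rank`,
#'   `imd_quintile`, `age_band`, `sex`, `population`).
#' @return Data frame: `area_id`, `imd_rank`, `imd_quintile`,
#'   `population_50plus`, `robust`, `pre_frail`, `frail`.
#' @export
post_stratify <- function(probs, areas) {
  M <- area_stratum_matrix(areas)
  P <- probs_matrix(probs)
  cnt <- M %*% P
  meta <- unique(areas[, c("area_id", "imd_rank", "imd_quintile")])
  meta <- meta[match(rownames(M), meta$area_id), ]
  data.frame(area_id = rownames(M),
             imd_rank = meta$imd_rank,
             imd_quintile = meta$imd_quintile,
             population_50plus = rowSums(M),
             robust = cnt[, 1L], pre_frail = cnt[, 2L], frail = cnt[, 3L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Area frailty estimates with parametric-bootstrap confidence intervals
#'
#' Draws coefficient vectors from the (pooled) fit's multivariate-normal
#' sampling distribution, recomputes stratum probabilities and area counts
#' for every draw, and reports percentile 95% intervals. The draws are
#' retained so downstream ratio intervals can reuse the joint uncertainty.
#'
#' @param fit A `frailty_po` or `frailty_po_pooled` object.
#' @param areas Long-format area table.
#' @param B Number of bootstrap draws (>= 100; default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return An object of class `area_frailty_estimate`: a list with
#'   `estimates` (data.frame with point estimates and `*_lo` / `*_hi`
#'   bounds per category) and `draws` (list of B x n_areas matrices per
#'   category, areas in column order of `estimates$area_id`).
#' @export
bootstrap_area_cis <- function(fit, areas, B = 1000L, seed = 1L,
                               level = 0.95) {
  if (B < 100L) stopf("B must be >= 100")
  M <- area_stratum_matrix(areas)
  point <- post_stratify(stratum_probs_of(fit), areas)
  dr <- draw_coefs(fit, B, seed)
  tmpl <- if (inherits(fit, "frailty_po_pooled")) fit$template else fit
  X <- po_design(tmpl, stratum_grid())
  K <- length(tmpl$levels)
  nA <- nrow(M)
  arr <- lapply(1:3, function(k) matrix(NA_real_, B, nA,
                                        dimnames = list(NULL, rownames(M))))
  for (b in seq_len(B)) {
    P <- po_probs_from_par(dr[b, ], X, K)
    cnt <- M %*% P
    for (k in 1:3) arr[[k]][b, ] <- cnt[, k]
  }
  names(arr) <- c("robust", "pre_frail", "frail")
  alpha <- (1 - level) / 2
  for (k in names(arr)) {
    qs <- apply(arr[[k]], 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    point[[paste0(k, "_lo")]] <- qs[1L, ]
    point[[paste0(k, "_hi")]] <- qs[2L, ]
  }
  structure(list(estimates = point, draws = arr, B = B, seed = seed,
                 level = level),
            class = "area_frailty_estimate")
}

# stratum probabilities from whatever carries them
stratum_probs_of <- function(fit) {
  if (inherits(fit, c("frailty_po", "frailty_po_pooled")))
    return(predict_strata(fit))
  if (is.data.frame(fit)) return(fit)
  stopf("cannot extract stratum probabilities from a '%s'", class(fit)[1L])
}

#' @export
print.area_frailty_estimate <- function(x, ...) {
  cat(sprintf("Area frailty estimates for %d areas (B = %d bootstrap draws)\n",
              nrow(x$estimates), x$B))
  print(utils::head(x$estimates))
  if (nrow(x$estimates) > 6L) cat("...\n")
  invisible(x)
}
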