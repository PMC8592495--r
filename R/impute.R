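# Multiple imputation by chained equations for missing deficit items.
#
# Each incomplete item is imputed from age band, sex, IMD quintile and the
# other deficit items. Binary items use a ridge-penalised logistic model
# (the penalty keeps separation in sparse strata estimable) with parameter
# draws from the approximate posterior; graded items use predictive-mean
# matching on a ridge linear model. Observed cells are never altered.

#' Configuration for chained-equations imputation
#'
#' @param m Number of completed datasets (default 10).
#' @param n_iter Chained sweeps per imputation (default 10).
#' @param seed Integer seed; imputations use independent sub-streams.
#' @param ridge Ridge penalty applied to every per-item regression. The
#'   default 0.1 keeps separated strata estimable with stable posterior
#'   draws; it is never applied to the intercept.
#' @param pmm_k Donor pool size for predictive-mean matching.
#' @return An object of class `mice_config`.
#' @export
mice_config <- function(m = 10L, n_iter = 10L, seed = 1L, ridge = 0.1,
                        pmm_k = 5L) {
  if (m < 1L) stopf("m must be >= 1")
  if (n_iter < 1L) stopf("n_iter must be >= 1")
  if (ridge <= 0) stopf("ridge must be > 0")
  structure(list(m = as.integer(m), n_iter = as.integer(n_iter),
                 seed = as.integer(seed), ridge = ridge,
                 pmm_k = as.integer(pmm_k)),
            class = "mice_config")
}

# ridge-penalised IRLS logistic fit; returns list(beta, cov)
ridge_logistic <- function(X, y, lambda) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  pen[1L, 1L] <- 0  # never penalise the intercept
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    wq <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wq
    A <- crossprod(X, X * wq) + pen
    beta_new <- solve(A, crossprod(X, wq * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- expit(eta)
  wq <- pmax(mu * (1 - mu), 1e-10)
  A <- crossprod(X, X * wq) + pen
  list(beta = drop(beta), cov = solve(A))
}

ridge_linear <- function(X, y, lambda) {
  p <- ncol(X)
  pen <- diag(lambda, p)
  pen[1L, 1L] <- 0
  A <- crossprod(X) + pen
  beta <- solve(A, crossprod(X, y))
  res <- y - drop(X %*% beta)
  s2 <- sum(res^2) / max(length(y) - p, 1L)
  list(beta = drop(beta), cov = s2 * solve(A), sigma2 = s2)
}

mvn_draw <- function(beta, V) {
  V <- (V + t(V)) / 2
  R <- tryCatch(chol(V), error = function(e)
    chol(V + diag(1e-10 * max(diag(V)) + 1e-12, nrow(V))))
  drop(beta + t(R) %*% stats::rnorm(length(beta)))
}

# covariate design shared by every item model
mice_base_design <- function(survey) {
  df <- po_canonical_factors(survey[, c("age_band", "sex", "imd_quintile")])
  stats::model.matrix(~ age_band + sex + imd_quintile, df)
}

#' Multiple imputation by chained equations for deficit items
#'
#' Fills missing deficit cells with `m` stochastic imputations. Item models
#' regress each incomplete item on age band, sex, IMD quintile and all
#' other deficit items; sweeps visit items in schema order `n_iter` times.
#' Missing cells are initialised by sampling observed values of the item.
#'
#' @param survey Survey data.frame; `age_band`, `sex`, `imd_quintile` must
#'   be fully observed, missingness confined to deficit columns.
#' @param schema A `deficit_schema` naming the deficit columns.
#' @param cfg A [mice_config()].
#' @return A list of `m` complete data.frames; observed cells identical to
#'   the input.
#' @export
mice_impute <- function(survey, schema = default_deficit_schema(),
                        cfg = mice_config()) {
  nm <- schema_names(schema)
  missing_cols <- setdiff(nm, names(survey))
  if (length(missing_cols))
    stopf("survey lacks deficit columns: %s",
          paste(missing_cols, collapse = ", "))
  if (anyNA(survey$age_band) || anyNA(survey$sex) ||
      anyNA(survey$imd_quintile))
    stopf("age_band, sex and imd_quintile must be fully observed")
  D <- length(nm)
  Y <- as.matrix(survey[, nm, drop = FALSE])
  storage.mode(Y) <- "double"
  na_mask <- is.na(Y)
  all_missing <- colSums(!na_mask) == 0L
  if (any(all_missing))
    stopf("deficit item '%s' is missing for every respondent; it cannot be imputed",
          nm[which(all_missing)[1L]])
  kinds <- vapply(schema$items, `[[`, "", "kind")

  if (!any(na_mask)) {
    return(replicate(cfg$m, survey, simplify = FALSE))
  }

  Xbase <- mice_base_design(survey)
  out <- vector("list", cfg$m)
  for (imp in seq_len(cfg$m)) {
    set.seed(derive_seed(cfg$seed, 100L + imp))
    Yc <- Y
    # initialise by sampling observed values per item
    for (j in which(colSums(na_mask) > 0L)) {
      obs <- Yc[!na_mask[, j], j]
      Yc[na_mask[, j], j] <- sample(obs, sum(na_mask[, j]), replace = TRUE)
    }
    for (sweep in seq_len(cfg$n_iter)) {
      for (j in which(colSums(na_mask) > 0L)) {
        mis <- na_mask[, j]
        X <- cbind(Xbase, Yc[, -j, drop = FALSE])
        yobs <- Y[!mis, j]
        if (kinds[j] == "binary") {
          if (length(unique(yobs)) == 1L) {
            # degenerate observed margin: impute the constant
            Yc[mis, j] <- yobs[1L]
            next
          }
          fit <- ridge_logistic(X[!mis, , drop = FALSE], yobs, cfg$ridge)
          bstar <- mvn_draw(fit$beta, fit$cov)
          pmis <- expit(drop(X[mis, , drop = FALSE] %*% bstar))
          Yc[mis, j] <- stats::rbinom(sum(mis), 1L, pmis)
        } else {
          fit <- ridge_linear(X[!mis, , drop = FALSE], yobs, cfg$ridge)
          bstar <- mvn_draw(fit$beta, fit$cov)
          pred_obs <- drop(X[!mis, , drop = FALSE] %*% fit$beta)
          pred_mis <- drop(X[mis, , drop = FALSE] %*% bstar)
          # predictive-mean matching against observed donors
          don <- vapply(pred_mis, function(pm) {
            d <- abs(pred_obs - pm)
            pool <- order(d)[seq_len(min(cfg$pmm_k, length(d)))]
            yobs[pool[sample.int(length(pool), 1L)]]
          }, numeric(1))
          Yc[mis, j] <- don
        }
      }
    }
    comp <- survey
    for (j in seq_along(nm)) {
      v <- Yc[, j]
      # keep the input column's storage type when values allow it
      if (is.integer(survey[[nm[j]]]) && all(v == round(v)))
        v <- as.integer(v)
      comp[[nm[j]]] <- v
    }
    out[[imp]] <- comp
  }
  out
}
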