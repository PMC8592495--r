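# Weighted proportional-odds (cumulative logit) regression.
#
# Parameterisation: P(Y <= k | x) = expit(theta_k - x'beta), so positive
# beta means a shift towards the frailer end of the scale. The weighted
# log-likelihood sum_i w_i log P(Y_i = y_i | x_i) is maximised by BFGS with
# the analytic gradient (thresholds kept ordered through a log-gap
# transform), then polished by damped Newton steps on the natural scale
# until the gradient max-norm is <= `tol`.

po_canonical_factors <- function(data) {
  if (!is.null(data$age_band) && !is.factor(data$age_band))
    data$age_band <- factor(data$age_band, levels = age_bands())
  if (!is.null(data$sex) && !is.factor(data$sex))
    data$sex <- factor(data$sex, levels = c("male", "female"))
  if (!is.null(data$imd_quintile) && !is.factor(data$imd_quintile))
    data$imd_quintile <- factor(data$imd_quintile, levels = 1:5)
  data
}

# negative weighted log-likelihood and analytic gradient in natural
# parameters c(beta, theta); X has no intercept column
po_nll <- function(par, X, y, w, K) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- par[p + seq_len(K - 1L)]
  if (is.unsorted(theta, strictly = TRUE)) return(Inf)
  eta <- drop(X %*% beta)
  up <- ifelse(y < K, expit(theta[pmin(y, K - 1L)] - eta), 1)
  lo <- ifelse(y > 1L, expit(theta[pmax(y - 1L, 1L)] - eta), 0)
  pr <- up - lo
  if (any(pr <= 0)) return(Inf)
  -sum(w * log(pr))
}

po_grad <- function(par, X, y, w, K) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- par[p + seq_len(K - 1L)]
  eta <- drop(X %*% beta)
  up <- ifelse(y < K, expit(theta[pmin(y, K - 1L)] - eta), 1)
  lo <- ifelse(y > 1L, expit(theta[pmax(y - 1L, 1L)] - eta), 0)
  pr <- up - lo
  g_up <- up * (1 - up) * (y < K)
  g_lo <- lo * (1 - lo) * (y > 1L)
  # d loglik / d eta, then chain to beta
  dl_eta <- -w * (g_up - g_lo) / pr
  g_beta <- drop(crossprod(X, dl_eta))
  g_theta <- numeric(K - 1L)
  contrib_up <- w * g_up / pr
  contrib_lo <- -w * g_lo / pr
  for (k in seq_len(K - 1L)) {
    g_theta[k] <- sum(contrib_up[y == k]) + sum(contrib_lo[y == k + 1L])
  }
  -c(g_beta, g_theta)
}

# per-observation score rows of the *weighted* log-likelihood (for the
# sandwich covariance)
po_scores <- function(par, X, y, w, K) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- par[p + seq_len(K - 1L)]
  eta <- drop(X %*% beta)
  up <- ifelse(y < K, expit(theta[pmin(y, K - 1L)] - eta), 1)
  lo <- ifelse(y > 1L, expit(theta[pmax(y - 1L, 1L)] - eta), 0)
  pr <- up - lo
  g_up <- up * (1 - up) * (y < K)
  g_lo <- lo * (1 - lo) * (y > 1L)
  S_beta <- X * (-w * (g_up - g_lo) / pr)
  S_theta <- matrix(0, length(y), K - 1L)
  for (k in seq_len(K - 1L)) {
    S_theta[y == k, k] <- (w * g_up / pr)[y == k]
    S_theta[y == k + 1L, k] <- (-w * g_lo / pr)[y == k + 1L]
  }
  cbind(S_beta, S_theta)
}

# transform: theta_1 = t_1, theta_k = t_1 + sum(exp(t_2..t_k))
theta_from_t <- function(t) cumsum(c(t[1L], exp(t[-1L])))
t_from_theta <- function(theta) c(theta[1L], log(diff(theta)))

#' Weighted proportional-odds regression of frailty category
#'
#' Fits the cumulative-logit model
#' \eqn{P(Y \le k \mid x) = \mathrm{expit}(\theta_k - x^\top\beta)} by
#' maximising the weighted log-likelihood
#' \eqn{\sum_i w_i \log P(Y_i = y_i \mid x_i)}. Categories are ordered
#' robust < pre-frail < frail; positive coefficients mean greater frailty.
#' `age_band`, `sex` and `imd_quintile` columns are indicator-coded with
#' references 50-54, male and quintile 1 (most deprived).
#'
#' @param formula Model formula; the response must be an ordered factor (or
#'   coercible via the scored `frailty_cat` column). Default
#'   `frailty_cat ~ age_band + sex + imd_quintile`.
#' @param data A scored survey data.frame (see [score_survey()]).
#' @param weights Positive case weights; defaults to the survey's `weight`
#'   column, or 1. Estimates are invariant to rescaling all weights.
#' @param vcov_type `"information"` (inverse observed information of the
#'   weighted likelihood, the default) or `"sandwich"`.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton polish iterations.
#' @return An object of class `frailty_po` with components `coefficients`
#'   (beta), `zeta` (ordered thresholds), `vcov` (over `c(beta, zeta)`),
#'   `logLik`, `n`, `sum_weights`, `converged`, `grad_norm` and the fitting
#'   frame metadata needed by [predict.frailty_po()].
#' @seealso [pool_rubin()], [predict_strata()], [lrt_interaction()]
#' @export
frailty_po <- function(formula = frailty_cat ~ age_band + sex + imd_quintile,
                       data, weights = NULL,
                       vcov_type = c("information", "sandwich"),
                       tol = 1e-8, max_iter = 50L) {
  vcov_type <- match.arg(vcov_type)
  data <- po_canonical_factors(as.data.frame(data))
  mf_call <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  yf <- stats::model.response(mf_call)
  if (!is.factor(yf)) stopf("the response must be a factor")
  yf <- as.factor(yf)
  K <- nlevels(yf)
  if (K < 2L) stopf("the response needs at least two categories")
  if (any(table(yf) == 0L))
    stopf("outcome category '%s' has no observations",
          names(which(table(yf) == 0L))[1L])
  y <- as.integer(yf)
  X <- stats::model.matrix(attr(mf_call, "terms"), mf_call)
  int_col <- which(colnames(X) == "(Intercept)")
  if (length(int_col)) X <- X[, -int_col, drop = FALSE]

  if (is.null(weights)) {
    weights <- if (!is.null(data$weight)) data$weight else rep(1, length(y))
  }
  w <- as.numeric(weights)
  if (length(w) != length(y) || any(!is.finite(w)) || any(w <= 0))
    stopf("weights must be positive and finite, one per observation")

  if (length(yf) != nrow(X)) stopf("internal: design/response mismatch")
  if (sum(table(yf) > 0L) < K) stopf("an outcome category is absent")

  p <- ncol(X)
  cum_w <- cumsum(tapply(w, yf, sum))[-K] / sum(w)
  par0 <- c(rep(0, p), logit(as.numeric(cum_w)))

  fn_t <- function(tp) po_nll(c(tp[seq_len(p)],
                                theta_from_t(tp[p + seq_len(K - 1L)])),
                              X, y, w, K)
  gr_t <- function(tp) {
    theta <- theta_from_t(tp[p + seq_len(K - 1L)])
    g <- po_grad(c(tp[seq_len(p)], theta), X, y, w, K)
    gt <- g[p + seq_len(K - 1L)]
    # Jacobian of theta wrt t: lower-triangular of ones times diag(1, exp(t))
    jt <- rev(cumsum(rev(gt)))
    if (K > 2L)
      jt[-1L] <- jt[-1L] * exp(tp[p + seq.int(2L, K - 1L)])
    c(g[seq_len(p)], jt)
  }
  tp0 <- c(par0[seq_len(p)], t_from_theta(par0[p + seq_len(K - 1L)]))
  opt <- stats::optim(tp0, fn_t, gr_t, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-13))
  par <- c(opt$par[seq_len(p)], theta_from_t(opt$par[p + seq_len(K - 1L)]))

  # damped Newton polish on the natural scale
  g <- po_grad(par, X, y, w, K)
  nll <- po_nll(par, X, y, w, K)
  H <- NULL
  iter <- 0L
  while (max(abs(g)) > tol && iter < max_iter) {
    iter <- iter + 1L
    H <- stats::optimHess(par, po_nll, po_grad, X = X, y = y, w = w, K = K)
    step <- tryCatch(-solve(H, g), error = function(e)
      -solve(H + diag(1e-6 * max(abs(diag(H))), nrow(H)), g))
    lambda <- 1
    repeat {
      cand <- par + lambda * step
      nll_c <- po_nll(cand, X, y, w, K)
      if (is.finite(nll_c) && nll_c <= nll + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- par; nll_c <- nll; break }
    }
    par <- cand; nll <- nll_c
    g <- po_grad(par, X, y, w, K)
  }
  grad_norm <- max(abs(g))
  if (grad_norm > sqrt(tol))
    stopf("proportional-odds fit did not converge (gradient max-norm %.3e)",
          grad_norm)
  if (is.null(H) || iter > 0L)
    H <- stats::optimHess(par, po_nll, po_grad, X = X, y = y, w = w, K = K)

  info <- (H + t(H)) / 2   # observed information of the weighted nll
  V <- tryCatch(solve(info), error = function(e)
    stopf("singular information matrix: %s", conditionMessage(e)))
  if (vcov_type == "sandwich") {
    S <- po_scores(par, X, y, w, K)
    B <- crossprod(S)
    V <- V %*% B %*% V
  }

  beta <- par[seq_len(p)]
  zeta <- par[p + seq_len(K - 1L)]
  lev <- levels(yf)
  names(beta) <- colnames(X)
  names(zeta) <- paste(lev[-K], lev[-1L], sep = "|")
  dimnames(V) <- list(c(names(beta), names(zeta)),
                      c(names(beta), names(zeta)))

  structure(list(coefficients = beta, zeta = zeta, vcov = V,
                 logLik = -nll, n = length(y), sum_weights = sum(w),
                 converged = TRUE, grad_norm = grad_norm,
                 vcov_type = vcov_type, levels = lev,
                 terms = attr(mf_call, "terms"),
                 xlevels = stats::.getXlevels(attr(mf_call, "terms"), mf_call),
                 call = match.call()),
            class = "frailty_po")
}

full_coef <- function(object) c(object$coefficients, object$zeta)

#' @export
coef.frailty_po <- function(object, ...) object$coefficients

#' @export
vcov.frailty_po <- function(object, ...) object$vcov

#' @export
logLik.frailty_po <- function(object, ...) {
  structure(object$logLik, df = length(full_coef(object)), class = "logLik")
}

#' @export
nobs.frailty_po <- function(object, ...) object$n

#' @export
print.frailty_po <- function(x, ...) {
  cat("Weighted proportional-odds fit\n")
  cat(sprintf("  n = %d, sum of weights = %.1f, log-likelihood = %.3f\n",
              x$n, x$sum_weights, x$logLik))
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat("Thresholds:\n")
  print(round(x$zeta, 4))
  invisible(x)
}

#' @export
summary.frailty_po <- function(object, ...) {
  est <- full_coef(object)
  se <- sqrt(diag(object$vcov))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, logLik = object$logLik, n = object$n,
              vcov_type = object$vcov_type)
  class(out) <- "summary.frailty_po"
  out
}

#' @export
print.summary.frailty_po <- function(x, ...) {
  cat(sprintf("Weighted proportional-odds fit (n = %d, logLik = %.3f, vcov = %s)\n",
              x$n, x$logLik, x$vcov_type))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# category probabilities for a design matrix under c(beta, theta)
po_probs_from_par <- function(par, X, K) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- par[p + seq_len(K - 1L)]
  eta <- drop(X %*% beta)
  cum <- vapply(theta, function(th) expit(th - eta), numeric(nrow(X)))
  cum <- matrix(cum, nrow = nrow(X))
  pr <- cbind(cum, 1)
  pr[, -1L] <- pr[, -1L, drop = FALSE] - cum
  pr
}

po_design <- function(object, newdata) {
  newdata <- po_canonical_factors(as.data.frame(newdata))
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  int_col <- which(colnames(X) == "(Intercept)")
  if (length(int_col)) X <- X[, -int_col, drop = FALSE]
  X
}

#' Predicted category probabilities
#'
#' @param object A `frailty_po` fit.
#' @param newdata Data frame of predictor values; defaults to the full
#'   90-stratum grid.
#' @param ... Unused.
#' @return Matrix with one row per `newdata` row and one column per
#'   category; rows sum to 1.
#' @export
predict.frailty_po <- function(object, newdata = stratum_grid(), ...) {
  X <- po_design(object, newdata)
  pr <- po_probs_from_par(full_coef(object), X, length(object$levels))
  colnames(pr) <- object$levels
  pr
}

#' Pool proportional-odds fits across imputations by Rubin's rules
#'
#' Point estimates are the mean of the per-imputation estimates; the total
#' covariance is \eqn{T = \bar W + (1 + 1/m) B} with \eqn{\bar W} the mean
#' within-imputation covariance and \eqn{B} the between-imputation sample
#' covariance of the estimates.
#'
#' @param fits A list of `frailty_po` fits sharing one parameterisation.
#' @return An object of class `frailty_po_pooled` with components `point`,
#'   `within`, `between`, `cov` (total T), `m`, and the first fit retained
#'   as prediction template.
#' @export
pool_rubin <- function(fits) {
  if (inherits(fits, "frailty_po")) fits <- list(fits)
  m <- length(fits)
  if (m < 1L) stopf("need at least one fit to pool")
  nm <- names(full_coef(fits[[1L]]))
  est <- vapply(fits, function(f) {
    fc <- full_coef(f)
    if (!identical(names(fc), nm)) stopf("fits have mismatched parameters")
    fc
  }, numeric(length(nm)))
  est <- matrix(est, nrow = length(nm), dimnames = list(nm, NULL))
  point <- rowMeans(est)
  W <- Reduce(`+`, lapply(fits, vcov)) / m
  B <- if (m > 1L) stats::cov(t(est)) else matrix(0, length(nm), length(nm),
                                                  dimnames = list(nm, nm))
  Tmat <- W + (1 + 1 / m) * B
  structure(list(point = point, within = W, between = B, cov = Tmat, m = m,
                 template = fits[[1L]]),
            class = "frailty_po_pooled")
}

#' @export
coef.frailty_po_pooled <- function(object, ...) {
  p <- length(object$template$coefficients)
  object$point[seq_len(p)]
}

#' @export
vcov.frailty_po_pooled <- function(object, ...) object$cov

#' @export
print.frailty_po_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled proportional-odds fit (m = %d imputations)\n", x$m))
  print(round(x$point, 4))
  invisible(x)
}

pooled_levels <- function(object) object$template$levels

#' Stratum probability table from a fitted or pooled model
#'
#' Evaluates the fitted cumulative-logit model over all 90 (age band, sex,
#' IMD quintile) strata: `p_robust = expit(theta_1 - x'beta)`,
#' `p_prefrail = expit(theta_2 - x'beta) - expit(theta_1 - x'beta)`,
#' `p_frail = 1 - expit(theta_2 - x'beta)`.
#'
#' @param fit A `frailty_po` or `frailty_po_pooled` object.
#' @return Data frame: `age_band`, `sex`, `imd_quintile`, `p_robust`,
#'   `p_prefrail`, `p_frail`; each row sums to 1.
#' @export
predict_strata <- function(fit) {
  g <- stratum_grid()
  if (inherits(fit, "frailty_po_pooled")) {
    X <- po_design(fit$template, g)
    pr <- po_probs_from_par(fit$point, X, length(pooled_levels(fit)))
  } else if (inherits(fit, "frailty_po")) {
    pr <- predict(fit, g)
  } else stopf("fit must be a frailty_po or frailty_po_pooled object")
  data.frame(g, p_robust = pr[, 1L], p_prefrail = pr[, 2L],
             p_frail = pr[, 3L])
}

#' Likelihood-ratio test between nested weighted fits
#'
#' Compares two proportional-odds fits on the same data and weights, e.g.
#' a main-effects model against one adding age-by-sex interactions. Under
#' case weights this is a pseudo-likelihood ratio: the chi-square reference
#' is approximate, which the result records.
#'
#' @param null_fit,alt_fit `frailty_po` fits; `alt_fit` must nest
#'   `null_fit`.
#' @return List with `statistic`, `df`, `p_value` and an `approximate`
#'   flag (TRUE when either fit used non-unit weights).
#' @export
lrt_interaction <- function(null_fit, alt_fit) {
  stat <- 2 * (alt_fit$logLik - null_fit$logLik)
  if (stat < -1e-6)
    stopf("alternative log-likelihood below the null: models are not nested or a fit failed")
  stat <- max(stat, 0)
  df <- length(full_coef(alt_fit)) - length(full_coef(null_fit))
  if (df < 0L) stopf("alternative model has fewer parameters than the null")
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p,
       approximate = !isTRUE(all.equal(null_fit$sum_weights,
                                       as.numeric(null_fit$n))))
}

#' Draw coefficient vectors from a fitted model's sampling distribution
#'
#' Multivariate-normal draws centred at the (pooled) point estimate with
#' the (total) covariance; draws violating the threshold ordering are
#' rejected and redrawn. Used by the parametric bootstrap for area counts.
#'
#' @param fit A `frailty_po` or `frailty_po_pooled` object.
#' @param B Number of draws.
#' @param seed Integer seed.
#' @return Matrix B x n_par of draws (named columns).
#' @export
draw_coefs <- function(fit, B, seed) {
  point <- if (inherits(fit, "frailty_po_pooled")) fit$point else
    full_coef(fit)
  V <- vcov(fit)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-300))
    stopf("covariance matrix is not positive semi-definite")
  R <- if (max(diag(V)) == 0) matrix(0, nrow(V), ncol(V)) else
    tryCatch(chol(V), error = function(e)
      chol(V + diag(1e-10 * max(diag(V)), nrow(V))))
  th_idx <- grep("\\|", names(point))
  set.seed(seed)
  draws <- matrix(NA_real_, B, length(point),
                  dimnames = list(NULL, names(point)))
  filled <- 0L
  attempts <- 0L
  while (filled < B) {
    need <- B - filled
    Z <- matrix(stats::rnorm(need * length(point)), need)
    cand <- Z %*% R + matrix(point, need, length(point), byrow = TRUE)
    ok <- apply(cand[, th_idx, drop = FALSE], 1L,
                function(th) !is.unsorted(th, strictly = TRUE))
    attempts <- attempts + need
    take <- which(ok)
    if (length(take)) {
      take <- take[seq_len(min(length(take), need))]
      draws[filled + seq_along(take), ] <- cand[take, , drop = FALSE]
      filled <- filled + length(take)
    }
    if (attempts > 2L * B && filled < attempts / 2)
      stopf("more than half of coefficient draws violate the threshold ordering; the fit is pathological")
  }
  draws
}
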