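# Shared fixtures: small generator configs and toy tables built in code.

small_config <- function(n = 800L, seed = 101L, ...) {
  generator_config(n_respondents = n, seed = seed, ...)
}

# a minimal complete scored survey with a single binary predictor, used by
# the brute-force likelihood oracles
toy_ordinal_data <- function() {
  # 20 respondents, predictor x in {0,1}, weights varying
  data.frame(
    y = factor(c("robust", "robust", "pre_frail", "robust", "frail",
                 "robust", "pre_frail", "robust", "robust", "frail",
                 "pre_frail", "frail", "frail", "pre_frail", "robust",
                 "frail", "frail", "pre_frail", "frail", "robust"),
               levels = c("robust", "pre_frail", "frail"), ordered = TRUE),
    x = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    w = c(1, 2, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 2, 1, 1, 1, 2, 1, 1, 1)
  )
}

# independent negative log-likelihood for the toy model (written from the
# cumulative-logit definition, no package internals)
toy_nll <- function(beta, th1, th2, d) {
  if (th1 >= th2) return(Inf)
  eta <- d$x * beta
  p1 <- plogis(th1 - eta)
  p2 <- plogis(th2 - eta) - p1
  p3 <- 1 - plogis(th2 - eta)
  p <- ifelse(d$y == "robust", p1, ifelse(d$y == "pre_frail", p2, p3))
  if (any(p <= 0)) return(Inf)
  -sum(d$w * log(p))
}

# iterated grid search over (beta, th1, th2): coarse grid then two
# refinements around the incumbent, vectorised over the grid
toy_grid_mle <- function(d, lo = c(-4, -4, -4), hi = c(4, 4, 4),
                         steps = 3L, pts = 25L) {
  best <- c(0, -0.5, 0.5)
  for (s in seq_len(steps)) {
    gb <- seq(lo[1], hi[1], length.out = pts)
    g1 <- seq(lo[2], hi[2], length.out = pts)
    g2 <- seq(lo[3], hi[3], length.out = pts)
    grid <- expand.grid(beta = gb, th1 = g1, th2 = g2)
    val <- mapply(function(b, t1, t2) toy_nll(b, t1, t2, d),
                  grid$beta, grid$th1, grid$th2)
    best <- as.numeric(grid[which.min(val), ])
    span <- (hi - lo) / (pts - 1) * 2.5
    lo <- best - span
    hi <- best + span
  }
  # final Nelder-Mead polish of the independent likelihood
  op <- optim(best, function(p) toy_nll(p[1], p[2], p[3], d),
              control = list(reltol = 1e-14, maxit = 5000))
  op$par
}
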