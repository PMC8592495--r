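#' Age bands used throughout the package
#'
#' Nine five-year bands from 50-54 to 85-89 plus an open-ended 90+ band.
#' All survey, stratum and area tables are keyed on these labels.
#'
#' @return Character vector of the nine age-band labels, youngest first.
#' @export
age_bands <- function() {
  c("50-54", "55-59", "60-64", "65-69", "70-74",
    "75-79", "80-84", "85-89", "90+")
}

#' Sex labels used throughout the package
#'
#' @return Character vector `c("female", "male")`.
#' @export
sex_levels <- function() c("female", "male")

n_age_bands <- function() 9L
n_imd_quintiles <- function() 5L

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

#' The full stratum grid
#'
#' All 90 combinations of age band, sex and IMD quintile, in a fixed order
#' (age band varying slowest, then sex, then quintile). Quintile 1 is the
#' most deprived.
#'
#' @return A data.frame with columns `age_band`, `sex`, `imd_quintile`.
#' @export
stratum_grid <- function() {
  g <- expand.grid(imd_quintile = 1:5,
                   sex = sex_levels(),
                   age_band = age_bands(),
                   KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, c("age_band", "sex", "imd_quintile")]
  rownames(g) <- NULL
  g
}

stratum_key <- function(age_band, sex, imd_quintile) {
  paste(age_band, sex, imd_quintile, sep = "|")
}

# Deterministic sub-stream seeds: keep everything well inside 32-bit range.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 2971 + as.double(k) * 7919 + 12345) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

check_proportion <- function(x, name) {
  check_scalar_number(x, name)
  if (x < 0 || x >= 1) stopf("'%s' must lie in [0, 1)", name)
  invisible(x)
}
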