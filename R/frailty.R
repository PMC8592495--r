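#' Define a deficit schema
#'
#' A deficit schema fixes the list of items entering the frailty index and,
#' for each item, how observed levels map onto deficit values in [0, 1].
#' The index denominator is always the number of schema items, regardless
#' of missingness (missing items are resolved by imputation, never by
#' rescaling the denominator).
#'
#' @param items A list; each element is a list with fields `name` (unique
#'   identifier), `kind` (`"binary"` or `"graded"`) and `mapping` (named
#'   numeric vector mapping observed levels to values in [0, 1]; binary
#'   items default to `c("0" = 0, "1" = 1)`).
#' @return An object of class `deficit_schema`.
#' @seealso [default_deficit_schema()] for the packaged 30-item binary schema.
#' @export
deficit_schema <- function(items) {
  if (!is.list(items) || length(items) < 1L)
    stopf("a schema needs at least one item")
  items <- lapply(items, function(it) {
    if (is.null(it$name)) stopf("every schema item needs a 'name'")
    if (is.null(it$kind)) it$kind <- "binary"
    if (!it$kind %in% c("binary", "graded"))
      stopf("item '%s': kind must be 'binary' or 'graded'", it$name)
    if (is.null(it$mapping)) {
      if (it$kind != "binary")
        stopf("item '%s': graded items need an explicit mapping", it$name)
      it$mapping <- c("0" = 0, "1" = 1)
    }
    m <- it$mapping
    if (is.null(names(m)) || !is.numeric(m) || any(m < 0 | m > 1))
      stopf("item '%s': mapping must be a named numeric vector in [0, 1]",
            it$name)
    it
  })
  nm <- vapply(items, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("schema item names must be unique")
  structure(list(items = items), class = "deficit_schema")
}

#' Default 30-item binary deficit schema
#'
#' A stand-in schema of 30 binary deficits (`deficit_001` ... `deficit_030`),
#' each coded 0 = absent, 1 = present. Real applications should declare
#' their own item list and level mappings with [deficit_schema()].
#'
#' @param n_deficits Number of binary items (default 30).
#' @return A `deficit_schema` object.
#' @export
default_deficit_schema <- function(n_deficits = 30L) {
  if (n_deficits < 1L) stopf("n_deficits must be >= 1")
  deficit_schema(lapply(seq_len(n_deficits), function(i) {
    list(name = sprintf("deficit_%03d", i), kind = "binary",
         mapping = c("0" = 0, "1" = 1))
  }))
}

schema_names <- function(schema) {
  vapply(schema$items, `[[`, "", "name")
}

schema_size <- function(schema) length(schema$items)

#' @export
print.deficit_schema <- function(x, ...) {
  kinds <- table(vapply(x$items, `[[`, "", "kind"))
  cat(sprintf("Deficit schema: %d items (%s)\n", schema_size(x),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", ")))
  invisible(x)
}

#' Frailty category cut-points
#'
#' Scores are categorised robust (<= `robust_max`), pre-frail
#' (> `robust_max` and <= `prefrail_max`) or frail (> `prefrail_max`).
#' The defaults 0.24 and 0.36 are the cut-points established in the
#' deficit-accumulation literature. Comparisons use the closed upper
#' bounds exactly; there is no epsilon tolerance.
#'
#' @param robust_max Upper bound (inclusive) of the robust category.
#' @param prefrail_max Upper bound (inclusive) of the pre-frail category.
#' @return An object of class `cut_points`.
#' @export
cut_points <- function(robust_max = 0.24, prefrail_max = 0.36) {
  check_scalar_number(robust_max, "robust_max")
  check_scalar_number(prefrail_max, "prefrail_max")
  if (!(0 < robust_max && robust_max < prefrail_max && prefrail_max < 1))
    stopf("cut-points must satisfy 0 < robust_max < prefrail_max < 1")
  structure(list(robust_max = robust_max, prefrail_max = prefrail_max),
            class = "cut_points")
}

#' Frailty category labels, in order
#'
#' @return `c("robust", "pre_frail", "frail")` (least to most frail).
#' @export
frailty_levels <- function() c("robust", "pre_frail", "frail")

#' Score one respondent's deficits
#'
#' The deficit-accumulation frailty index: the sum of mapped deficit values
#' divided by the total number of schema items D. Values must be complete —
#' scoring runs on imputation-completed data, and missingness is an error,
#' not a denominator adjustment.
#'
#' @param deficit_values Numeric vector of mapped deficit values in [0, 1],
#'   one per schema item, in schema order.
#' @param schema A `deficit_schema`.
#' @return The frailty score, a single number in [0, 1].
#' @export
frailty_score <- function(deficit_values, schema) {
  D <- schema_size(schema)
  if (length(deficit_values) != D)
    stopf("expected %d deficit values, got %d", D, length(deficit_values))
  if (anyNA(deficit_values))
    stopf("missing deficit values: impute before scoring")
  if (any(deficit_values < 0 | deficit_values > 1))
    stopf("deficit values must lie in [0, 1]")
  sum(deficit_values) / D
}

#' Categorise a frailty score
#'
#' @param score Numeric vector of frailty scores in [0, 1].
#' @param cuts A `cut_points` object.
#' @return An ordered factor with levels robust < pre_frail < frail.
#' @export
frailty_categorize <- function(score, cuts = cut_points()) {
  if (anyNA(score) || any(score < 0 | score > 1))
    stopf("scores must lie in [0, 1] with no missing values")
  lv <- frailty_levels()
  out <- ifelse(score <= cuts$robust_max, lv[1L],
                ifelse(score <= cuts$prefrail_max, lv[2L], lv[3L]))
  factor(out, levels = lv, ordered = TRUE)
}

# Map observed item levels to deficit values; binary 0/1 passes through.
map_deficit_column <- function(x, item) {
  m <- item$mapping
  idx <- match(as.character(x), names(m))
  bad <- which(!is.na(x) & is.na(idx))
  if (length(bad))
    stopf("item '%s': unmapped level '%s' (row %d)",
          item$name, as.character(x[bad[1L]]), bad[1L])
  out <- unname(m[idx])
  out[is.na(x)] <- NA_real_
  out
}

#' Score a complete survey table
#'
#' Adds `frailty_score` and `frailty_cat` columns to a survey table. The
#' table must be complete (post-imputation): any missing deficit cell is an
#' error naming the offending row.
#'
#' @param survey A survey data.frame with one column per schema item.
#' @param schema A `deficit_schema`.
#' @param cuts A `cut_points` object.
#' @return The input data.frame with `frailty_score` (numeric) and
#'   `frailty_cat` (ordered factor) appended; row count unchanged.
#' @export
score_survey <- function(survey, schema = default_deficit_schema(),
                         cuts = cut_points()) {
  nm <- schema_names(schema)
  missing_cols <- setdiff(nm, names(survey))
  if (length(missing_cols))
    stopf("survey lacks deficit columns: %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(survey) == 0L) {
    survey$frailty_score <- numeric(0)
    survey$frailty_cat <- factor(character(0), levels = frailty_levels(),
                                 ordered = TRUE)
    return(survey)
  }
  vals <- matrix(0, nrow(survey), length(nm))
  for (j in seq_along(nm))
    vals[, j] <- map_deficit_column(survey[[nm[j]]], schema$items[[j]])
  na_row <- which(rowSums(is.na(vals)) > 0)
  if (length(na_row))
    stopf("missing deficit cell in row %d: impute before scoring", na_row[1L])
  survey$frailty_score <- rowSums(vals) / schema_size(schema)
  survey$frailty_cat <- frailty_categorize(survey$frailty_score, cuts)
  survey
}
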