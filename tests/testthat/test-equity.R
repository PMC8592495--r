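test_that("dose ratios divide doses by the denominator and enumerate draw CIs", {
  r <- dose_ratio(100, 25)
  expect_equal(r$ratio, 4.0)
  expect_true(is.na(r$ci_lo))

  rd <- dose_ratio(100, 25, denominator_draws = c(20, 25, 50))
  draws <- 100 / c(20, 25, 50)
  expect_equal(rd$ci_lo, unname(quantile(draws, 0.025)))
  expect_equal(rd$ci_hi, unname(quantile(draws, 0.975)))

  r0 <- dose_ratio(100, 25, denominator_draws = rep(25, 50))
  expect_equal(r0$ci_lo, 4.0)
  expect_equal(r0$ci_hi, 4.0)

  expect_error(dose_ratio(100, 0), "denominator")
  expect_error(dose_ratio(100, 25, denominator_draws = c(10, -2)), "> 0")
  expect_error(dose_ratio(-1, 25), "doses")
})

test_that("extreme factor reproduces the printed worked examples", {
  rec <- data.frame(area_id = c("low", "high"), ratio = c(4.4, 20.1))
  ef <- extreme_factor(rec)
  expect_equal(ef$display, 4.6)
  expect_equal(ef$max_area, "high")
  expect_equal(ef$min_area, "low")

  rec2 <- data.frame(area_id = c("a", "b"), ratio = c(12.7, 4.3))
  expect_equal(round(extreme_factor(rec2)$factor), 3)

  same <- data.frame(area_id = c("a", "b", "c"), ratio = c(2, 2, 2))
  expect_equal(extreme_factor(same)$factor, 1.0)
  expect_error(extreme_factor(rec[1, , drop = FALSE]), "two areas")
})

test_that("extreme factor is scale-invariant and its draw CI brackets the point", {
  set.seed(12)
  rec <- data.frame(area_id = sprintf("A%02d", 1:10),
                    ratio = runif(10, 2, 20))
  ef1 <- extreme_factor(rec)
  rec2 <- rec; rec2$ratio <- rec2$ratio * 7  # all doses scaled by 7
  expect_equal(extreme_factor(rec2)$factor, ef1$factor)

  draws <- sapply(rec$ratio, function(m) m * exp(rnorm(400, 0, 0.05)))
  colnames(draws) <- rec$area_id
  efd <- extreme_factor(rec, ratio_draws = draws)
  expect_lt(efd$ci_lo, efd$ci_hi)
  fac_b <- apply(draws, 1, function(r) max(r) / min(r))
  expect_equal(efd$ci_lo, unname(quantile(fac_b, 0.025)))
})

test_that("total risk diagnoses ratio sums factor counts per area", {
  doses <- data.frame(area_id = "Z", doses = 30)
  risks <- data.frame(area_id = "Z",
                      factor = c("diabetes", "obesity", "smoking_current"),
                      count = c(10, 20, 30))
  r <- total_risk_diagnoses_ratio(doses, risks,
                                  factors = c("diabetes", "obesity",
                                              "smoking_current"))
  expect_equal(r$ratio, 0.5)
  risks2 <- risks; risks2$count <- risks2$count * 2
  expect_equal(total_risk_diagnoses_ratio(doses, risks2,
                                          factors = risks$factor)$ratio, 0.25)

  d3 <- data.frame(area_id = c("X", "Y", "W"), doses = c(10, 40, 90))
  r3 <- expand.grid(area_id = c("X", "Y", "W"),
                    factor = c("diabetes", "obesity"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r3$count <- c(5, 10, 30, 15, 10, 60)   # X: 5+15, Y: 10+10, W: 30+60
  out <- total_risk_diagnoses_ratio(d3, r3, factors = c("diabetes", "obesity"))
  expect_equal(out$ratio[match(c("X", "Y", "W"), out$area_id)],
               c(10 / 20, 40 / 20, 90 / 90))
  expect_error(total_risk_diagnoses_ratio(
    data.frame(area_id = "Q", doses = 1), risks, factors = "diabetes"),
    "absent")
  expect_error(total_risk_diagnoses_ratio(d3, r3, factors = character(0)),
               "empty")
})

test_that("quintile assignment balances group sizes and breaks ties by id", {
  v5 <- setNames(c(5, 3, 1, 4, 2), sprintf("A%d", 1:5))
  q5 <- assign_quintiles(v5)
  expect_setequal(q5, 1:5)
  expect_equal(unname(q5["A1"]), 5L)  # largest value, most advantaged
  expect_equal(unname(q5["A3"]), 1L)

  v135 <- setNames(rnorm(135), sprintf("B%03d", 1:135))
  expect_true(all(table(assign_quintiles(v135)) == 27L))

  v7 <- setNames(7:1, sprintf("C%d", 1:7))
  expect_equal(as.numeric(table(assign_quintiles(v7))), c(2, 2, 1, 1, 1))

  ties <- setNames(rep(1, 5), c("b", "a", "d", "c", "e"))
  qt <- assign_quintiles(ties)
  expect_equal(unname(qt[order(names(qt))]), 1:5)  # a..e by id

  # direction flag flips the ordering
  qd <- assign_quintiles(v5, larger_is_advantaged = FALSE)
  expect_equal(unname(qd["A1"]), 1L)
  expect_error(assign_quintiles(c(v5[-1], x = NaN)), "finite")
  expect_error(assign_quintiles(v5[1:4]), "five areas")
})

test_that("heatmap tables align metrics and are input-order invariant", {
  ids <- sprintf("A%d", 1:5)
  m1 <- setNames(c(10, 8, 6, 4, 2), ids)
  m2 <- setNames(c(1, 5, 3, 2, 4), ids)
  dep <- setNames(c(1L, 2L, 3L, 4L, 5L), ids)
  h1 <- heatmap_table(list(a = m1, b = m2), dep, order_by = "a")
  expect_equal(h1$table$q_a,
               unname(assign_quintiles(m1)[h1$table$area_id]))
  h2 <- heatmap_table(list(b = m2, a = m1), dep, order_by = "a")
  expect_identical(h1$table, h2$table)
  expect_equal(h1$table$area_id, ids)  # ordered by metric a, descending
  expect_error(heatmap_table(list(a = m1, b = m2[1:4]), dep, "a"),
               "different area set")
})

test_that("default synthetic run shows the expected deprivation gradient", {
  cfg <- small_config(n = 2500L, item_missing_rate = 0, seed = 91)
  sv <- generate_survey(cfg)
  ar <- generate_areas(cfg)
  fit <- frailty_po(data = score_survey(sv$survey))
  est <- post_stratify(predict_strata(fit), ar$areas)
  ratio <- ar$doses$doses[match(est$area_id, ar$doses$area_id)] / est$frail
  # most-deprived areas get fewer doses per frail person: ratios rise with
  # rank (rank 1 = most deprived)
  expect_gt(cor(ratio, est$imd_rank, method = "spearman"), 0.3)
  q_frail <- assign_quintiles(setNames(ratio, est$area_id))
  mean_dep <- tapply(q_frail[est$area_id], est$imd_quintile, mean)
  expect_lt(mean_dep[["1"]], mean_dep[["5"]])
})
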