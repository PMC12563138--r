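test_that("autogenous bone crosses at ~18.4 d / 13.5% inside the interval", {
  res <- analyze_series(autogenous_series())
  # closed form from the two-point lines: slopes 32.4/28 and -22.7/28
  expect_equal(res$time_days, (22.7 + 7 * 22.7 / 28 + 7.8) / (55.1 / 28))
  expect_equal(round(res$time_days, 1), 18.4)
  expect_equal(round(res$level_pct, 1), 13.5)
  expect_identical(res$status, "within_interval")
  expect_true(is.na(res$extrapolation_factor))
})

test_that("symmetric toy lines cross at the midpoint", {
  bone <- linear_trend(10, 0, 0.5, 10)
  graft <- linear_trend(-10, 100, 0.5, 10)
  res <- estimate_break_even(bone, graft)
  expect_equal(res$time_days, 5)
  expect_equal(res$level_pct, 50)
  expect_identical(res$status, "within_interval")
})

test_that("parallel lines are divergent and report no coordinates", {
  bone <- linear_trend(1, 0, 5, 20)
  graft <- linear_trend(1, 30, 5, 20)
  res <- estimate_break_even(bone, graft)
  expect_identical(res$status, "divergent")
  expect_true(is.na(res$time_days))
  expect_true(is.na(res$level_pct))
})

test_that("separating lines with bone below graft are divergent", {
  s <- healing_series(c(7, 35), c(10, 12), c(30, 40))
  res <- analyze_series(s)
  expect_identical(res$status, "divergent")
  expect_true(is.na(res$time_days))
})

test_that("bone already above graft at the first observation is already_crossed", {
  s <- healing_series(c(10, 30), c(50, 55), c(40, 42))
  res <- analyze_series(s)
  expect_identical(res$status, "already_crossed")
  expect_lt(res$time_days, 10)
})

test_that("moderate forward extrapolation is flagged with its factor", {
  inject <- healing_series(c(14, 70), c(0.08, 23.28), c(79.72, 48.63),
                           study = "Costa 2021", material = "Maxresorb Inject")
  res <- analyze_series(inject)
  expect_identical(res$status, "extrapolated")
  expect_equal(round(res$time_days, 1), 96.1)
  expect_equal(round(res$level_pct, 1), 34.1)
  expect_equal(res$extrapolation_factor, res$time_days / 70)
  expect_lt(res$extrapolation_factor, 1.5)
})

test_that("the extrapolation bound separates usable from unreliable projections", {
  lambert <- healing_series(c(7, 180), c(0.1, 16), c(42.7, 34.9),
                            study = "Lambert 2011", material = "Bio-Oss")
  res <- analyze_series(lambert)
  expect_identical(res$status, "not_reached")
  expect_true(is.na(res$time_days))
  expect_true(is.na(res$level_pct))
  expect_equal(round(res$projected_time_days), 318)
  # a laxer bound turns the same projection into a (flagged) estimate
  wide <- analyze_series(lambert, breakeven_config(max_extrapolation_factor = 2))
  expect_identical(wide$status, "extrapolated")
  expect_equal(round(wide$time_days), 318)
})

test_that("trends must share their segment", {
  bone <- linear_trend(1, 0, 5, 20)
  graft <- linear_trend(-1, 30, 5, 25)
  expect_error(estimate_break_even(bone, graft), "same segment")
})

test_that("dimension loss is the relative area reduction, signed", {
  expect_equal(dimension_loss(10, 5, 14, 70)$loss_pct, 50)
  expect_equal(dimension_loss(10, 10, 14, 70)$loss_pct, 0)
  expect_equal(dimension_loss(8, 9.2, 14, 70)$loss_pct, -15)
  expect_equal(dimension_loss(10, 5, 14, 70)$period, c(14, 70))
  expect_error(dimension_loss(0, 5, 14, 70), "positive")
  expect_error(dimension_loss(10, 5, 70, 14), "later")
})

test_that("comparison table orders materials by crossing time, NA last", {
  cmp <- compare_materials(fixture_series())
  expect_equal(nrow(cmp), 7)
  expect_equal(
    cmp$material[1:6],
    c("Autogenous", "Gen-Os", "Bio-Oss Collagen", "Maxresorb", "Bio-Oss",
      "Maxresorb Inject")
  )
  expect_identical(cmp$status[7], "not_reached")
  expect_identical(cmp$material[7], "Bio-Oss")
  expect_identical(cmp$study[7], "Lambert 2011")
  expect_equal(cmp$extrapolated,
               c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("comparison handles empty and single-series input", {
  empty <- compare_materials(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("material", "time_days", "status") %in% names(empty)))
  one <- compare_materials(list(autogenous_series()))
  expect_equal(nrow(one), 1)
  expect_equal(one$time_days, analyze_series(autogenous_series())$time_days)
})

test_that("dimension loss appears in the comparison when areas are supplied", {
  s <- healing_series(c(14, 56), c(6, 30), c(40, 10),
                      total_area_mm2 = c(10, 7), material = "with areas")
  cmp <- compare_materials(list(s))
  expect_equal(cmp$dimension_loss_pct, 30)
})
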