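ref_model <- function() {
  kinetic_model(b_max = 40, k_bone = 0.05, g0 = 50, g_res = 0, k_graft = 0.03)
}

test_that("noiseless simulation reproduces the curves exactly", {
  m <- ref_model()
  d <- sampling_design(times = c(14, 70), n_animals = 1, noise_sd = 0)
  s <- simulate_series(m, d)
  means <- series_means(s)
  expect_equal(means$new_bone_pct, bone_fraction(m, c(14, 70)))
  expect_equal(means$residual_graft_pct, graft_fraction(m, c(14, 70)))
})

test_that("the same seed reproduces the same series", {
  m <- ref_model()
  d <- sampling_design(times = c(14, 35, 70), n_animals = 5, noise_sd = 2,
                       seed = 99)
  expect_identical(simulate_series(m, d), simulate_series(m, d))
})

test_that("per-timepoint means stay within the standard-error bound", {
  m <- ref_model()
  d <- sampling_design(times = c(14, 70), n_animals = 200, noise_sd = 2,
                       seed = 7)
  means <- series_means(simulate_series(m, d))
  bound <- 3 * 2 / sqrt(200)
  expect_true(all(abs(means$new_bone_pct - bone_fraction(m, c(14, 70))) < bound))
  expect_true(all(abs(means$residual_graft_pct - graft_fraction(m, c(14, 70))) < bound))
})

test_that("simulated compositions are truncated and never exceed 100%", {
  # near-saturated composition with heavy noise exercises the rescaling
  m <- kinetic_model(b_max = 45, k_bone = 0.1, g0 = 55, g_res = 40,
                     k_graft = 0.01)
  d <- sampling_design(times = c(30, 60, 90), n_animals = 50, noise_sd = 15,
                       seed = 11)
  obs <- simulate_series(m, d)$observations
  expect_true(all(obs$new_bone_pct >= 0))
  expect_true(all(obs$residual_graft_pct >= 0))
  expect_true(all(obs$new_bone_pct + obs$residual_graft_pct <= 100 + 1e-9))
})

test_that("the linear estimate is exact for linear dynamics", {
  # over a window where both curves are still near-linear (tiny rates),
  # the secant estimate coincides with the true crossing
  m <- kinetic_model(b_max = 90, k_bone = 1e-4, g0 = 10, g_res = 0,
                     k_graft = 1e-4)
  truth <- true_break_even(m)
  d <- sampling_design(times = c(truth - 20, truth + 20), n_animals = 1,
                       noise_sd = 0)
  res <- analyze_series(simulate_series(m, d))
  expect_lt(abs(res$time_days - truth), 0.05)
})

test_that("tight noiseless brackets estimate the crossing almost exactly", {
  m <- ref_model()
  truth <- true_break_even(m)
  d <- sampling_design(times = c(truth - 1, truth + 1), n_animals = 1,
                       noise_sd = 0)
  res <- analyze_series(simulate_series(m, d))
  expect_identical(res$status, "within_interval")
  expect_lt(abs(res$time_days - truth), 0.1)
})

test_that("|bias| shrinks monotonically with the bracket half-width", {
  m <- ref_model()
  truth <- true_break_even(m)
  bias_at <- function(h) {
    d <- sampling_design(times = c(truth - h, truth + h), n_animals = 1,
                         noise_sd = 0)
    analyze_series(simulate_series(m, d))$time_days - truth
  }
  biases <- vapply(c(16, 8, 4, 2), bias_at, numeric(1))
  expect_true(all(diff(abs(biases)) < 0))
})

test_that("one-sided early sampling produces a systematic, signed bias", {
  m <- ref_model()
  truth <- true_break_even(m)
  d <- sampling_design(times = c(2, 6), n_animals = 1, noise_sd = 0)
  res <- analyze_series(simulate_series(m, d),
                        breakeven_config(max_extrapolation_factor = 100))
  bias <- res$time_days - truth
  expect_gt(abs(bias), 0.5)
  # far below the crossing both curves are at their steepest, so the secant
  # overstates the closing speed and the projection lands early
  expect_lt(bias, 0)
})

test_that("bias_study summarizes estimator error against the true crossing", {
  m <- ref_model()
  d <- sampling_design(times = c(14, 35), n_animals = 4, noise_sd = 1,
                       seed = 5)
  out <- bias_study(m, d, reps = 50)
  expect_equal(out$true_crossing, true_break_even(m))
  expect_gte(out$rmse, abs(out$bias))
  expect_equal(length(out$estimates), 50)
  expect_gte(out$status_coverage, 0.9)
  # reproducible end to end: the seed lives in the design
  expect_equal(bias_study(m, d, reps = 50)$estimates, out$estimates)
})

test_that("bootstrap collapses to the point estimate for identical animals", {
  s <- constant_replicate_series()
  bs <- bootstrap_break_even(s, reps = 100, seed = 1)
  expect_equal(bs$lower, bs$point)
  expect_equal(bs$upper, bs$point)
  expect_equal(bs$frac_nonconvergent, 0)
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  m <- ref_model()
  d <- sampling_design(times = c(14, 35), n_animals = 6, noise_sd = 2, seed = 3)
  s <- simulate_series(m, d)
  b1 <- bootstrap_break_even(s, reps = 200, seed = 42)
  b2 <- bootstrap_break_even(s, reps = 200, seed = 42)
  expect_identical(b1$times, b2$times)
  expect_identical(c(b1$lower, b1$upper), c(b2$lower, b2$upper))
  expect_true(b1$lower <= b1$point && b1$point <= b1$upper)
})

test_that("bootstrap refuses group-mean series", {
  expect_error(bootstrap_break_even(autogenous_series(), reps = 10),
               "replicates")
  one_animal <- healing_series(c(14, 56), c(6, 30), c(40, 10),
                               animal_id = c("r1", "r1"))
  expect_error(bootstrap_break_even(one_animal, reps = 10), "2 animals")
})
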