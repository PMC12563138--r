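#' Sampling design for simulated histomorphometry
#'
#' Describes when and how a simulated study samples the kinetic curves:
#' biopsy times, number of animals per time point, and the standard deviation
#' of additive measurement noise on the percent scale.
#'
#' @param times Sampling days, strictly increasing and positive.
#' @param n_animals Replicates per time point (>= 1).
#' @param noise_sd Standard deviation of additive Gaussian noise, percent
#'   (>= 0). The defaults are illustrative: published group-mean tables carry
#'   no inter-animal variance to calibrate against.
#' @param seed Optional integer seed. When set, [simulate_series()] is
#'   deterministic; when `NULL`, the current RNG stream is used (this is how
#'   [bias_study()] threads one generator through all of its replicates).
#' @return An object of class `sampling_design`.
#' @examples
#' sampling_design(times = c(14, 70), n_animals = 6, noise_sd = 2, seed = 1)
#' @export
sampling_design <- function(times, n_animals = 1, noise_sd = 0, seed = NULL) {
  if (!is.numeric(times) || length(times) < 2 || any(!is.finite(times)) ||
      any(times <= 0) || any(diff(times) <= 0)) {
    abort("`times` must be at least two strictly increasing positive days.")
  }
  if (!is.numeric(n_animals) || length(n_animals) != 1 || n_animals < 1) {
    abort("`n_animals` must be a single count >= 1.")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number.")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(times = as.numeric(times), n_animals = as.integer(n_animals),
         noise_sd = as.numeric(noise_sd), seed = seed),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("<sampling_design>\n")
  cat("  times (d):", paste(x$times, collapse = ", "), "\n")
  cat("  n_animals:", x$n_animals, " noise_sd:", x$noise_sd, "%\n")
  cat("  seed:", if (is.null(x$seed)) "none (current RNG)" else x$seed, "\n")
  invisible(x)
}

#' Simulate a healing series from nonlinear kinetics
#'
#' Draws, for every animal and time point, the curve values of a
#' [kinetic_model()] plus independent Gaussian noise, truncates to the
#' physical range `[0, 100]`, and rescales bone and graft proportionally
#' whenever their sum exceeds 100% so the compositional constraint holds.
#'
#' @param model A [kinetic_model()].
#' @param design A [sampling_design()].
#' @param study,material Labels attached to the simulated series.
#' @return A [healing_series()]; animal-level (with `animal_id`) when
#'   `n_animals > 1`, group-level otherwise.
#' @examples
#' m <- kinetic_model(b_max = 40, k_bone = 0.05, g0 = 50, g_res = 0, k_graft = 0.03)
#' d <- sampling_design(times = c(14, 70), n_animals = 4, noise_sd = 2, seed = 42)
#' simulate_series(m, d)
#' @export
simulate_series <- function(model, design, study = "simulated",
                            material = "simulated") {
  stopifnot(inherits(model, "kinetic_model"), inherits(design, "sampling_design"))
  draw <- function() {
    grid <- expand.grid(animal = seq_len(design$n_animals),
                        time_days = design$times)
    b <- bone_fraction(model, grid$time_days)
    g <- graft_fraction(model, grid$time_days)
    if (design$noise_sd > 0) {
      b <- b + rnorm(nrow(grid), sd = design$noise_sd)
      g <- g + rnorm(nrow(grid), sd = design$noise_sd)
    }
    b <- pmin(pmax(b, 0), 100)
    g <- pmin(pmax(g, 0), 100)
    s <- b + g
    over <- s > 100
    b[over] <- b[over] * 100 / s[over]
    g[over] <- g[over] * 100 / s[over]
    healing_series(
      time_days = grid$time_days, new_bone_pct = b, residual_graft_pct = g,
      animal_id = if (design$n_animals > 1) sprintf("a%02d", grid$animal) else NULL,
      study = study, material = material
    )
  }
  if (is.null(design$seed)) draw() else withr::with_seed(design$seed, draw())
}

#' Bias of the linear estimator under nonlinear kinetics
#'
#' Repeatedly simulates a study from known nonlinear kinetics, applies the
#' linear break-even estimator ([analyze_series()]) to each simulated
#' dataset, and summarizes the error of the linear estimate against the true
#' crossing time ([true_break_even()]). One generator, seeded once from the
#' design, drives all replicates in order, so results are reproducible.
#'
#' @param model A [kinetic_model()] whose curves cross.
#' @param design A [sampling_design()]; its `seed` (default 1 when unset)
#'   seeds the single RNG stream.
#' @param reps Number of simulated datasets (>= 1).
#' @param config A [breakeven_config()] passed to the estimator.
#' @return An object of class `bias_study_result` with fields
#'   `true_crossing`, `mean_estimate`, `bias`, `rmse` (all days, over the
#'   convergent replicates) and `status_coverage` (fraction of replicates
#'   classified `within_interval` or `extrapolated`).
#' @examples
#' m <- kinetic_model(b_max = 40, k_bone = 0.05, g0 = 50, g_res = 0, k_graft = 0.03)
#' d <- sampling_design(times = c(14, 70), n_animals = 4, noise_sd = 1, seed = 7)
#' bias_study(m, d, reps = 20)
#' @export
bias_study <- function(model, design, reps, config = breakeven_config()) {
  stopifnot(inherits(model, "kinetic_model"), inherits(design, "sampling_design"))
  if (!is.numeric(reps) || length(reps) != 1 || reps < 1) {
    abort("`reps` must be a single count >= 1.")
  }
  reps <- as.integer(reps)
  truth <- true_break_even(model)
  inner <- design
  inner$seed <- NULL
  seed <- if (is.null(design$seed)) 1L else design$seed
  results <- withr::with_seed(seed, {
    lapply(seq_len(reps), function(i) analyze_series(simulate_series(model, inner), config))
  })
  status <- vapply(results, function(r) r$status, character(1))
  est <- vapply(results, function(r) r$time_days, numeric(1))
  ok <- status %in% c("within_interval", "extrapolated")
  est_ok <- est[ok]
  structure(
    list(
      true_crossing = truth,
      mean_estimate = if (length(est_ok)) mean(est_ok) else NA_real_,
      bias = if (length(est_ok)) mean(est_ok) - truth else NA_real_,
      rmse = if (length(est_ok)) sqrt(mean((est_ok - truth)^2)) else NA_real_,
      status_coverage = mean(ok),
      reps = reps,
      estimates = est,
      statuses = status
    ),
    class = "bias_study_result"
  )
}

#' @export
print.bias_study_result <- function(x, ...) {
  cat("<bias_study_result>\n")
  cat(sprintf("  true crossing: %.3f d\n", x$true_crossing))
  cat(sprintf("  mean estimate: %.3f d  (bias %+.3f d, rmse %.3f d)\n",
              x$mean_estimate, x$bias, x$rmse))
  cat(sprintf("  convergent replicates: %.1f%% of %d\n",
              100 * x$status_coverage, x$reps))
  invisible(x)
}

#' Bootstrap interval for the break-even time
#'
#' Resamples animals with replacement within each time point (the
#' randomization unit of the source studies), re-estimates the break-even
#' point on every resampled dataset, and returns a percentile interval of
#' the crossing time over the convergent resamples.
#'
#' @param series A [healing_series()] with animal-level replicates (at least
#'   two animals per time point).
#' @param reps Number of bootstrap resamples.
#' @param seed Integer seed for the resampling stream.
#' @param conf Confidence level of the percentile interval.
#' @param config A [breakeven_config()].
#' @return An object of class `break_even_bootstrap` with `point` (estimate
#'   on the full data), `lower`, `upper`, `conf`, `reps`,
#'   `frac_nonconvergent` (share of resamples not classified
#'   `within_interval`/`extrapolated`) and the vector `times` of resampled
#'   estimates.
#' @examples
#' m <- kinetic_model(b_max = 40, k_bone = 0.05, g0 = 50, g_res = 0, k_graft = 0.03)
#' d <- sampling_design(times = c(14, 35), n_animals = 6, noise_sd = 2, seed = 3)
#' s <- simulate_series(m, d)
#' bootstrap_break_even(s, reps = 200, seed = 3)
#' @export
bootstrap_break_even <- function(series, reps = 2000, seed = NULL, conf = 0.95,
                                 config = breakeven_config()) {
  stopifnot(inherits(series, "healing_series"))
  if (!has_replicates(series)) {
    abort("Bootstrapping requires animal-level replicates (`animal_id`).")
  }
  obs <- series$observations
  by_time <- split(obs, obs$time_days)
  if (any(vapply(by_time, nrow, integer(1)) < 2)) {
    abort("Bootstrapping requires at least 2 animals per time point.")
  }
  if (!is.numeric(reps) || reps < 1) abort("`reps` must be >= 1.")
  if (!is.numeric(conf) || conf <= 0 || conf >= 1) abort("`conf` must be in (0, 1).")
  reps <- as.integer(reps)

  point <- analyze_series(series, config)

  one <- function() {
    resampled <- lapply(by_time, function(d) d[sample.int(nrow(d), replace = TRUE), ])
    d <- dplyr::bind_rows(resampled)
    s <- healing_series(d$time_days, d$new_bone_pct, d$residual_graft_pct,
                        animal_id = d$animal_id,
                        study = series$study, material = series$material)
    analyze_series(s, config)
  }
  run <- function() lapply(seq_len(reps), function(i) one())
  results <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())

  status <- vapply(results, function(r) r$status, character(1))
  times <- vapply(results, function(r) r$time_days, numeric(1))
  ok <- status %in% c("within_interval", "extrapolated")
  alpha <- (1 - conf) / 2
  ci <- if (any(ok)) {
    unname(quantile(times[ok], probs = c(alpha, 1 - alpha)))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(point = point$time_days, lower = ci[1], upper = ci[2], conf = conf,
         reps = reps, frac_nonconvergent = mean(!ok), times = times),
    class = "break_even_bootstrap"
  )
}

#' @export
print.break_even_bootstrap <- function(x, ...) {
  cat("<break_even_bootstrap>\n")
  cat(sprintf("  point estimate: %.2f d\n", x$point))
  cat(sprintf("  %d%% percentile interval: [%.2f, %.2f] d (%d resamples)\n",
              round(100 * x$conf), x$lower, x$upper, x$reps))
  if (x$frac_nonconvergent > 0) {
    cat(sprintf("  non-convergent resamples: %.1f%%\n", 100 * x$frac_nonconvergent))
  }
  invisible(x)
}
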