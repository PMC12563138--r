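# Shared builders for the test suite. Everything is constructed in code;
# the only file fixture is the bundled rabbit sinus-lift CSV.

fixture_series <- function() {
  as_series_list(read_study_table(breakeven_fixture()))
}

autogenous_series <- function() {
  healing_series(
    time_days = c(7, 35),
    new_bone_pct = c(0.3, 32.7),
    residual_graft_pct = c(22.7, 0),
    study = "Lambert 2011", material = "Autogenous"
  )
}

genos_series <- function() {
  healing_series(
    time_days = c(14, 56),
    new_bone_pct = c(6.17, 26.72),
    residual_graft_pct = c(35.2, 9.62),
    study = "Iida 2017", material = "Gen-Os"
  )
}

# random converging trend pair: bone ascending from below, graft descending,
# crossing somewhere in (t_start, 3 * t_end]
random_trend_pair <- function() {
  t_start <- runif(1, 2, 20)
  t_end <- t_start + runif(1, 5, 30)
  b1 <- runif(1, 0, 20)
  g1 <- b1 + runif(1, 5, 60)                 # graft starts above bone
  slope_b <- runif(1, 0.2, 2)
  slope_g <- slope_b - runif(1, 0.3, 2)      # strictly converging
  dt <- t_end - t_start
  list(
    bone = linear_trend(slope_b, b1 - slope_b * t_start, t_start, t_end),
    graft = linear_trend(slope_g, g1 - slope_g * t_start, t_start, t_end)
  )
}

# independent locator: scan |bone - graft| on a fixed grid
grid_crossing <- function(bone, graft, step = 1e-3, upper = 3 * bone$t_end) {
  grid <- seq(bone$t_start, upper, by = step)
  gap <- abs(trend_at(bone, grid) - trend_at(graft, grid))
  grid[which.min(gap)]
}

# replicate-level series with identical animals (zero variance)
constant_replicate_series <- function(n_animals = 4) {
  healing_series(
    time_days = rep(c(14, 56), each = n_animals),
    new_bone_pct = rep(c(6, 30), each = n_animals),
    residual_graft_pct = rep(c(40, 10), each = n_animals),
    animal_id = rep(sprintf("r%d", seq_len(n_animals)), times = 2)
  )
}
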