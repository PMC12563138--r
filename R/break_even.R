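break_even_statuses <- c("within_interval", "extrapolated", "not_reached",
                         "already_crossed", "divergent")

new_break_even_result <- function(time_days, level_pct, status, segment,
                                  projected_time_days, extrapolation_factor,
                                  study = "", material = "") {
  structure(
    list(
      time_days = time_days,
      level_pct = level_pct,
      status = status,
      segment = segment,
      projected_time_days = projected_time_days,
      extrapolation_factor = extrapolation_factor,
      study = study,
      material = material
    ),
    class = "break_even_result"
  )
}

#' Estimate the break-even point from two fitted trends
#'
#' Solves for the intersection of the ascending bone trend and the descending
#' graft trend fitted on the same segment: the closed-form crossing time is
#' `t* = (intercept_graft - intercept_bone) / (slope_bone - slope_graft)`,
#' and the level is either line evaluated at `t*`. The crossing is then
#' classified:
#'
#' * `within_interval` — `t*` falls inside the fitted segment; an
#'   interpolation, the most reliable case.
#' * `extrapolated` — `t*` lies beyond the last observation but within
#'   `max_extrapolation_factor` times the last observation time; reported
#'   with a footnote in rendered tables.
#' * `not_reached` — the projected crossing lies beyond that bound;
#'   extrapolating that far is considered unreliable and the coordinates are
#'   reported as NA (the projection is retained in
#'   `projected_time_days` for diagnostics).
#' * `already_crossed` — the projected crossing precedes the first
#'   observation while bone already exceeds graft there; the equilibrium was
#'   passed before sampling started.
#' * `divergent` — no forward break-even exists: the lines are parallel, or
#'   bone lies below graft and the gap widens with time (for the usual
#'   ascending-bone/descending-graft orientation this is exactly
#'   `slope_bone <= slope_graft`).
#'
#' @param bone,graft [linear_trend()] objects fitted on the same segment
#'   (see [fit_segment_trends()]).
#' @param config A [breakeven_config()].
#' @return A `break_even_result` with fields `time_days`, `level_pct`
#'   (both `NA` for `not_reached`/`divergent`), `status`, `segment`,
#'   `projected_time_days` and `extrapolation_factor` (`time / t_end`,
#'   defined when the crossing is past the last observation).
#' @examples
#' tr <- fit_segment_trends(healing_series(c(7, 35), c(0.3, 32.7), c(22.7, 0)))
#' estimate_break_even(tr$bone, tr$graft)
#' @export
estimate_break_even <- function(bone, graft, config = breakeven_config()) {
  stopifnot(inherits(bone, "linear_trend"), inherits(graft, "linear_trend"))
  config <- as_breakeven_config(config)
  if (bone$t_start != graft$t_start || bone$t_end != graft$t_end) {
    abort("`bone` and `graft` trends must be fitted on the same segment.")
  }
  segment <- c(bone$t_start, bone$t_end)

  divergent <- function() {
    new_break_even_result(
      time_days = NA_real_, level_pct = NA_real_, status = "divergent",
      segment = segment, projected_time_days = NA_real_,
      extrapolation_factor = NA_real_
    )
  }
  slope_diff <- bone$slope - graft$slope
  if (slope_diff == 0) return(divergent()) # parallel lines never meet

  t_star <- (graft$intercept - bone$intercept) / slope_diff
  # absorb floating-point jitter when the crossing sits on a segment endpoint
  eps <- 1e-9 * max(1, segment[2])
  # a crossing behind the data means the gap only widens going forward:
  # with bone below graft the trends are separating (no break-even exists);
  # with bone already above, the crossing happened before the first sample
  if (t_star < segment[1] - eps &&
      trend_at(bone, segment[1]) < trend_at(graft, segment[1])) {
    return(divergent())
  }
  level <- trend_at(bone, t_star)
  t_end <- segment[2]
  factor <- if (t_star > t_end) t_star / t_end else NA_real_

  if (t_star < segment[1] - eps) {
    status <- "already_crossed"
  } else if (t_star <= t_end + eps) {
    status <- "within_interval"
  } else if (t_star <= config$max_extrapolation_factor * t_end) {
    status <- "extrapolated"
  } else {
    status <- "not_reached"
  }

  keep <- status %in% c("within_interval", "extrapolated", "already_crossed")
  new_break_even_result(
    time_days = if (keep) t_star else NA_real_,
    level_pct = if (keep) level else NA_real_,
    status = status,
    segment = segment,
    projected_time_days = t_star,
    extrapolation_factor = factor
  )
}

#' Analyze one healing series end to end
#'
#' Composes [select_segment()], [fit_segment_trends()] and
#' [estimate_break_even()]: the canonical per-material analysis.
#'
#' @param series A [healing_series()].
#' @param config A [breakeven_config()].
#' @return A `break_even_result` carrying the series' study and material
#'   labels.
#' @examples
#' genos <- healing_series(c(14, 56), c(6.17, 26.72), c(35.2, 9.62),
#'                         study = "Iida 2017", material = "Gen-Os")
#' analyze_series(genos)
#' @export
analyze_series <- function(series, config = breakeven_config()) {
  stopifnot(inherits(series, "healing_series"))
  segment <- select_segment(series)
  trends <- fit_segment_trends(series, segment)
  res <- estimate_break_even(trends$bone, trends$graft, config)
  res$study <- series$study
  res$material <- series$material
  res
}

#' @export
print.break_even_result <- function(x, ...) {
  label <- paste0(
    if (nzchar(x$material)) paste0(" ", x$material) else "",
    if (nzchar(x$study)) paste0(" (", x$study, ")") else ""
  )
  cat("<break_even_result>", label, "\n", sep = "")
  cat(sprintf("  segment: %g-%g d\n", x$segment[1], x$segment[2]))
  if (is.na(x$time_days)) {
    cat("  break-even: NA  [", x$status, "]\n", sep = "")
    if (!is.na(x$projected_time_days)) {
      cat(sprintf("  projected crossing: %.1f d (%.2fx last observation)\n",
                  x$projected_time_days, x$projected_time_days / x$segment[2]))
    }
  } else {
    cat(sprintf("  break-even: %.1f d at %.1f%%  [%s]\n",
                x$time_days, x$level_pct, x$status))
    if (!is.na(x$extrapolation_factor)) {
      cat(sprintf("  extrapolation factor: %.2f\n", x$extrapolation_factor))
    }
  }
  invisible(x)
}

#' Coerce a break-even result to a JSON-compatible list
#'
#' @param x A `break_even_result`.
#' @param ... Unused.
#' @return A named list of scalars (`NULL` for NA coordinates).
#' @export
as.list.break_even_result <- function(x, ...) {
  list(
    study = x$study, material = x$material,
    t_start = x$segment[1], t_end = x$segment[2],
    time_days = if (is.na(x$time_days)) NULL else x$time_days,
    level_pct = if (is.na(x$level_pct)) NULL else x$level_pct,
    status = x$status,
    projected_time_days = if (is.na(x$projected_time_days)) NULL else x$projected_time_days,
    extrapolation_factor = if (is.na(x$extrapolation_factor)) NULL else x$extrapolation_factor
  )
}

#' Compare break-even behavior across materials
#'
#' Runs [analyze_series()] on every series and assembles one comparison row
#' per material, ordered by increasing break-even time with non-convergent
#' series (`not_reached`, `divergent`) last. When the series carry total
#' augmented areas, the dimension loss over the selected segment is included.
#'
#' @param series_list A list of [healing_series()] objects (possibly empty).
#' @param config A [breakeven_config()].
#' @return A tibble with columns `study`, `material`, `t_start`, `t_end`,
#'   `time_days`, `level_pct`, `status`, `extrapolated`,
#'   `extrapolation_factor` and `dimension_loss_pct`.
#' @examples
#' tbl <- read_study_table(breakeven_fixture())
#' compare_materials(as_series_list(tbl))
#' @export
compare_materials <- function(series_list, config = breakeven_config()) {
  config <- as_breakeven_config(config)
  empty <- tibble::tibble(
    study = character(), material = character(),
    t_start = numeric(), t_end = numeric(),
    time_days = numeric(), level_pct = numeric(),
    status = character(), extrapolated = logical(),
    extrapolation_factor = numeric(), dimension_loss_pct = numeric()
  )
  if (length(series_list) == 0) return(empty)
  rows <- lapply(series_list, function(s) {
    res <- analyze_series(s, config)
    means <- series_means(s)
    dl <- NA_real_
    if ("total_area_mm2" %in% names(means)) {
      a <- means$total_area_mm2[match(res$segment, means$time_days)]
      if (!anyNA(a) && a[1] > 0) {
        dl <- dimension_loss(a[1], a[2], res$segment[1], res$segment[2])$loss_pct
      }
    }
    tibble::tibble(
      study = s$study, material = s$material,
      t_start = res$segment[1], t_end = res$segment[2],
      time_days = res$time_days, level_pct = res$level_pct,
      status = res$status,
      extrapolated = identical(res$status, "extrapolated"),
      extrapolation_factor = res$extrapolation_factor,
      dimension_loss_pct = dl
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$time_days)
}

#' Dimension loss between two healing periods
#'
#' Percent reduction of the total augmented area between two time points,
#' `(area_t1 - area_t2) / area_t1 * 100`. Distinct from the change in graft
#' fraction: it tracks shrinkage of the grafted region itself. A gain is
#' reported as a negative loss.
#'
#' @param area_t1,area_t2 Total augmented areas (mm^2) at the earlier and
#'   later time point; `area_t1` must be positive.
#' @param t1,t2 The two time points in days, `t2 > t1`.
#' @return A list of class `dimension_loss_result` with `loss_pct` and
#'   `period`.
#' @examples
#' dimension_loss(10, 5, 14, 70) # 50% loss
#' @export
dimension_loss <- function(area_t1, area_t2, t1, t2) {
  if (!is.numeric(area_t1) || area_t1 <= 0) {
    abort("`area_t1` must be a positive area.")
  }
  if (!is.numeric(area_t2) || area_t2 < 0) abort("`area_t2` must be non-negative.")
  if (!(t2 > t1)) abort("`t2` must be later than `t1`.")
  structure(
    list(loss_pct = (area_t1 - area_t2) / area_t1 * 100,
         period = c(as.numeric(t1), as.numeric(t2))),
    class = "dimension_loss_result"
  )
}

#' @export
print.dimension_loss_result <- function(x, ...) {
  cat(sprintf("<dimension_loss_result> %.1f%% over %g-%g d\n",
              x$loss_pct, x$period[1], x$period[2]))
  invisible(x)
}
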