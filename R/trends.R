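#' Linear trend over a time segment
#'
#' A straight line in (percent vs days) space anchored on the two observations
#' that delimit a segment of a healing series. Two-point fits are exact: the
#' line passes through both anchoring observations.
#'
#' @param slope Percent per day.
#' @param intercept Percent at day 0.
#' @param t_start,t_end Days spanned by the fitted segment (`t_start < t_end`).
#' @return An object of class `linear_trend`.
#' @examples
#' tr <- linear_trend(slope = 1.2, intercept = -5, t_start = 7, t_end = 35)
#' trend_at(tr, c(7, 35))
#' @export
linear_trend <- function(slope, intercept, t_start, t_end) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            is.numeric(t_start), is.numeric(t_end))
  if (!(t_start < t_end)) abort("`t_start` must be strictly less than `t_end`.")
  structure(
    list(slope = as.numeric(slope), intercept = as.numeric(intercept),
         t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
    class = "linear_trend"
  )
}

#' Evaluate a linear trend
#'
#' @param trend A [linear_trend()].
#' @param t Times in days (vectorized).
#' @return Percent values at `t`.
#' @export
trend_at <- function(trend, t) {
  stopifnot(inherits(trend, "linear_trend"))
  trend$intercept + trend$slope * t
}

#' @export
print.linear_trend <- function(x, ...) {
  cat(sprintf("<linear_trend> %.4g + %.4g * t  on [%g, %g] d\n",
              x$intercept, x$slope, x$t_start, x$t_end))
  invisible(x)
}

#' Fit two-point trend lines over one segment of a healing series
#'
#' Draws the straight line through the bone observations at the two segment
#' endpoints, and likewise for the graft observations. With replicates the
#' per-timepoint group means anchor the lines. These exact two-point fits are
#' the linear-progression assumption under which the break-even point is
#' estimated.
#'
#' @param series A [healing_series()].
#' @param segment Numeric pair of times (days); both must be observed time
#'   points of the series. Defaults to [select_segment()].
#' @return A list with components `bone` and `graft`, each a [linear_trend()].
#' @examples
#' s <- healing_series(c(7, 35), c(0.3, 32.7), c(22.7, 0))
#' fit_segment_trends(s)
#' @export
fit_segment_trends <- function(series, segment = select_segment(series)) {
  stopifnot(inherits(series, "healing_series"))
  if (length(segment) != 2 || !is.numeric(segment)) {
    abort("`segment` must be a numeric pair of times in days.")
  }
  segment <- sort(as.numeric(segment))
  if (segment[1] == segment[2]) abort("Segment times must be distinct.")
  means <- series_means(series)
  idx <- match(segment, means$time_days)
  if (anyNA(idx)) {
    abort(sprintf("Segment time(s) %s not observed in the series.",
                  paste(segment[is.na(idx)], collapse = ", ")))
  }
  anchor <- means[idx, ]
  two_point <- function(y) {
    slope <- (y[2] - y[1]) / (segment[2] - segment[1])
    linear_trend(slope = slope, intercept = y[1] - slope * segment[1],
                 t_start = segment[1], t_end = segment[2])
  }
  list(bone = two_point(anchor$new_bone_pct),
       graft = two_point(anchor$residual_graft_pct))
}

#' Select the segment to interpolate over
#'
#' With more than two time points, the pair of adjacent observations closest
#' to the anticipated crossing gives the most reliable linear estimate. The
#' selection scans adjacent pairs in time order and returns the earliest pair
#' across which the sign of (bone - graft) changes or touches zero; when the
#' difference never changes sign within the data, the crossing is anticipated
#' beyond the last observation and the last pair is returned.
#'
#' @param series A [healing_series()].
#' @return Numeric pair of times in days.
#' @examples
#' s <- healing_series(c(7, 21, 42), c(10, 25, 40), c(40, 30, 30))
#' select_segment(s) # (21, 42): bone - graft changes sign there
#' @export
select_segment <- function(series) {
  stopifnot(inherits(series, "healing_series"))
  means <- series_means(series)
  if (nrow(means) < 2) abort("A healing series needs at least 2 distinct time points.")
  d <- means$new_bone_pct - means$residual_graft_pct
  for (i in seq_len(nrow(means) - 1)) {
    if ((d[i] <= 0 && d[i + 1] >= 0) || (d[i] >= 0 && d[i + 1] <= 0)) {
      return(c(means$time_days[i], means$time_days[i + 1]))
    }
  }
  c(means$time_days[nrow(means) - 1], means$time_days[nrow(means)])
}
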