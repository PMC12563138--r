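#' Estimator configuration
#'
#' Settings shared by the break-even estimator and the reporting layer.
#'
#' @param max_extrapolation_factor Upper bound on forward extrapolation,
#'   expressed as a multiple of the last observation time. A projected
#'   crossing at time `t* > t_end` is reported as `extrapolated` while
#'   `t* <= max_extrapolation_factor * t_end`, and as `not_reached` beyond
#'   that. The default of 1.5 accepts crossings projected up to half again
#'   the observed healing period; there is no biological consensus value, so
#'   the bound is explicit and configurable.
#' @param report_digits Number of decimals used when formatting reports.
#'   Internal values are never rounded.
#'
#' @return A list of class `breakeven_config`.
#' @examples
#' breakeven_config()
#' breakeven_config(max_extrapolation_factor = 2)
#' @export
breakeven_config <- function(max_extrapolation_factor = 1.5, report_digits = 1) {
  if (!is.numeric(max_extrapolation_factor) || length(max_extrapolation_factor) != 1 ||
      is.na(max_extrapolation_factor) || max_extrapolation_factor < 1) {
    abort("`max_extrapolation_factor` must be a single number >= 1.")
  }
  if (!is.numeric(report_digits) || length(report_digits) != 1 ||
      is.na(report_digits) || report_digits < 0) {
    abort("`report_digits` must be a single non-negative number.")
  }
  structure(
    list(
      max_extrapolation_factor = as.numeric(max_extrapolation_factor),
      report_digits = as.integer(report_digits)
    ),
    class = "breakeven_config"
  )
}

#' @export
print.breakeven_config <- function(x, ...) {
  cat("<breakeven_config>\n")
  cat("  max_extrapolation_factor:", x$max_extrapolation_factor, "\n")
  cat("  report_digits:", x$report_digits, "\n")
  invisible(x)
}

as_breakeven_config <- function(config) {
  if (inherits(config, "breakeven_config")) return(config)
  if (is.null(config)) return(breakeven_config())
  abort("`config` must be created with breakeven_config().")
}
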