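#' Construct a healing series
#'
#' A healing series holds the histomorphometric observations for one graft
#' material in one study: at each healing time, the percentage of the
#' evaluated tissue area occupied by newly formed bone and by residual graft.
#' Observations may be group means (one row per time point) or animal-level
#' replicates (`animal_id` set); replicates are aggregated to the arithmetic
#' group mean per time point before any trend fitting, which mirrors how
#' published histomorphometric tables report their data.
#'
#' @param time_days Healing time in days; strictly positive.
#' @param new_bone_pct Newly formed bone, percent of evaluated tissue area.
#' @param residual_graft_pct Residual graft, percent of evaluated tissue area.
#' @param animal_id Optional replicate labels; `NULL` means group means.
#' @param total_area_mm2 Optional total augmented area (mm^2), used for
#'   dimension-loss reporting.
#' @param study Study label (free text).
#' @param material Graft material label (free text).
#'
#' @return An object of class `healing_series` with fields `study`,
#'   `material` and `observations` (a tibble).
#' @examples
#' healing_series(
#'   time_days = c(7, 35),
#'   new_bone_pct = c(0.3, 32.7),
#'   residual_graft_pct = c(22.7, 0),
#'   study = "Lambert 2011", material = "Autogenous"
#' )
#' @export
healing_series <- function(time_days, new_bone_pct, residual_graft_pct,
                           animal_id = NULL, total_area_mm2 = NULL,
                           study = "", material = "") {
  n <- length(time_days)
  if (length(new_bone_pct) != n || length(residual_graft_pct) != n) {
    abort("`time_days`, `new_bone_pct` and `residual_graft_pct` must have equal length.")
  }
  obs <- tibble::tibble(
    time_days = as.numeric(time_days),
    new_bone_pct = as.numeric(new_bone_pct),
    residual_graft_pct = as.numeric(residual_graft_pct)
  )
  if (!is.null(animal_id)) {
    if (length(animal_id) != n) abort("`animal_id` must match the number of observations.")
    obs$animal_id <- as.character(animal_id)
  }
  if (!is.null(total_area_mm2)) {
    if (length(total_area_mm2) != n) abort("`total_area_mm2` must match the number of observations.")
    obs$total_area_mm2 <- as.numeric(total_area_mm2)
  }
  validate_observations(obs)
  times <- sort(unique(obs$time_days))
  if (length(times) < 2) {
    abort("A healing series needs at least 2 distinct time points.")
  }
  obs <- obs[order(obs$time_days), , drop = FALSE]
  structure(
    list(study = as.character(study), material = as.character(material),
         observations = obs),
    class = "healing_series"
  )
}

validate_observations <- function(obs) {
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0) {
      abort(sprintf("%s (observation %s).", msg, paste(i, collapse = ", ")))
    }
  }
  bad(!is.finite(obs$time_days) | obs$time_days <= 0,
      "Healing times must be positive")
  bad(!is.finite(obs$new_bone_pct) | obs$new_bone_pct < 0 | obs$new_bone_pct > 100,
      "New bone percentages must lie in [0, 100]")
  bad(!is.finite(obs$residual_graft_pct) | obs$residual_graft_pct < 0 |
        obs$residual_graft_pct > 100,
      "Residual graft percentages must lie in [0, 100]")
  bad(obs$new_bone_pct + obs$residual_graft_pct > 100 + 1e-9,
      "Bone and graft fractions sum above 100%")
  invisible(obs)
}

#' Per-timepoint group means of a healing series
#'
#' Aggregates animal-level replicates (when present) to the arithmetic mean
#' per time point and returns one row per time point, sorted ascending.
#'
#' @param series A [healing_series()].
#' @return A tibble with columns `time_days`, `new_bone_pct`,
#'   `residual_graft_pct` and, when areas were supplied, `total_area_mm2`.
#' @examples
#' s <- healing_series(
#'   time_days = c(7, 7, 35, 35),
#'   new_bone_pct = c(1, 3, 30, 34),
#'   residual_graft_pct = c(20, 24, 1, 3),
#'   animal_id = c("r1", "r2", "r1", "r2")
#' )
#' series_means(s)
#' @export
series_means <- function(series) {
  stopifnot(inherits(series, "healing_series"))
  obs <- series$observations
  out <- obs |>
    dplyr::group_by(.data$time_days) |>
    dplyr::summarise(
      new_bone_pct = mean(.data$new_bone_pct),
      residual_graft_pct = mean(.data$residual_graft_pct),
      dplyr::across(dplyr::any_of("total_area_mm2"), mean),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time_days)
  out
}

has_replicates <- function(series) {
  "animal_id" %in% names(series$observations)
}

#' @export
print.healing_series <- function(x, ...) {
  label <- paste0(
    if (nzchar(x$material)) x$material else "unnamed material",
    if (nzchar(x$study)) paste0(" (", x$study, ")") else ""
  )
  cat("<healing_series> ", label, "\n", sep = "")
  if (has_replicates(x)) {
    cat("  ", nrow(x$observations), " observations (animal-level) at ",
        length(unique(x$observations$time_days)), " time points\n", sep = "")
  }
  print(series_means(x), ...)
  invisible(x)
}
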