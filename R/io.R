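time_unit_days <- c(day = 1, week = 7, month = 30)

#' Read a study table of histomorphometric measurements
#'
#' Reads a tidy CSV with one row per study, material and time point (and
#' animal, when replicate-level data are available)
#' and validates it. Required columns: `study`, `material`, `time_value`,
#' `time_unit` (`day`, `week` or `month`), `new_bone_pct`,
#' `residual_graft_pct`; optional: `animal_id`, `total_area_mm2`. Times are
#' converted to days (week = 7 d, month = 30 d) into a `time_days` column.
#'
#' @param path Path to a UTF-8, comma-separated file with a header.
#' @return A tibble of class `study_table`.
#' @examples
#' tbl <- read_study_table(breakeven_fixture())
#' dplyr::count(tbl, study, material)
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_study_table(raw)
}

#' Validate a data frame as a study table
#'
#' @param x A data frame with the columns documented in [read_study_table()].
#' @return A tibble of class `study_table` with `time_days` filled in.
#' @export
as_study_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("study", "material", "time_value", "time_unit",
                "new_bone_pct", "residual_graft_pct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  row_err <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0) {
      abort(sprintf("%s in row(s) %s.", msg, paste(i, collapse = ", ")))
    }
  }
  x$time_unit <- tolower(trimws(as.character(x$time_unit)))
  row_err(!x$time_unit %in% names(time_unit_days), "Unknown time unit")
  x$time_value <- as.numeric(x$time_value)
  row_err(!is.finite(x$time_value) | x$time_value <= 0, "Non-positive time value")
  for (col in c("new_bone_pct", "residual_graft_pct")) {
    x[[col]] <- as.numeric(x[[col]])
    row_err(!is.finite(x[[col]]) | x[[col]] < 0 | x[[col]] > 100,
            sprintf("`%s` outside [0, 100]", col))
  }
  row_err(x$new_bone_pct + x$residual_graft_pct > 100 + 1e-9,
          "Bone and graft percentages sum above 100")
  x$time_days <- x$time_value * unname(time_unit_days[x$time_unit])
  class(x) <- c("study_table", class(x))
  x
}

#' Write a study table back to CSV
#'
#' Writes the user-facing columns (without the derived `time_days`), so that
#' reading the result with [read_study_table()] round-trips.
#'
#' @param x A `study_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  keep <- intersect(
    c("study", "material", "time_value", "time_unit",
      "new_bone_pct", "residual_graft_pct", "animal_id", "total_area_mm2"),
    names(x)
  )
  readr::write_csv(tibble::as_tibble(x)[, keep], path, progress = FALSE)
  invisible(path)
}

#' Split a study table into healing series
#'
#' Groups rows by (study, material) — in their order of first appearance —
#' and builds one [healing_series()] per group.
#'
#' @param x A `study_table` from [read_study_table()] or [as_study_table()].
#' @return A named list of [healing_series()] objects
#'   (`"study: material"` keys).
#' @examples
#' series <- as_series_list(read_study_table(breakeven_fixture()))
#' names(series)
#' @export
as_series_list <- function(x) {
  if (!inherits(x, "study_table")) x <- as_study_table(x)
  key <- paste(x$study, x$material, sep = ": ")
  groups <- split(seq_len(nrow(x)), factor(key, levels = unique(key)))
  lapply(groups, function(i) {
    d <- x[i, ]
    healing_series(
      time_days = d$time_days,
      new_bone_pct = d$new_bone_pct,
      residual_graft_pct = d$residual_graft_pct,
      animal_id = if ("animal_id" %in% names(d)) d$animal_id else NULL,
      total_area_mm2 = if ("total_area_mm2" %in% names(d)) d$total_area_mm2 else NULL,
      study = d$study[1], material = d$material[1]
    )
  })
}

#' Path to the bundled rabbit sinus-lift dataset
#'
#' Group-mean new-bone and residual-graft percentages for six biomaterials
#' (autogenous bone chips, Bio-Oss in two studies, Bio-Oss Collagen,
#' Maxresorb granules and paste, Gen-Os) from four published rabbit sinus
#' floor elevation experiments, each measured at two healing times.
#'
#' @return Path to the bundled CSV file.
#' @examples
#' read_study_table(breakeven_fixture())
#' @export
breakeven_fixture <- function() {
  system.file("extdata", "rabbit_sinus_lift.csv", package = "breakeven",
              mustWork = TRUE)
}
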