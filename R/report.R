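#' Render a comparison table as text or CSV
#'
#' Formats the output of [compare_materials()] the way published
#' histomorphometric comparisons are laid out: one row per material with the
#' analyzed period, the break-even coordinates, and the dimension loss when
#' areas were supplied. Non-convergent rows show `NA` coordinates;
#' extrapolated estimates carry an `a` footnote marker indicating that the
#' trend lines had not yet converged by the last observation, so the estimate
#' assumes linear behavior beyond it.
#'
#' @param comparison A tibble from [compare_materials()].
#' @param format `"text"` for an aligned plain-text table, `"csv"` for CSV.
#' @param digits Decimals for the day and percent columns.
#' @param path Optional output file; when `NULL` the rendering is returned.
#' @return A character vector of lines, invisibly when `path` is given.
#' @examples
#' cmp <- compare_materials(as_series_list(read_study_table(breakeven_fixture())))
#' cat(render_report(cmp), sep = "\n")
#' @export
render_report <- function(comparison, format = c("text", "csv"), digits = 1,
                          path = NULL) {
  format <- match.arg(format)
  fmt_num <- function(x, mark = rep(FALSE, length(x))) {
    out <- ifelse(is.na(x), "NA",
                  formatC(round(x, digits), format = "f", digits = digits))
    ifelse(mark & !is.na(x), paste0(out, " a"), out)
  }
  n <- nrow(comparison)
  mark <- if (n) comparison$extrapolated else logical(0)
  cells <- data.frame(
    study = as.character(comparison$study),
    material = as.character(comparison$material),
    period = if (n) sprintf("%g-%g d", comparison$t_start, comparison$t_end) else character(0),
    days = fmt_num(comparison$time_days, mark),
    level_pct = fmt_num(comparison$level_pct, mark),
    status = as.character(comparison$status),
    stringsAsFactors = FALSE
  )
  header <- c("study", "material", "period", "days", "level_pct", "status")
  if (n && any(!is.na(comparison$dimension_loss_pct))) {
    cells$dimension_loss_pct <- fmt_num(comparison$dimension_loss_pct)
    header <- c(header, "dimension_loss_pct")
  }

  lines <- if (format == "csv") {
    esc <- function(x) {
      needs <- grepl('[",\n]', x)
      x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
      x
    }
    rows <- if (n) {
      apply(cells, 1, function(r) paste(esc(unname(r)), collapse = ","))
    } else {
      character(0)
    }
    c(paste(header, collapse = ","), rows)
  } else {
    mat <- rbind(header, as.matrix(cells))
    widths <- apply(nchar(mat), 2, max)
    apply(mat, 1, function(r) {
      padded <- mapply(function(v, w) formatC(v, width = w, flag = "-"),
                       r, widths)
      trimws(paste(padded, collapse = "  "), which = "right")
    })
  }
  lines <- unname(lines)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
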