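#' Plot the crossing of bone and graft trend lines
#'
#' Draws the ascending new-bone line and the descending residual-graft line
#' over the fitted segment, with the break-even point marked when the
#' estimate is usable. For extrapolated estimates the continuation beyond the
#' last observation is dashed, making the assumption of linear behavior past
#' the data visually explicit; for non-convergent series only the observed
#' segments are drawn.
#'
#' @param series A [healing_series()].
#' @param result The matching `break_even_result`; defaults to
#'   [analyze_series()] on `series`.
#' @param path Optional output file (`.png`, `.svg`, `.pdf`); when given, the
#'   plot is saved there.
#' @param width,height Device size in inches when saving.
#' @return A ggplot object, invisibly when `path` is given.
#' @examples
#' s <- healing_series(c(7, 35), c(0.3, 32.7), c(22.7, 0),
#'                     study = "Lambert 2011", material = "Autogenous")
#' p <- plot_crossing(s)
#' @export
plot_crossing <- function(series, result = analyze_series(series), path = NULL,
                          width = 6, height = 4) {
  stopifnot(inherits(series, "healing_series"),
            inherits(result, "break_even_result"))
  trends <- fit_segment_trends(series, result$segment)
  seg <- result$segment

  seg_df <- function(trend, tissue, t0, t1, part) {
    tibble::tibble(
      time_days = c(t0, t1),
      pct = trend_at(trend, c(t0, t1)),
      tissue = tissue, part = part,
      grp = paste(tissue, part)
    )
  }
  dat <- dplyr::bind_rows(
    seg_df(trends$bone, "new bone", seg[1], seg[2], "observed"),
    seg_df(trends$graft, "residual graft", seg[1], seg[2], "observed")
  )
  show_point <- !is.na(result$time_days)
  if (show_point && result$time_days > seg[2]) {
    dat <- dplyr::bind_rows(
      dat,
      seg_df(trends$bone, "new bone", seg[2], result$time_days, "extrapolated"),
      seg_df(trends$graft, "residual graft", seg[2], result$time_days, "extrapolated")
    )
  }

  title <- trimws(paste(series$material, if (nzchar(series$study)) paste0("(", series$study, ")") else ""))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_days, y = .data$pct,
                                         colour = .data$tissue,
                                         linetype = .data$part,
                                         group = .data$grp)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_linetype_manual(
      values = c(observed = "solid", extrapolated = "dashed"), guide = "none"
    ) +
    ggplot2::scale_colour_manual(
      values = c("new bone" = "#2166ac", "residual graft" = "#b2182b"),
      name = NULL
    ) +
    ggplot2::labs(
      title = title,
      subtitle = if (show_point) {
        sprintf("break-even at %.1f d / %.1f%% (%s)",
                result$time_days, result$level_pct, result$status)
      } else {
        sprintf("no break-even estimate (%s)", result$status)
      },
      x = "healing time (days)", y = "% of evaluated tissue area"
    ) +
    ggplot2::theme_minimal()
  if (show_point) {
    p <- p + ggplot2::annotate("point", x = result$time_days,
                               y = result$level_pct, size = 2.5)
  }
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 150)
  invisible(p)
}
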