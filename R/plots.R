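#' Box plot of hydrodynamic radii per condition
#'
#' One box per condition over the per-representative hydrodynamic radii —
#' the standard ensemble-compactness comparison figure.
#'
#' @param report a `comparison_report`.
#' @return A ggplot object.
#' @export
plot_radius_boxplot <- function(report) {
  df <- rbind(
    data.frame(condition = "WT", radius = report$radius$wt$radii),
    data.frame(condition = "variant", radius = report$radius$variant$radii))
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = radius,
                                   fill = condition)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "hydrodynamic radius (Å)") +
    ggplot2::theme_minimal()
}

#' Bar chart of the flagged F-F pairs
#'
#' Side-by-side bars of the wild-type and variant mean distances for every
#' F-F pair whose percent variation exceeds the flag threshold.
#'
#' @param report a `comparison_report`.
#' @return A ggplot object (empty plot if no pairs are flagged).
#' @export
plot_variation_bars <- function(report) {
  fp <- report$cohesion$flagged_pairs
  if (NROW(fp) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no F-F pairs above threshold") +
             ggplot2::theme_void())
  }
  fp$pair <- paste0("F", fp$site_i, "-F", fp$site_j)
  long <- rbind(
    data.frame(pair = fp$pair, condition = "WT", distance = fp$d_wt),
    data.frame(pair = fp$pair, condition = "variant", distance = fp$d_var))
  ggplot2::ggplot(long, ggplot2::aes(x = pair, y = distance,
                                     fill = condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "F-F pair", y = "mean distance (Å)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Emit the report figures as SVG files
#'
#' Writes the radius box plot, the flagged-pair bar chart and the two
#' cohesion network drawings (edge thickness increasing with distance)
#' under `dir`.
#'
#' @param report a `comparison_report` (fresh from [run_comparison()], so
#'   the full cohesion object is attached).
#' @param dir output directory.
#' @return Character vector of the files written, invisibly.
#' @export
report_figures <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f1 <- file.path(dir, "radius_boxplot.svg")
  grDevices::svg(f1, width = 5, height = 4)
  print(plot_radius_boxplot(report)); grDevices::dev.off()
  f2 <- file.path(dir, "ff_variation_bars.svg")
  grDevices::svg(f2, width = 7, height = 4)
  print(plot_variation_bars(report)); grDevices::dev.off()
  files <- c(f1, f2)
  cohesion <- attr(report, "cohesion_full")
  if (!is.null(cohesion)) {
    for (cond in c("wt", "variant")) {
      g <- cohesion_network(cohesion, cond)
      f <- file.path(dir, sprintf("network_%s.svg", cond))
      grDevices::svg(f, width = 6, height = 6)
      plot(g, edge.width = igraph::E(g)$thickness,
           layout = igraph::layout_in_circle(g),
           main = sprintf("F-F network (%s)", cond))
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}
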