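## Figure helpers for the uptake analytics.

#' @importFrom rlang .data
NULL

#' Butterfly plot of differential deuterium uptake
#'
#' Per-peptide uptake differences along the sequence, one line per
#' labeling time, with the max-replicate-SD significance band shaded
#' symmetrically about zero.
#'
#' @param diffs data.frame from [butterflyDifferences()].
#' @return a ggplot object.
#' @export
plotButterfly <- function(diffs) {
  thr <- attr(diffs, "threshold")
  d <- diffs
  d$mid <- (d$start + d$end) / 2
  d$time <- factor(d$time_s)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$diff_da,
                                        colour = .data$time,
                                        group = .data$time))
  if (!is.null(thr))
    gg <- gg + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                                 ymin = -thr, ymax = thr,
                                 alpha = 0.2, fill = "grey50")
  gg + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "residue (peptide midpoint)",
                  y = "uptake difference (Da)",
                  colour = "labeling time (s)") +
    ggplot2::theme_minimal()
}

#' Residue-level relative-uptake heat map
#'
#' @param mat matrix from [heatmapMatrix()] (residues x times).
#' @return a ggplot object; uncovered residues are rendered as missing.
#' @export
plotUptakeHeatmap <- function(mat) {
  df <- expand.grid(residue = as.integer(rownames(mat)),
                    time_s = as.numeric(colnames(mat)))
  df$rel_uptake <- as.vector(mat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                   y = factor(.data$time_s),
                                   fill = .data$rel_uptake)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "residue", y = "labeling time (s)",
                  fill = "relative uptake") +
    ggplot2::theme_minimal()
}
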