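#' Plot an ensemble MSD curve with its SEM band
#'
#' @param curve ensemble `msd_curve` (columns `tau_s`, `msd_um2`, `sem`).
#' @param add add to an existing plot.
#' @param col curve color.
#' @param ... passed to [plot()].
#' @return invisibly, the curve.
#' @export
plot_ensemble_msd <- function(curve, add = FALSE, col = "black", ...) {
  if (!add)
    plot(curve$tau_s, curve$msd_um2, type = "n",
         xlab = expression(tau ~ "(s)"),
         ylab = expression(MSD ~ (mu * m^2)), ...)
  if (!is.null(curve$sem)) {
    graphics::polygon(c(curve$tau_s, rev(curve$tau_s)),
                      c(curve$msd_um2 - curve$sem,
                        rev(curve$msd_um2 + curve$sem)),
                      col = grDevices::adjustcolor(col, alpha.f = 0.25),
                      border = NA)
  }
  graphics::lines(curve$tau_s, curve$msd_um2, col = col, lwd = 2)
  invisible(curve)
}

#' Plot the apparent -log10 D series over delay time
#' @param curve `msd_curve`.
#' @param d dimensionality (default 2).
#' @param ... passed to [plot()].
#' @return invisibly, the series from [logD_vs_time()].
#' @export
plot_logD_vs_time <- function(curve, d = 2, ...) {
  s <- logD_vs_time(curve, d)
  plot(s$tau_s, s$neg_log10_D_app, type = "b", pch = 16,
       xlab = expression(tau ~ "(s)"),
       ylab = expression(-log[10] ~ D[app]), ...)
  invisible(s)
}

#' Boxplot of a per-track statistic by condition
#' @param values per-track statistic (e.g. alpha or neg_log10_D).
#' @param groups condition labels.
#' @param ylab y-axis label.
#' @param ... passed to [boxplot()].
#' @return invisibly, the per-group [box_stats()] table.
#' @export
plot_group_box <- function(values, groups, ylab = "value", ...) {
  graphics::boxplot(values ~ groups, range = 1.5, ylab = ylab,
                    xlab = "", ...)
  invisible(do.call(rbind, lapply(sort(unique(groups)), function(g)
    cbind(group = g, box_stats(values[groups == g])))))
}

#' Pie chart of motion-class fractions
#' @param fractions output of [class_fractions()].
#' @param ... passed to [pie()].
#' @return invisibly, `fractions`.
#' @export
plot_class_pie <- function(fractions, ...) {
  keep <- fractions$count > 0
  graphics::pie(fractions$count[keep],
                labels = sprintf("%s (%.0f%%)",
                                 fractions$motion_class[keep],
                                 100 * fractions$fraction[keep]),
                col = c(anomalous_confined = "grey60",
                        brownian = "firebrick",
                        directed = "forestgreen")[
                          fractions$motion_class[keep]], ...)
  invisible(fractions)
}
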