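#' Plot a group difference spectrum with significance bars
#'
#' Base-graphics rendering of one channel's patient-minus-control difference
#' curve, with horizontal bars under the axis marking bins covered by
#' significant clusters (thin bar: permutation p < 0.05, thick bar:
#' p < 0.01), in the convention of clinical QEEG difference plots.
#'
#' @param contrast output of [groupDifferenceSpectra()]
#' @param result the matching [ClusterTestResult-class]
#' @param channel channel label
#' @param ... passed on to [graphics::plot()]
#' @return invisibly, the significance-bar table for the channel
#' @export
plotDifferenceSpectrum <- function(contrast, result, channel, ...) {
  stopifnot(channel %in% rownames(contrast$difference))
  y <- contrast$difference[channel, ]
  f <- contrast$freq
  ylab <- if (contrast$measure == "relAmplitude")
    "difference, % relative amplitude" else "difference, power"
  yr <- range(y)
  pad <- 0.15 * diff(yr)
  graphics::plot(f, y, type = "l", xlab = "frequency (Hz)", ylab = ylab,
                 ylim = c(yr[1] - 2 * pad, yr[2]),
                 main = sprintf("%s (%s)", channel, contrast$condition), ...)
  graphics::abline(h = 0, lty = 3)
  bars <- significanceBars(result, channel)
  for (i in seq_len(nrow(bars))) {
    lw <- if (bars$level[i] <= 0.01) 4 else 2
    yb <- yr[1] - (if (bars$level[i] <= 0.01) 2 else 1) * pad * 0.8
    graphics::segments(f[bars$binStart[i]], yb, f[bars$binEnd[i]], yb,
                       lwd = lw)
  }
  invisible(bars)
}
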