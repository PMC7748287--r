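# Quick-look base-graphics plots for the standard behavioural summaries.

#' Plot per-stimulus learning curves
#'
#' @param perf output of [aggregate_performance()].
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the wide curve matrix.
#' @export
plot_performance <- function(perf, ...) {
  labs <- sort(unique(perf$label))
  triplets <- sort(unique(perf$triplet))
  m <- sapply(labs, function(l)
    perf$mean[perf$label == l][order(perf$triplet[perf$label == l])])
  graphics::matplot(triplets, m, type = "b", pch = 1:3, lty = 1,
                    xlab = "triplet", ylab = "proportion correct",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = labs, pch = 1:3,
                   col = seq_along(labs), lty = 1, bty = "n")
  invisible(m)
}

#' Plot the reaction-time curve over representative steps
#'
#' @param rt output of [aggregate_rt()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `rt`.
#' @export
plot_rt <- function(rt, ...) {
  graphics::plot(rt$step, rt$mean, type = "b", pch = 16,
                 xlab = "representative step",
                 ylab = "reaction time (planning cycles)", ...)
  graphics::arrows(rt$step, rt$mean - rt$se, rt$step, rt$mean + rt$se,
                   angle = 90, code = 3, length = 0.03)
  invisible(rt)
}
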