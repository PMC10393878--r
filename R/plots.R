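#' Bland-Altman plot
#'
#' @param ba A [bland_altman()] result with `means` recorded.
#' @param xlab,ylab,main Plot labels.
#' @export
plot_bland_altman <- function(ba, xlab = "mean vFFR",
                              ylab = "difference (reference - test)",
                              main = "Bland-Altman agreement") {
  means <- ba$means %||% seq_along(ba$differences)
  graphics::plot(means, ba$differences, pch = 19, col = "grey30",
                 xlab = xlab, ylab = ylab, main = main,
                 ylim = range(c(ba$differences, ba$loa_low, ba$loa_high)))
  graphics::abline(h = ba$bias, col = "firebrick", lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "firebrick",
                   lty = 2)
  invisible(ba)
}

#' Fidelity sweep summary panel (duration and accuracy vs fidelity)
#'
#' Strip plots of per-case duration and accuracy with median/IQR bars,
#' matching the structure of a fidelity benchmarking report.
#'
#' @param summary A [sweep_summary()] result.
#' @export
plot_fidelity_sweep <- function(summary) {
  pairs <- summary$pairs
  bf <- summary$by_fidelity
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  xj <- jitter(match(pairs$fidelity_percent, bf$fidelity_percent), 0.4)
  graphics::plot(xj, pairs$duration_s, pch = 19,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xaxt = "n", xlab = "fidelity (%)", ylab = "duration (s)",
                 main = "simulation duration")
  graphics::axis(1, at = seq_len(nrow(bf)), labels = bf$fidelity_percent)
  graphics::segments(seq_len(nrow(bf)) - 0.2, bf$duration_median,
                     seq_len(nrow(bf)) + 0.2, bf$duration_median, lwd = 3)
  graphics::plot(xj, pairs$accuracy_pct, pch = 19,
                 col = grDevices::adjustcolor("darkorange", 0.5),
                 xaxt = "n", xlab = "fidelity (%)", ylab = "accuracy (%)",
                 main = "accuracy vs reference")
  graphics::axis(1, at = seq_len(nrow(bf)), labels = bf$fidelity_percent)
  graphics::segments(seq_len(nrow(bf)) - 0.2, bf$accuracy_median,
                     seq_len(nrow(bf)) + 0.2, bf$accuracy_median, lwd = 3)
  invisible(summary)
}
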