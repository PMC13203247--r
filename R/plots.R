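#' Plot a dose-response sweep
#'
#' Two panels: mean undershoot and mean 1--3 Hz band power against the
#' proprioceptive gain, with across-trial SD bars. The sham (0.25) and
#' stimulation (0.70) gains are highlighted when present in the grid.
#'
#' @param x A [dose_response_sweep()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dose_response_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.2, 4.2, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(mu, sd, ylab, main) {
    ylim <- range(mu - sd, mu + sd, na.rm = TRUE)
    graphics::plot(x$g_proprio, mu, type = "b", pch = 19, ylim = ylim,
                   xlab = "proprioceptive gain", ylab = ylab, main = main,
                   ...)
    graphics::arrows(x$g_proprio, mu - sd, x$g_proprio, mu + sd,
                     angle = 90, code = 3, length = 0.03)
    hl <- x$g_proprio %in% c(0.25, 0.70)
    if (any(hl))
      graphics::points(x$g_proprio[hl], mu[hl], pch = 21, cex = 1.8,
                       bg = c("blue", "red")[seq_len(sum(hl))])
  }
  panel(x$undershoot_mean, x$undershoot_sd, "undershoot (%)",
        "Undershoot vs gain")
  panel(x$band_power_1_3_mean, x$band_power_1_3_sd,
        expression(paste("1-3 Hz power (", N^2, ")")),
        "Corrective power vs gain")
  invisible(x)
}

#' Plot a simulated trial
#'
#' Summed bimanual force over the full trial, with the target line, the
#' epoch switch, and the (summed) internal target after visual feedback is
#' removed.
#'
#' @param x A [simulate_trial()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.simulated_trial <- function(x, ...) {
  p <- x$params
  target <- 2 * p$target_per_hand
  fsum <- x$force_left + x$force_right
  graphics::plot(x$time, fsum, type = "l", col = "grey30",
                 xlab = "time (s)", ylab = "summed force (N)",
                 main = sprintf("Simulated trial (g_proprio = %.2f)",
                                p$g_proprio), ...)
  graphics::abline(h = target, col = "darkgreen", lty = 2)
  graphics::abline(v = p$vision_off_time, col = "grey60", lty = 3)
  graphics::lines(x$time, 2 * x$internal_target, col = "orange", lty = 1)
  graphics::legend("bottomleft",
                   legend = c("summed force", "target", "internal target"),
                   col = c("grey30", "darkgreen", "orange"),
                   lty = c(1, 2, 1), bty = "n", cex = 0.8)
  invisible(x)
}
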