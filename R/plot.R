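#' Scatter of per-station beta diversity with the fitted broken stick
#'
#' @param fit a `breakpoint_fit`.
#' @param x,y the data the fit was computed from.
#' @param ... passed to [graphics::plot()].
#' @export
plot_breakpoint <- function(fit, x, y, ...) {
  graphics::plot(x, y, pch = 19, col = "grey30",
                 xlab = "gradient", ylab = "beta diversity", ...)
  xs <- seq(min(x), max(x), length.out = 200)
  b <- fit$coefficients
  graphics::lines(xs, b[1] + b[2] * xs + b[3] * pmax(0, xs - fit$psi),
                  col = "firebrick", lwd = 2)
  graphics::abline(v = fit$psi, lty = 2)
  invisible(fit)
}

#' Occupancy versus dispersion bubble plot
#'
#' Bubble areas follow the convention of replacing a class's total-abundance
#' circle area with sqrt(abundance) / pi.
#'
#' @param evenness data frame from [dispersion_evenness()].
#' @param ... passed to [graphics::symbols()].
#' @export
plot_evenness_bubbles <- function(evenness, ...) {
  radius <- sqrt(sqrt(evenness$total_abundance) / pi)
  graphics::symbols(evenness$occupancy, evenness$dispersion,
                    circles = radius / max(radius),
                    inches = 0.15, fg = "steelblue",
                    xlab = "occupancy (stations)", ylab = "dispersion J",
                    ...)
  invisible(evenness)
}
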