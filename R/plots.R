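## Diagnostic plots (base graphics, in the display-unit convention of the
## peak finder).

#' Plot extracted input/output curves
#'
#' Scatter of the [input; output] mode pairs in display units, one panel
#' per output channel, high branch in color and low branch in grey; an
#' optional stable-integration mode table is overlaid as open circles.
#'
#' @param io data.frame from \code{\link{extractIOPoints}}.
#' @param stableModes optional data.frame from
#'   \code{\link{extractStableModes}}.
#' @param channels output channels to draw.
#' @return invisibly, NULL.
#' @export
plotIOCurve <- function(io, stableModes = NULL,
                        channels = unique(io$channel)) {
  op <- graphics::par(mfrow = c(1, length(channels)))
  on.exit(graphics::par(op))
  for (ch in channels) {
    sub <- io[io$channel == ch, , drop = FALSE]
    col <- ifelse(sub$outputBranch == "HIGH", "#d95f02", "#7570b3")
    graphics::plot(sub$inputMode, sub$outputMode, col = col, pch = 3,
                   xlab = "input mode (display units)",
                   ylab = "output mode (display units)", main = ch)
    if (!is.null(stableModes)) {
      ss <- stableModes[stableModes$channel == ch, , drop = FALSE]
      ## stable frames carry no input mode; use matched dox rank order
      graphics::points(rank(ss$dox) / length(unique(ss$dox)) *
                         diff(range(sub$inputMode)) + min(sub$inputMode),
                       ss$mode, pch = 1, col = "grey40")
    }
  }
  invisible(NULL)
}

#' Histogram of one channel with its fitted modes
#'
#' @param values display-transformed channel values.
#' @param rules fit rule set used.
#' @return invisibly, the mode table.
#' @export
plotModeFit <- function(values, rules = inputFitRules()) {
  m <- fitModes(values, rules)
  graphics::hist(values, breaks = seq(min(values) - rules@binWidth,
                                      max(values) + rules@binWidth,
                                      by = rules@binWidth),
                 freq = FALSE, col = "grey85", border = "white",
                 xlab = "display units", main = "")
  graphics::abline(v = m$mode, col = "#d95f02", lwd = 2)
  invisible(m)
}
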