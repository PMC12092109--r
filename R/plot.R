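#' Plot a length/height profile along the tail
#'
#' Draws centrum length and total height against caudal position, the style
#' in which whip-tailed reptile vertebral columns are usually presented. The
#' crossing of the two curves is the transition point to the whip-like
#' segment; when detectable it is marked with a vertical line.
#'
#' @param x a `tail_profile` (see [tail_profile()]).
#' @param mark_tp logical; mark the first position where length exceeds
#'   height.
#' @param ... passed on to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.tail_profile <- function(x, mark_tp = TRUE, ...) {
  graphics::matplot(x$position, cbind(x$height_cm, x$length_cm),
                    type = "o", pch = c(1, 16), lty = c(2, 1),
                    col = c("grey40", "black"),
                    xlab = "caudal position (Ca)",
                    ylab = "measurement (cm)", ...)
  if (mark_tp && any(x$ratio > 1)) {
    tp <- x$position[which(x$ratio > 1)[1L]]
    graphics::abline(v = tp, col = "red3", lty = 3)
    graphics::mtext(paste0("TP = Ca", tp), side = 3, at = tp, cex = 0.8,
                    col = "red3")
  }
  graphics::legend("topright", c("total height", "centrum length"),
                   pch = c(1, 16), lty = c(2, 1), col = c("grey40", "black"),
                   bty = "n")
  invisible(x)
}
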