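#' Plot rarefaction curves
#'
#' Pan- and core-genome size against the number of genomes included.
#' Boxes span +/- one standard deviation around the per-n median; the
#' fitted Heaps curve is overlaid when supplied.
#'
#' @param x a `"rarefaction"` object.
#' @param fit optional `"heaps_fit"` to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot_rarefaction <- function(x, fit = NULL, ...) {
  stopifnot(inherits(x, "rarefaction"))
  n <- x$n
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  draw <- function(med, sd, main, col) {
    graphics::plot(n, med, type = "n",
                   ylim = range(c(med - 2 * sd, med + 2 * sd), na.rm = TRUE),
                   xlab = "genomes included", ylab = "genes", main = main, ...)
    graphics::arrows(n, med - 2 * sd, n, med + 2 * sd,
                     angle = 90, code = 3, length = 0.02, col = "grey60")
    graphics::rect(n - 0.3, med - sd, n + 0.3, med + sd,
                   col = col, border = "grey30")
    graphics::segments(n - 0.3, med, n + 0.3, med, lwd = 2)
  }
  draw(x$core_median, x$core_sd, "core genome", "lightblue")
  draw(x$pan_median, x$pan_sd, "pan-genome", "lightsalmon")
  if (!is.null(fit)) {
    graphics::curve(fit$kappa * x^fit$gamma, from = 1, to = max(n),
                    add = TRUE, col = "red", lwd = 2)
  }
  invisible(x)
}
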