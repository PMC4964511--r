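#' Diagnostic plots for codon-usage analyses
#'
#' Base-graphics renderings of the three standard displays: the ENC plot
#' (per-gene ENC against GC3s with the mutational null curve), the
#' neutrality scatter (GC12 against GC3 with the fitted regression line),
#' and the ENC-ratio frequency histogram.
#'
#' @param gc3s,encObs per-gene GC3s and observed ENC.
#' @param ... further arguments passed to [graphics::plot()].
#' @return NULL, invisibly.
#' @examples
#' sim <- generateGenes(syntheticSpec(nGenes = 50, seed = 2))
#' idx <- geneIndices(sim$sequences)
#' plotEncCurve(idx$gc3s, idx$enc)
#' @export
plotEncCurve <- function(gc3s, encObs, ...) {
  graphics::plot(gc3s, encObs, xlim = c(0, 1), ylim = c(15, 62),
                 xlab = "GC3s", ylab = "ENC", pch = 20,
                 col = grDevices::grey(0.3, 0.6), ...)
  s <- seq(0, 1, length.out = 256)
  graphics::lines(s, encExpected(s), lwd = 2)
  invisible(NULL)
}

#' @rdname plotEncCurve
#' @param gc3,gc12 per-gene fractions for the neutrality scatter.
#' @param fit optional [NeutralityFit-class]; fitted from the points when
#'   omitted.
#' @export
plotNeutrality <- function(gc3, gc12, fit = NULL, ...) {
  graphics::plot(gc3, gc12, xlab = "GC3", ylab = "GC12", pch = 20,
                 col = grDevices::grey(0.3, 0.6), ...)
  if (is.null(fit)) fit <- neutralityFit(gc3, gc12)
  graphics::abline(intercept(fit), slope(fit), lwd = 2)
  invisible(NULL)
}

#' @rdname plotEncCurve
#' @param ratios per-gene ENC ratios.
#' @param binWidth histogram bin width.
#' @export
plotEncRatioHist <- function(ratios, binWidth = 0.1, ...) {
  h <- encRatioHistogram(ratios, binWidth = binWidth)
  graphics::barplot(h$count, names.arg = sprintf("%.1f", h$bin_lo),
                    xlab = "(ENCexp - ENCobs) / ENCexp",
                    ylab = "genes", ...)
  invisible(NULL)
}
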