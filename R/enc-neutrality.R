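#' Expected ENC under mutation alone
#'
#' The null-curve value of the effective number of codons for a gene whose
#' synonymous third-position G+C content is `s` (GC3s), under mutational
#' pressure only: `2 + s + 29 / (s^2 + (1 - s)^2)`. The curve peaks at
#' s = 0.5 (value 60.5) and falls to 31 at s = 0 and 32 at s = 1.
#'
#' @param s GC3s value(s) in `[0, 1]`.
#' @return Expected ENC value(s).
#' @examples
#' encExpected(c(0, 0.5, 1))
#' @export
encExpected <- function(s) {
  if (any(s < 0 | s > 1, na.rm = TRUE))
    stop("GC3s values must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' ENC ratio: relative departure from the null curve
#'
#' `(ENCexp - ENCobs) / ENCexp`, positive when the gene is more biased than
#' expected from its GC3s alone, negative when less.
#'
#' @param encObs observed ENC value(s); NA propagates.
#' @param s GC3s value(s) in `[0, 1]`.
#' @return Numeric ratio(s).
#' @examples
#' encRatio(30.25, 0.5)  # 0.5
#' @export
encRatio <- function(encObs, s) {
  e <- encExpected(s)
  (e - encObs) / e
}

#' Frequency distribution of ENC ratios
#'
#' Bins defined ENC-ratio values into left-closed, right-open intervals of
#' width `binWidth`, aligned to integer multiples of `binWidth` and spanning
#' the data range.
#'
#' @param ratios numeric ENC ratios; NAs are dropped.
#' @param binWidth bin width, default 0.1.
#' @return A data.frame with columns `bin_lo`, `bin_hi`, `count`; the counts
#'   sum to the number of defined ratios.
#' @examples
#' encRatioHistogram(c(0.05, 0.05, 0.15))
#' @export
encRatioHistogram <- function(ratios, binWidth = 0.1) {
  r <- ratios[!is.na(ratios)]
  if (!length(r)) stop("no defined ENC ratios to bin")
  lo <- floor(min(r) / binWidth)
  hi <- floor(max(r) / binWidth)
  edges <- (lo:(hi + 1L)) * binWidth
  idx <- findInterval(r, edges, rightmost.closed = FALSE)
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
             count = cnt)
}

#' Neutrality regression of GC12 on GC3
#'
#' Fit of the neutrality plot: ordinary least squares of per-gene GC12 on
#' GC3, with the Pearson correlation and its two-sided t-test p-value. A
#' slope of 1 indicates complete neutrality (mutation alone shapes all codon
#' positions equally); a slope of 0 indicates no directional mutation
#' pressure (complete selective constraint). The slope is reported as the
#' mutation share, its complement to 1 as the selection share, without
#' endorsing a strict causal reading.
#'
#' @slot slope,intercept OLS coefficients of GC12 on GC3.
#' @slot pearsonR,rSquared,pValue Pearson correlation, its square, and the
#'   two-sided p-value.
#' @slot nGenes number of points used.
#' @slot mutationShare,selectionShare slope and 1 - slope.
#' @export
setClass("NeutralityFit",
         representation(slope = "numeric", intercept = "numeric",
                        pearsonR = "numeric", rSquared = "numeric",
                        pValue = "numeric", nGenes = "integer",
                        mutationShare = "numeric",
                        selectionShare = "numeric"))

setValidity("NeutralityFit", function(object) {
  msg <- character()
  if (abs(object@rSquared - object@pearsonR^2) > 1e-12)
    msg <- c(msg, "rSquared must equal pearsonR^2")
  if (abs(object@mutationShare + object@selectionShare - 1) > 1e-12)
    msg <- c(msg, "mutation and selection shares must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NeutralityFit", function(object) {
  cat(sprintf("Neutrality fit (GC12 ~ GC3), n = %d genes\n", object@nGenes))
  cat(sprintf("  slope %.4f, intercept %.4f\n",
              object@slope, object@intercept))
  cat(sprintf("  Pearson r = %.3f (r^2 = %.4f), p = %.3g\n",
              object@pearsonR, object@rSquared, object@pValue))
  cat(sprintf("  mutation share %.2f%%, other factors %.2f%%\n",
              100 * object@mutationShare, 100 * object@selectionShare))
})

#' @describeIn NeutralityFit-class Fit the neutrality regression.
#' @param gc3,gc12 per-gene fractions (or percentages, which leave slope and
#'   r unchanged); pairs with NA are dropped.
#' @return A `NeutralityFit` object.
#' @examples
#' f <- neutralityFit(gc3 = (1:10)/10, gc12 = (1:10)/10)
#' slope(f)
#' @export
neutralityFit <- function(gc3, gc12) {
  ok <- !is.na(gc3) & !is.na(gc12)
  gc3 <- gc3[ok]; gc12 <- gc12[ok]
  if (length(gc3) < 3L)
    stop("neutrality fit needs at least 3 complete (gc3, gc12) points")
  if (sd(gc3) == 0)
    stop("gc3 has zero variance; regression is degenerate")
  fit <- lm(gc12 ~ gc3)
  b <- unname(coef(fit))
  if (sd(gc12) == 0) {
    r <- 0; p <- 1   # flat response: no association, slope 0 exactly
  } else {
    ct <- cor.test(gc3, gc12, method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  new("NeutralityFit", slope = b[2L], intercept = b[1L],
      pearsonR = r, rSquared = r^2, pValue = p,
      nGenes = length(gc3), mutationShare = b[2L],
      selectionShare = 1 - b[2L])
}

#' @describeIn NeutralityFit-class OLS slope (the mutation share).
#' @param object a `NeutralityFit`.
#' @export
slope <- function(object) object@slope

#' @describeIn NeutralityFit-class OLS intercept.
#' @export
intercept <- function(object) object@intercept

#' @describeIn NeutralityFit-class Pearson correlation coefficient.
#' @export
pearsonR <- function(object) object@pearsonR

#' @describeIn NeutralityFit-class two-sided p-value of the correlation.
#' @export
pValue <- function(object) object@pValue

#' @describeIn NeutralityFit-class fit parameters as a one-row data.frame.
#' @export
neutralityFitTable <- function(object) {
  data.frame(slope = object@slope, intercept = object@intercept,
             pearson_r = object@pearsonR, r_squared = object@rSquared,
             p_value = object@pValue, n_genes = object@nGenes,
             mutation_share = object@mutationShare,
             selection_share = object@selectionShare)
}
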