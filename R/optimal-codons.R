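#' High- and low-bias gene subsets by ENC ratio
#'
#' Orders genes by ENC ratio (descending; ties broken by gene id for
#' determinism) and takes the `fraction` of sequences from either end:
#' the "high bias" subset holds the genes whose observed ENC falls furthest
#' below the null expectation, the "low bias" subset the genes closest to
#' (or above) it. Subset size is `ceiling(fraction * N)`.
#'
#' @param geneIds character vector of gene ids.
#' @param ratios per-gene ENC ratios ([encRatio()]); NAs are dropped (with
#'   their ids) before ranking.
#' @param fraction tail fraction, default 0.05.
#' @return A list with `highIds`, `lowIds`, `subsetSize`, `fraction`.
#'   Errors if the two subsets would overlap.
#' @examples
#' selectBiasSubsets(letters[1:10], ratios = (1:10)/20)$subsetSize
#' @export
selectBiasSubsets <- function(geneIds, ratios, fraction = 0.05) {
  stopifnot(length(geneIds) == length(ratios),
            fraction > 0, fraction < 0.5)
  ok <- !is.na(ratios)
  geneIds <- geneIds[ok]; ratios <- ratios[ok]
  n <- length(geneIds)
  size <- as.integer(ceiling(fraction * n))
  if (2L * size > n)
    stop("subsets of size ", size, " would overlap with only ", n, " genes")
  ord <- order(-ratios, geneIds)
  list(highIds = geneIds[ord[seq_len(size)]],
       lowIds = geneIds[rev(ord)[seq_len(size)]],
       subsetSize = size, fraction = fraction)
}

#' Optimal-codon determination table
#'
#' Per-codon contrast between the pooled RSCU of the high-bias and low-bias
#' gene subsets. A sense codon of a multi-codon family is flagged optimal
#' when `delta_rscu = rscu_high - rscu_low` is strictly greater than the
#' threshold; stop codons, Met and Trp are reported but never optimal.
#' Codons whose family is absent from either subset get NA delta and are
#' never optimal.
#'
#' @slot table data.frame with columns `amino_acid`, `codon`, `rscu_high`,
#'   `n_high`, `rscu_low`, `n_low`, `delta_rscu`, `optimal`.
#' @slot threshold the delta-RSCU cutoff used.
#' @export
setClass("OptimalCodonTable",
         representation(table = "data.frame", threshold = "numeric"))

setValidity("OptimalCodonTable", function(object) {
  tb <- object@table
  d <- tb$rscu_high - tb$rscu_low
  ok <- !is.na(d)
  if (any(abs(d[ok] - tb$delta_rscu[ok]) > 1e-9))
    return("delta_rscu must equal rscu_high - rscu_low")
  if (any(tb$optimal & is.na(d)))
    return("codons with undefined delta cannot be optimal")
  TRUE
})

setMethod("show", "OptimalCodonTable", function(object) {
  tb <- object@table
  cat(sprintf("Optimal-codon table: %d optimal of %d codons (delta RSCU > %g)\n",
              sum(tb$optimal), nrow(tb), object@threshold))
  cat("  optimal:", paste(tb$codon[tb$optimal], collapse = " "), "\n")
})

#' @describeIn OptimalCodonTable-class the underlying data.frame.
#' @param object an `OptimalCodonTable`.
#' @export
optimalCodonTable <- function(object) object@table

#' @describeIn OptimalCodonTable-class codons flagged optimal.
#' @export
optimalCodonSet <- function(object) {
  tb <- object@table
  sort(tb$codon[tb$optimal])
}

#' Compute the optimal-codon table from subset counts
#'
#' @param highCounts,lowCounts pooled codon counts (named vector or genes x
#'   64 matrix) of the high- and low-bias subsets.
#' @param threshold delta-RSCU cutoff, strict (`>`); default 0.08.
#' @param code a [GeneticCode-class] object.
#' @return An [OptimalCodonTable-class].
#' @examples
#' hi <- c(AAA = 10, AAG = 90); lo <- c(AAA = 45, AAG = 55)
#' optimalCodonSet(optimalCodons(hi, lo))
#' @export
optimalCodons <- function(highCounts, lowCounts, threshold = 0.08,
                          code = standardGeneticCode()) {
  hv <- .as_count_vector(highCounts, code)
  lv <- .as_count_vector(lowCounts, code)
  if (sum(hv) == 0 || sum(lv) == 0)
    stop("both subset count tables must be non-empty")
  rh <- rscu(hv, includeStops = TRUE, code = code)
  rl <- rscu(lv, includeStops = TRUE, code = code)
  aa <- geneticCodeMap(code)
  deg <- geneticCodeDegeneracy(code)
  codons <- geneticCodeCodons(code)
  eligible <- aa[codons] != "*" & deg[aa[codons]] >= 2L
  eligible[is.na(eligible)] <- FALSE
  delta <- rh - rl
  optimal <- !is.na(delta) & delta > threshold & eligible
  tb <- data.frame(amino_acid = aaThreeLetter(aa[codons]),
                   codon = codons,
                   rscu_high = unname(rh), n_high = unname(hv),
                   rscu_low = unname(rl), n_low = unname(lv),
                   delta_rscu = unname(delta),
                   optimal = unname(optimal),
                   row.names = NULL)
  # present in family order like a codon usage table
  tb <- tb[order(tb$amino_acid, tb$codon), ]
  rownames(tb) <- NULL
  new("OptimalCodonTable", table = tb, threshold = threshold)
}

#' Third-position base tally of optimal codons
#'
#' @param x an [OptimalCodonTable-class].
#' @return Named integer vector of counts over A, C, G, T third bases of the
#'   optimal codons.
#' @examples
#' hi <- c(AAA = 10, AAG = 90); lo <- c(AAA = 45, AAG = 55)
#' endingBaseTally(optimalCodons(hi, lo))
#' @export
endingBaseTally <- function(x) {
  opt <- optimalCodonSet(x)
  third <- substring(opt, 3L, 3L)
  vapply(c(A = "A", C = "C", G = "G", T = "T"),
         function(b) sum(third == b), integer(1))
}
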