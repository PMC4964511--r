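#' Published codon-usage summary tables for Epichloe festucae
#'
#' Two small reference tables transcribed from a published genome-wide codon
#' usage study of the grass endophyte *Epichloe festucae* (strain E2368,
#' 4870 filtered CDS), shipped as plain-text TSV in `extdata`. They let the
#' optimal-codon and RSCU machinery be exercised against real genome-scale
#' numbers without downloading the genome.
#'
#' `efestucaeCodonUsage()` returns the genome-wide per-codon totals and the
#' RSCU values as printed (amino acid, codon, count, rscu_printed). Note the
#' printed counts and printed RSCU are not perfectly mutually consistent in
#' the source; both are returned unchanged.
#'
#' `efestucaeOptimalCodons()` returns the published high-/low-bias subset
#' contrast (244 genes from each end of the ENC-ratio ordering): per codon,
#' the subset RSCU values, subset counts, and whether the codon was starred
#' as optimal.
#'
#' @param asDna if TRUE (default) codons are returned as DNA (U replaced by
#'   T) to match the rest of the package; FALSE keeps the printed RNA form.
#' @return A data.frame; see above.
#' @examples
#' head(efestucaeCodonUsage())
#' @export
efestucaeCodonUsage <- function(asDna = TRUE) {
  path <- system.file("extdata", "efestucae_codon_usage.tsv",
                      package = "codonBias", mustWork = TRUE)
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (asDna) tb$codon <- chartr("U", "T", tb$codon)
  tb
}

#' @rdname efestucaeCodonUsage
#' @export
efestucaeOptimalCodons <- function(asDna = TRUE) {
  path <- system.file("extdata", "efestucae_optimal_codons.tsv",
                      package = "codonBias", mustWork = TRUE)
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (asDna) tb$codon <- chartr("U", "T", tb$codon)
  tb
}

#' @describeIn efestucaeCodonUsage the genome-wide totals as a named
#'   64-codon count vector, ready for [rscu()] or [enc()].
#' @export
efestucaeCodonCounts <- function() {
  tb <- efestucaeCodonUsage(asDna = TRUE)
  setNames(tb$count, tb$codon)[geneticCodeCodons()]
}
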