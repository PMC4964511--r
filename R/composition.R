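#' Per-gene nucleotide-composition indices
#'
#' Computes, for each coding sequence, the G+C fraction overall (GC) and at
#' each codon position (GC1, GC2, GC3), their positional mean GC12 =
#' (GC1 + GC2)/2, and the synonymous third-position fractions GC3s, A3s,
#' T3s, C3s and G3s. The terminal stop codon is excluded from every index;
#' ambiguous codons are skipped. GC/GC1/GC2/GC3 are taken over all remaining
#' coding codons; the x3s indices use only third positions of synonymous
#' codons, i.e. codons of amino acids with two or more synonyms (Met, Trp
#' and stop codons excluded from the denominator), so A3s+T3s+C3s+G3s = 1.
#'
#' @param seqs a [Biostrings::DNAStringSet], or a precomputed genes x 64
#'   codon count matrix from `countCodons(..., dropTerminalStop = TRUE)`.
#' @param code a [GeneticCode-class] object.
#' @return A data.frame with one row per gene: `gene_id`, `length_nt`,
#'   `n_codons` (countable coding codons), `gc`, `gc1`, `gc2`, `gc3`,
#'   `gc12`, `gc3s`, `a3s`, `t3s`, `c3s`, `g3s`. Fractions are in `[0, 1]`;
#'   x3s values are NA when a gene has no synonymous codons.
#' @examples
#' compositionProfile(Biostrings::DNAStringSet(c(g = "GGAGGA")))
#' @export
compositionProfile <- function(seqs, code = standardGeneticCode()) {
  if (is.matrix(seqs)) {
    counts <- seqs
    lenNt <- NA_integer_
    ids <- rownames(counts)
  } else {
    counts <- countCodons(seqs, dropTerminalStop = TRUE, code = code)
    lenNt <- nchar(as.character(seqs))
    ids <- names(seqs)
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  codons <- colnames(counts)
  bases <- vapply(1:3, function(p) substring(codons, p, p), character(64L))
  gcInd <- bases %in% c("G", "C")
  dim(gcInd) <- dim(bases)
  nCod <- rowSums(counts)
  if (any(nCod == 0))
    warning("genes with zero countable codons yield NA composition: ",
            paste(ids[nCod == 0], collapse = ", "))
  gcPos <- counts %*% gcInd / nCod        # genes x 3
  gc1 <- gcPos[, 1]; gc2 <- gcPos[, 2]; gc3 <- gcPos[, 3]
  gc <- (gc1 + gc2 + gc3) / 3
  gc12 <- (gc1 + gc2) / 2

  deg <- geneticCodeDegeneracy(code)
  aa <- geneticCodeMap(code)
  syn <- aa[codons] != "*" & deg[aa[codons]] >= 2L
  syn[is.na(syn)] <- FALSE
  third <- bases[, 3]
  synDen <- rowSums(counts[, syn, drop = FALSE])
  x3s <- vapply(c("A", "T", "C", "G"), function(b)
    rowSums(counts[, syn & third == b, drop = FALSE]) / synDen,
    numeric(nrow(counts)))
  if (nrow(counts) == 1L) x3s <- matrix(x3s, nrow = 1L,
                                        dimnames = list(NULL, c("A", "T", "C", "G")))
  gc3s <- x3s[, "G"] + x3s[, "C"]
  data.frame(gene_id = ids, length_nt = lenNt, n_codons = as.integer(nCod),
             gc = gc, gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = gc12,
             gc3s = gc3s, a3s = x3s[, "A"], t3s = x3s[, "T"],
             c3s = x3s[, "C"], g3s = x3s[, "G"],
             row.names = NULL)
}

#' Pooled composition summary across genes
#'
#' Unweighted mean and sample standard deviation (n - 1 denominator) of each
#' per-gene index, in the style of a genome-summary "mean +/- SD" table,
#' plus the total countable codon count.
#'
#' @param profiles data.frame from [compositionProfile()], optionally with
#'   further numeric index columns (ENC, CAI, GRAVY, ...) appended, e.g.
#'   from [geneIndices()].
#' @return A data.frame with columns `index`, `mean`, `sd` (sd is 0 for a
#'   single gene), with attribute `n_genes` and, when `n_codons` is present,
#'   `total_codons`.
#' @examples
#' prof <- compositionProfile(Biostrings::DNAStringSet(
#'   c(a = "ATGGGATAA", b = "ATGAAATAA")))
#' pooledComposition(prof)
#' @export
pooledComposition <- function(profiles) {
  stopifnot(nrow(profiles) >= 1L)
  num <- profiles[vapply(profiles, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("length_nt", "n_codons"))]
  mu <- vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1))
  sdv <- vapply(num, function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s)) 0 else s
  }, numeric(1))
  out <- data.frame(index = names(num), mean = mu, sd = sdv,
                    row.names = NULL)
  attr(out, "n_genes") <- nrow(profiles)
  if ("n_codons" %in% names(profiles))
    attr(out, "total_codons") <- sum(profiles$n_codons)
  out
}
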