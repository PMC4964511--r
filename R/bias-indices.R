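#' Count codons per gene
#'
#' Counts in-frame codon occurrences for each sequence over the 64
#' unambiguous codons. Codons containing N or any other ambiguity code fall
#' into no bin and are therefore skipped (the skip-codon policy); a trailing
#' partial codon is likewise ignored.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param dropTerminalStop if TRUE, the final codon of each sequence is
#'   removed from its bin when it is a stop codon, so the matrix reflects the
#'   coding part only. Internal stop codons are always retained.
#' @param code a [GeneticCode-class] object.
#' @return Integer matrix, genes x 64 codons (columns in fixed alphabetical
#'   codon order), with `rownames` the sequence names.
#' @examples
#' m <- countCodons(Biostrings::DNAStringSet(c(g1 = "ATGAAAAAATAA")))
#' m[, c("ATG", "AAA", "TAA")]
#' @export
countCodons <- function(seqs, dropTerminalStop = FALSE,
                        code = standardGeneticCode()) {
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 3L, step = 3L)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  counts <- counts[, geneticCodeCodons(code), drop = FALSE]
  rownames(counts) <- names(seqs)
  storage.mode(counts) <- "integer"
  if (dropTerminalStop && length(seqs)) {
    chr <- as.character(seqs)
    n <- nchar(chr)
    full <- (n %/% 3L) * 3L
    ok <- full >= 3L
    last <- rep(NA_character_, length(chr))
    last[ok] <- substring(chr[ok], full[ok] - 2L, full[ok])
    isStop <- !is.na(last) & last %in% stopCodons(code)
    if (any(isStop)) {
      idx <- cbind(which(isStop), match(last[isStop], colnames(counts)))
      counts[idx] <- counts[idx] - 1L
    }
  }
  counts
}

#' @describeIn countCodons Pool a count matrix (or list of count vectors)
#'   into one named 64-codon count vector.
#' @param counts a genes x 64 matrix or a single named count vector.
#' @export
pooledCounts <- function(counts) {
  if (is.matrix(counts)) colSums(counts) else counts
}

.as_count_vector <- function(counts, code) {
  if (is.matrix(counts)) counts <- colSums(counts)
  full <- setNames(numeric(64L), geneticCodeCodons(code))
  full[names(counts)] <- counts
  full
}

#' @describeIn countCodons Numbers of sense and stop codons in a count
#'   vector or matrix, as a list `list(nSense, nStop)`.
#' @export
senseStopCounts <- function(counts, code = standardGeneticCode()) {
  v <- .as_count_vector(counts, code)
  stops <- stopCodons(code)
  list(nSense = sum(v[setdiff(names(v), stops)]), nStop = sum(v[stops]))
}

#' Relative synonymous codon usage
#'
#' For codon i of an amino acid with family size k and observed family total
#' X, RSCU_i = k * x_i / X: the observed count relative to the count expected
#' were all synonyms used equally. RSCU 1 means unbiased use; values sum to k
#' within every observed family. Families with zero observations yield NA
#' for their codons.
#'
#' @param counts named codon count vector (64 or fewer codons), or a genes x
#'   codons matrix (which is pooled first).
#' @param includeStops if TRUE the three stop codons are treated as one
#'   3-membered family and receive RSCU values; otherwise they are NA.
#' @param code a [GeneticCode-class] object.
#' @return Named numeric vector of RSCU values over all 64 codons
#'   (single-codon amino acids get 1 when observed, NA when absent).
#' @examples
#' rscu(c(AAA = 1, AAG = 3))[c("AAA", "AAG")]
#' @export
rscu <- function(counts, includeStops = FALSE, code = standardGeneticCode()) {
  v <- .as_count_vector(counts, code)
  out <- setNames(rep(NA_real_, 64L), names(v))
  fams <- geneticCodeFamilies(code)
  if (includeStops) fams <- c(fams, list(`*` = stopCodons(code)))
  for (f in fams) {
    tot <- sum(v[f])
    if (tot > 0) out[f] <- length(f) * v[f] / tot
  }
  out
}

#' Wright's corrected codon homozygosity for one synonymous family
#'
#' With n the family total and p-hat the observed codon proportions, the
#' estimator is F = (n * sum(p^2) - 1) / (n - 1). It is undefined for n <= 1.
#' An estimate of exactly 0 (possible at small n) cannot enter the
#' reciprocal averaging in [enc()] and is treated as undefined there.
#'
#' @param famCounts numeric vector of codon counts within one family.
#' @return The homozygosity estimate, or NA when n <= 1.
#' @examples
#' familyHomozygosity(c(2, 2))  # 1/3
#' familyHomozygosity(c(4, 0)) # 1
#' @export
familyHomozygosity <- function(famCounts) {
  n <- sum(famCounts)
  if (n <= 1) return(NA_real_)
  p <- famCounts / n
  (n * sum(p^2) - 1) / (n - 1)
}

# per-gene class-mean homozygosities; counts: genes x 64 matrix
.class_homozygosity <- function(counts, code) {
  fams <- geneticCodeFamilies(code)
  deg <- geneticCodeDegeneracy(code)
  multi <- names(fams)[deg >= 2L]
  classes <- c(2L, 3L, 4L, 6L)
  ng <- nrow(counts)
  fsum <- matrix(0, ng, length(classes), dimnames = list(NULL, classes))
  fn <- matrix(0L, ng, length(classes), dimnames = list(NULL, classes))
  for (a in multi) {
    sub <- counts[, fams[[a]], drop = FALSE]
    n <- rowSums(sub)
    sq <- rowSums((sub / pmax(n, 1))^2)
    f <- (n * sq - 1) / (n - 1)
    ok <- n >= 2 & !is.na(f) & f > 0
    cl <- as.character(deg[[a]])
    fsum[ok, cl] <- fsum[ok, cl] + f[ok]
    fn[ok, cl] <- fn[ok, cl] + 1L
  }
  fbar <- fsum / fn
  fbar[fn == 0L] <- NA_real_
  fbar
}

#' Effective number of codons (ENC)
#'
#' Wright's summary of how far a gene departs from uniform synonymous codon
#' usage: 20 when a single codon is used per amino acid, 61 when all
#' synonyms are used equally. Computed as
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the mean corrected
#' homozygosity ([familyHomozygosity()]) over the amino acids of degeneracy
#' k with a defined estimate. Met, Trp and stop codons never contribute.
#'
#' Missing-class conventions: an absent 3-fold class (no usable Ile counts)
#' is replaced by the harmonic-style combination `2 / (1/F2 + 1/F4)`; an
#' absent 6-fold class falls back to `F4`; if the 2-fold or 4-fold class
#' itself is empty the ENC is undefined (NA). The unbiased estimator can
#' slightly exceed 61 on finite samples; results are capped at 61.
#'
#' @param counts a named 64-codon count vector, or a genes x 64 matrix for
#'   vectorized per-gene computation.
#' @param code a [GeneticCode-class] object.
#' @return Numeric ENC in `[20, 61]`, or NA when undefined; one value per
#'   row when `counts` is a matrix.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(g = strrep("AAA", 50)))
#' enc(countCodons(seqs))
#' @export
enc <- function(counts, code = standardGeneticCode()) {
  if (!is.matrix(counts))
    counts <- matrix(.as_count_vector(counts, code), nrow = 1L,
                     dimnames = list(NULL, geneticCodeCodons(code)))
  fbar <- .class_homozygosity(counts, code)
  f2 <- fbar[, "2"]; f3 <- fbar[, "3"]; f4 <- fbar[, "4"]; f6 <- fbar[, "6"]
  f3 <- ifelse(is.na(f3), 2 / (1 / f2 + 1 / f4), f3)
  f6 <- ifelse(is.na(f6), f4, f6)
  out <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  out[is.na(f2) | is.na(f4)] <- NA_real_
  unname(pmin(out, 61))
}

#' Relative adaptiveness weights for CAI
#'
#' Within each synonymous family of the reference count table, each codon's
#' weight is its count divided by the count of the family's most frequent
#' codon, so the best codon has weight 1. Reference codons with zero counts
#' are floored at 0.01 so the geometric mean stays finite; families entirely
#' absent from the reference get uninformative weights of 1 (flagged by a
#' warning). Met, Trp and stop codons get weight 1 but are excluded from CAI
#' itself.
#'
#' @param reference named codon count vector or genes x 64 matrix, pooled
#'   over the reference gene set (classically: highly expressed genes; here,
#'   by default, the most ENC-ratio-biased genes, see [geneIndices()]).
#' @param floor weight assigned to zero-count reference codons.
#' @param code a [GeneticCode-class] object.
#' @return Named numeric vector of weights in `(0, 1]` over the 61 sense
#'   codons.
#' @examples
#' caiWeights(c(AAA = 75, AAG = 25))[c("AAA", "AAG")]
#' @export
caiWeights <- function(reference, floor = 0.01, code = standardGeneticCode()) {
  v <- .as_count_vector(reference, code)
  if (sum(v) == 0) stop("empty reference count table")
  fams <- geneticCodeFamilies(code)
  w <- setNames(rep(1, 61L),
                unlist(fams, use.names = FALSE))
  emptyFams <- character()
  for (a in names(fams)) {
    f <- fams[[a]]
    if (length(f) == 1L) { w[f] <- 1; next }
    mx <- max(v[f])
    if (mx == 0) { emptyFams <- c(emptyFams, a); w[f] <- 1; next }
    w[f] <- pmax(v[f] / mx, floor)
  }
  if (length(emptyFams))
    warning("families absent from CAI reference, weights set to 1: ",
            paste(emptyFams, collapse = ", "))
  w
}

#' Codon adaptation index
#'
#' The count-weighted geometric mean of relative adaptiveness weights over a
#' gene's codons, excluding Met, Trp and stop codons. CAI ranges in (0, 1]
#' and equals 1 exactly when the gene uses only family-maximal codons.
#'
#' @param counts named codon count vector or genes x 64 matrix (per-gene
#'   CAI for each row).
#' @param weights named weight vector from [caiWeights()].
#' @param code a [GeneticCode-class] object.
#' @return CAI value(s) in (0, 1]; NA for genes with no countable codons.
#' @examples
#' w <- caiWeights(c(AAA = 75, AAG = 25))
#' cai(c(AAA = 1, AAG = 1), w)  # sqrt(1/3)
#' @export
cai <- function(counts, weights, code = standardGeneticCode()) {
  single <- !is.matrix(counts)
  if (single)
    counts <- matrix(.as_count_vector(counts, code), nrow = 1L,
                     dimnames = list(NULL, geneticCodeCodons(code)))
  fams <- geneticCodeFamilies(code)
  deg <- geneticCodeDegeneracy(code)
  countable <- unlist(fams[deg >= 2L], use.names = FALSE)
  sub <- counts[, countable, drop = FALSE]
  lw <- log(weights[countable])
  tot <- rowSums(sub)
  out <- exp(as.vector(sub %*% lw) / tot)
  out[tot == 0] <- NA_real_
  if (single) out[[1L]] else out
}

# amino-acid counts from a codon count matrix, coding (non-stop) codons only
.aa_counts <- function(counts, code) {
  aa <- geneticCodeMap(code)
  sense <- names(aa)[aa != "*"]
  m <- counts[, sense, drop = FALSE]
  grp <- factor(aa[sense], levels = names(.KYTE_DOOLITTLE))
  t(rowsum(t(m), grp))
}

#' GRAVY: grand average of hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over the residues of the translated coding
#' region (terminal stop excluded; ambiguous codons and internal stops yield
#' no residue). Order-invariant: computed from codon counts.
#'
#' @param seqs a [Biostrings::DNAStringSet], or a precomputed genes x 64
#'   codon count matrix.
#' @param code a [GeneticCode-class] object.
#' @return Numeric vector, one GRAVY per gene; NA for zero residues.
#' @examples
#' gravy(Biostrings::DNAStringSet(c(polyIle = strrep("ATT", 20))))
#' @export
gravy <- function(seqs, code = standardGeneticCode()) {
  counts <- if (is.matrix(seqs)) seqs else
    countCodons(seqs, dropTerminalStop = TRUE, code = code)
  aam <- .aa_counts(counts, code)
  tot <- rowSums(aam)
  out <- as.vector(aam %*% .KYTE_DOOLITTLE[colnames(aam)]) / unname(tot)
  out[tot == 0] <- NA_real_
  unname(out)
}

#' Aromaticity
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) in the translated coding
#' region, terminal stop excluded.
#'
#' @inheritParams gravy
#' @return Numeric vector in `[0, 1]`, one value per gene; NA for zero
#'   residues.
#' @examples
#' aromo(Biostrings::DNAStringSet(c(g = "TTTTATTGGATTATTATTATTATTATT")))
#' @export
aromo <- function(seqs, code = standardGeneticCode()) {
  counts <- if (is.matrix(seqs)) seqs else
    countCodons(seqs, dropTerminalStop = TRUE, code = code)
  aam <- .aa_counts(counts, code)
  tot <- rowSums(aam)
  out <- rowSums(aam[, .AROMATIC, drop = FALSE]) / tot
  out[tot == 0] <- NA_real_
  unname(out)
}
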