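#' Specification for the synthetic CDS generator
#'
#' Collects the parameters of the generative model behind
#' [generateGenes()]. The defaults emulate a filtered fungal CDS set of the
#' kind the package targets: 4870 genes, lengths well above the 300-nt
#' filter with a mean around 500 codons, a wide per-gene GC3 spread
#' (targets uniform on 0.20-0.95), and a mixture of mutation-driven genes
#' (selection strength 0) and selection-driven genes (exponential strengths,
#' capped) so per-gene ENC spans roughly the upper 20s to 61.
#'
#' @param nGenes number of genes.
#' @param lengthMeanLog,lengthSdLog log-normal parameters for interior
#'   length in codons.
#' @param lengthMin,lengthMax clamp bounds on interior length (codons);
#'   the minimum keeps every gene above the 300-nt filter.
#' @param gc3Range range of the per-gene uniform GC3 target.
#' @param selectionZeroProb probability that a gene is purely
#'   mutation-driven (s = 0).
#' @param selectionRate rate of the exponential draw for selected genes.
#' @param selectionCap upper cap on s.
#' @param selectionStrength optional fixed selection strength: a scalar or a
#'   length-`nGenes` vector of s values (s >= 0) that replaces the random
#'   mixture draw entirely; used for planted-selection experiments.
#' @param preferredCodons named character vector mapping each multi-codon
#'   amino acid (one-letter) to its planted preferred codon; default
#'   [defaultPreferredCodons()].
#' @param aaFreqs amino-acid sampling frequencies (named over the 20
#'   one-letter codes); default uniform.
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `"syntheticSpec"`.
#' @examples
#' syntheticSpec(nGenes = 10, seed = 1)$nGenes
#' @export
syntheticSpec <- function(nGenes = 4870,
                          lengthMeanLog = log(400), lengthSdLog = 0.6,
                          lengthMin = 101L, lengthMax = 3000L,
                          gc3Range = c(0.20, 0.95),
                          selectionZeroProb = 0.5,
                          selectionRate = 1, selectionCap = 3,
                          selectionStrength = NULL,
                          preferredCodons = defaultPreferredCodons(),
                          aaFreqs = NULL,
                          seed = 1L) {
  stopifnot(nGenes >= 1, lengthMin >= 99L, lengthMin <= lengthMax,
            gc3Range[1] >= 0, gc3Range[2] <= 1, gc3Range[1] < gc3Range[2],
            selectionZeroProb >= 0, selectionZeroProb <= 1)
  if (!is.null(selectionStrength)) {
    stopifnot(all(selectionStrength >= 0),
              length(selectionStrength) %in% c(1L, nGenes))
    selectionStrength <- rep_len(selectionStrength, nGenes)
  }
  code <- standardGeneticCode()
  deg <- geneticCodeDegeneracy(code)
  fams <- geneticCodeFamilies(code)
  multi <- names(deg)[deg >= 2L]
  if (!all(multi %in% names(preferredCodons)))
    stop("preferredCodons must cover every multi-codon amino acid")
  bad <- vapply(multi, function(a)
    !(preferredCodons[[a]] %in% fams[[a]]), logical(1))
  if (any(bad))
    stop("preferred codon is not a synonym of its amino acid: ",
         paste(multi[bad], collapse = ", "))
  if (is.null(aaFreqs)) {
    aaFreqs <- setNames(rep(1 / 20, 20L), names(.KYTE_DOOLITTLE))
  } else {
    stopifnot(setequal(names(aaFreqs), names(.KYTE_DOOLITTLE)),
              all(aaFreqs >= 0), sum(aaFreqs) > 0)
    aaFreqs <- aaFreqs[names(.KYTE_DOOLITTLE)] / sum(aaFreqs)
  }
  structure(list(nGenes = as.integer(nGenes),
                 lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
                 lengthMin = as.integer(lengthMin),
                 lengthMax = as.integer(lengthMax),
                 gc3Range = gc3Range,
                 selectionZeroProb = selectionZeroProb,
                 selectionRate = selectionRate,
                 selectionCap = selectionCap,
                 selectionStrength = selectionStrength,
                 preferredCodons = preferredCodons,
                 aaFreqs = aaFreqs,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Default planted preferred-codon set
#'
#' For each multi-codon amino acid, the C-ending codon (or the G-ending one
#' for the purine-only 2-fold families Lys, Gln, Glu), mirroring the
#' C/G-ending optima typical of GC-rich fungal genomes.
#'
#' @return Named character vector, one codon per multi-codon amino acid.
#' @examples
#' defaultPreferredCodons()[c("K", "F")]
#' @export
defaultPreferredCodons <- function() {
  fams <- geneticCodeFamilies(standardGeneticCode())
  deg <- geneticCodeDegeneracy(standardGeneticCode())
  multi <- fams[deg[names(fams)] >= 2L]
  vapply(multi, function(f) {
    third <- substring(f, 3L, 3L)
    if (any(third == "C")) f[third == "C"][1L] else f[third == "G"][1L]
  }, character(1))
}

# per-gene codon sampling distribution over the 61 sense codons:
# P(codon) = aaFreq(aa) * famProb(codon | gc3 kernel, selection tilt)
.codon_distribution <- function(gc3Target, s, preferred, aaFreqs, code) {
  fams <- geneticCodeFamilies(code)
  codons <- unlist(fams, use.names = FALSE)
  third <- substring(codons, 3L, 3L)
  kern <- ifelse(third %in% c("G", "C"), gc3Target / 2, (1 - gc3Target) / 2)
  names(kern) <- codons
  p <- numeric(length(codons))
  names(p) <- codons
  for (a in names(fams)) {
    f <- fams[[a]]
    w <- kern[f]
    if (length(f) >= 2L && s > 0) {
      pc <- preferred[[a]]
      w[pc] <- w[pc] * exp(s)
    }
    p[f] <- aaFreqs[[a]] * w / sum(w)
  }
  p
}

#' Generate synthetic coding sequences
#'
#' Generative model: per gene, an interior length is drawn (log-normal,
#' clamped), amino acids are drawn i.i.d. from the spec's frequencies, and
#' each amino acid's codon is drawn from its synonymous family with
#' probability proportional to a third-position mutation kernel
#' (P(G) = P(C) = gc3_target/2, P(A) = P(T) = (1 - gc3_target)/2,
#' renormalized within the family), exponentially tilted toward the gene's
#' planted preferred codon by the factor `exp(s)`. `s = 0` recovers pure
#' mutational choice. Every gene gets an ATG start and a kernel-weighted
#' stop codon, and passes [filterCds()] by construction. Output is fully
#' deterministic given the spec's seed.
#'
#' @param spec a [syntheticSpec()].
#' @return A list with `sequences` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame of per-gene `gene_id`, `gc3_target`, `s`,
#'   `length_codons`), with the planted preferred codons attached as
#'   attribute `"preferred_codons"` of `truth`.
#' @examples
#' sim <- generateGenes(syntheticSpec(nGenes = 5, seed = 7))
#' sim$truth
#' @export
generateGenes <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  code <- standardGeneticCode()
  set.seed(spec$seed)
  n <- spec$nGenes
  len <- round(exp(rnorm(n, spec$lengthMeanLog, spec$lengthSdLog)))
  len <- pmin(pmax(len, spec$lengthMin), spec$lengthMax)
  gc3 <- runif(n, spec$gc3Range[1], spec$gc3Range[2])
  s <- if (!is.null(spec$selectionStrength)) spec$selectionStrength else
    ifelse(runif(n) < spec$selectionZeroProb, 0,
           pmin(rexp(n, spec$selectionRate), spec$selectionCap))
  stops <- stopCodons(code)
  stopThird <- substring(stops, 3L, 3L)
  seqs <- character(n)
  for (i in seq_len(n)) {
    p <- .codon_distribution(gc3[i], s[i], spec$preferredCodons,
                             spec$aaFreqs, code)
    body <- sample(names(p), len[i], replace = TRUE, prob = p)
    wStop <- ifelse(stopThird %in% c("G", "C"), gc3[i] / 2, (1 - gc3[i]) / 2)
    stop_i <- sample(stops, 1L, prob = wStop)
    seqs[i] <- paste0("ATG", paste(body, collapse = ""), stop_i)
  }
  ids <- sprintf("synth_%05d", seq_len(n))
  out <- Biostrings::DNAStringSet(setNames(seqs, ids))
  truth <- data.frame(gene_id = ids, gc3_target = gc3, s = s,
                      length_codons = len + 2L)
  attr(truth, "preferred_codons") <- spec$preferredCodons
  list(sequences = out, truth = truth)
}

#' Generate genes with a planted GC12-on-GC3 linear relation
#'
#' Builds position-controllable genes from the codon pool
#' {GGG, GGA, AAG, AAA} (Gly and Lys), in which the first two positions are
#' either both G+C or both A+T and the third position is G or A
#' independently. Each gene's realized GC3 is set by a rounded count of
#' G-ending codons and its GC12 follows `intercept + slope * gc3` plus
#' Gaussian noise, so [neutralityFit()] can be validated against known
#' parameters. All genes share the same interior length; with noise 0 and
#' slope 1 the fitted slope is exactly 1.
#'
#' @param n number of genes.
#' @param slope,intercept,noiseSd the planted linear relation between GC12
#'   and GC3 (fractions) and the Gaussian noise on GC12.
#' @param gc3Range range of per-gene GC3 targets.
#' @param lengthCodons interior length in codons (constant across genes).
#' @param seed integer seed.
#' @return A named [Biostrings::DNAStringSet]; the per-gene targets are in
#'   attribute `"truth"`.
#' @examples
#' seqs <- generateNeutralitySet(10, slope = 1, intercept = 0, noiseSd = 0,
#'                               seed = 1)
#' @export
generateNeutralitySet <- function(n, slope, intercept, noiseSd = 0,
                                  gc3Range = c(0.05, 0.95),
                                  lengthCodons = 200L, seed = 1L) {
  stopifnot(n >= 3L, lengthCodons >= 99L)
  implied <- intercept + slope * gc3Range
  if (any(implied < 0.02 | implied > 0.98))
    stop("infeasible relation: implied GC12 outside [0.02, 0.98] over the GC3 range")
  set.seed(seed)
  L <- as.integer(lengthCodons)
  gc3t <- runif(n, gc3Range[1], gc3Range[2])
  nG3 <- round(gc3t * L)
  gc12t <- intercept + slope * (nG3 / L) + rnorm(n, 0, noiseSd)
  nGG <- round(pmin(pmax(gc12t, 0), 1) * L)
  seqs <- vapply(seq_len(n), function(i) {
    prefix <- c(rep("GG", nGG[i]), rep("AA", L - nGG[i]))
    third <- c(rep("G", nG3[i]), rep("A", L - nG3[i]))
    paste0("ATG", paste0(prefix, third, collapse = ""), "TAA")
  }, character(1))
  out <- Biostrings::DNAStringSet(setNames(seqs, sprintf("neu_%05d", seq_len(n))))
  attr(out, "truth") <- data.frame(gene_id = names(out), gc3_target = gc3t,
                                   gc12_target = gc12t)
  out
}
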