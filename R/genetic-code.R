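#' @import methods
#' @importFrom stats lm cor.test coef rnorm rexp runif sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' The standard genetic code and its synonymous-family structure
#'
#' A container for the standard (translation table 1) genetic code as used
#' throughout the package: the codon-to-amino-acid map, the synonymous
#' families, and the degeneracy class of every amino acid. Codons are DNA
#' 3-mers (T, not U). Under the standard code there are 61 sense codons and
#' 3 stop codons (TAA, TAG, TGA); nine amino acids are 2-fold degenerate,
#' Ile is the single 3-fold case, five are 4-fold and three (Leu, Ser, Arg)
#' are 6-fold.
#'
#' @slot codonToAa named character; one-letter amino acid per codon, `"*"`
#'   for stops.
#' @slot families named list; for each multi-codon-capable amino acid
#'   (one-letter name), the character vector of its codons.
#' @slot degeneracy named integer; synonymous-family size per amino acid.
#' @slot stops character; the three stop codons.
#' @slot singletons character; codons of the single-codon amino acids
#'   (ATG for Met, TGG for Trp).
#'
#' @export
setClass("GeneticCode",
         representation(codonToAa = "character",
                        families = "list",
                        degeneracy = "integer",
                        stops = "character",
                        singletons = "character"))

setValidity("GeneticCode", function(object) {
  msg <- character()
  aa <- object@codonToAa
  if (length(aa) != 64L)
    msg <- c(msg, "codonToAa must map exactly 64 codons")
  if (sum(aa == "*") != 3L)
    msg <- c(msg, "there must be exactly 3 stop codons")
  if (sum(aa != "*") != 61L)
    msg <- c(msg, "there must be exactly 61 sense codons")
  if (sum(object@degeneracy) != 61L)
    msg <- c(msg, "family sizes must sum to 61")
  cls <- table(object@degeneracy)
  expect <- c(`1` = 2L, `2` = 9L, `3` = 1L, `4` = 5L, `6` = 3L)
  if (!identical(as.integer(cls[names(expect)]), unname(expect)))
    msg <- c(msg, "degeneracy classes must be 2x1-fold, 9x2-fold, 1x3-fold, 5x4-fold, 3x6-fold")
  if (length(msg)) msg else TRUE
})

.pkg_cache <- new.env(parent = emptyenv())

#' @describeIn GeneticCode-class Construct (and cache) the standard genetic
#'   code object from the Biostrings `GENETIC_CODE` table.
#' @return A [GeneticCode-class] object.
#' @examples
#' gc <- standardGeneticCode()
#' geneticCodeDegeneracy(gc)[c("I", "L", "K")]
#' @export
standardGeneticCode <- function() {
  if (!is.null(.pkg_cache$gencode))
    return(.pkg_cache$gencode)
  tab <- Biostrings::GENETIC_CODE
  codons <- names(tab)
  aa <- as.character(tab)
  names(aa) <- codons
  sense <- codons[aa != "*"]
  fam <- split(sense, aa[sense])
  deg <- vapply(fam, length, integer(1))
  obj <- new("GeneticCode",
             codonToAa = aa,
             families = fam,
             degeneracy = deg,
             stops = codons[aa == "*"],
             singletons = sense[deg[aa[sense]] == 1L])
  .pkg_cache$gencode <- obj
  obj
}

#' @describeIn GeneticCode-class All 64 codons, in the fixed column order
#'   used by codon count matrices.
#' @param code a [GeneticCode-class] object.
#' @export
geneticCodeCodons <- function(code = standardGeneticCode()) names(code@codonToAa)

#' @describeIn GeneticCode-class Named character vector mapping codons to
#'   one-letter amino acids (`"*"` = stop).
#' @export
geneticCodeMap <- function(code = standardGeneticCode()) code@codonToAa

#' @describeIn GeneticCode-class Synonymous families as a named list of
#'   codon vectors (sense codons only).
#' @export
geneticCodeFamilies <- function(code = standardGeneticCode()) code@families

#' @describeIn GeneticCode-class Family size (degeneracy) per amino acid.
#' @export
geneticCodeDegeneracy <- function(code = standardGeneticCode()) code@degeneracy

#' @describeIn GeneticCode-class The three stop codons.
#' @export
stopCodons <- function(code = standardGeneticCode()) code@stops

setMethod("show", "GeneticCode", function(object) {
  cat("Standard genetic code: 61 sense codons, 3 stops (",
      paste(object@stops, collapse = ", "), ")\n", sep = "")
  cat("Degeneracy classes:",
      paste(names(table(object@degeneracy)), table(object@degeneracy),
            sep = "-fold x ", collapse = ", "), "\n")
})

# Kyte-Doolittle hydropathy scale, one value per amino acid
.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

.AROMATIC <- c("F", "Y", "W")

#' Kyte-Doolittle hydropathy values
#'
#' The per-residue hydropathy scale used for GRAVY: positive values are
#' hydrophobic (Ile 4.5), negative hydrophilic (Arg -4.5).
#'
#' @return Named numeric vector over the 20 amino acids (one-letter names).
#' @examples
#' kyteDoolittle()[c("I", "R")]
#' @export
kyteDoolittle <- function() .KYTE_DOOLITTLE

# three-letter display names for output tables
.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
          `*` = "Ter")

aaThreeLetter <- function(aa) unname(.AA3[aa])
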