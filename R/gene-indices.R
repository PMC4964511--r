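#' Per-gene codon-usage index table
#'
#' One row per gene with every index the analysis uses: the composition
#' profile ([compositionProfile()]), GRAVY, aromaticity, observed ENC,
#' expected ENC from GC3s, the ENC ratio, and CAI.
#'
#' CAI needs a reference set of putatively highly expressed genes. By
#' default the package derives it internally: genes are ranked by ENC ratio
#' and the pooled codon counts of the top `caiReferenceFraction` (default
#' 5%) most biased genes define the relative-adaptiveness weights
#' ([caiWeights()]). A user-supplied weight vector (e.g. weights from a
#' model organism) can be passed instead via `caiReference`.
#'
#' @param seqs a [Biostrings::DNAStringSet] of filtered CDS.
#' @param caiReference optional named weight vector over the sense codons
#'   (as from [caiWeights()]); overrides the internal reference.
#' @param caiReferenceFraction tail fraction of most biased genes used to
#'   build the internal CAI reference.
#' @param code a [GeneticCode-class] object.
#' @return A data.frame, one row per gene: composition columns plus `gravy`,
#'   `aromo`, `enc`, `enc_exp`, `enc_ratio`, `cai`.
#' @examples
#' sim <- generateGenes(syntheticSpec(nGenes = 50, seed = 1))
#' head(geneIndices(sim$sequences))
#' @export
geneIndices <- function(seqs, caiReference = NULL,
                        caiReferenceFraction = 0.05,
                        code = standardGeneticCode()) {
  counts <- countCodons(seqs, dropTerminalStop = TRUE, code = code)
  prof <- compositionProfile(counts, code = code)
  prof$length_nt <- nchar(as.character(seqs))
  prof$gravy <- gravy(counts, code = code)
  prof$aromo <- aromo(counts, code = code)
  prof$enc <- enc(counts, code = code)
  prof$enc_exp <- encExpected(prof$gc3s)
  prof$enc_ratio <- encRatio(prof$enc, prof$gc3s)
  if (is.null(caiReference)) {
    subs <- selectBiasSubsets(prof$gene_id, prof$enc_ratio,
                              fraction = caiReferenceFraction)
    ref <- pooledCounts(counts[match(subs$highIds, prof$gene_id), ,
                               drop = FALSE])
    caiReference <- caiWeights(ref, code = code)
  }
  prof$cai <- cai(counts, caiReference, code = code)
  attr(prof, "cai_weights") <- caiReference
  prof
}
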