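#' Run the full codon-usage analysis pipeline
#'
#' End-to-end orchestration over a CDS FASTA (or an in-memory sequence set):
#' quality filtering, the per-gene index table, the pooled RSCU table, the
#' ENC-plot and neutrality outputs, correspondence analysis of per-gene
#' RSCU with the index/axis correlation report, and the optimal-codon
#' table. Each stage is written as a TSV with a single header row into
#' `outDir`, and a manifest records the package version, the configuration,
#' and an MD5 checksum per artifact. Outputs are a pure function of the
#' input sequences and the configuration, so reruns are byte-identical.
#'
#' @param input path to a CDS FASTA file, or a [Biostrings::DNAStringSet].
#' @param outDir output directory (created if needed).
#' @param minLenNt strict minimum CDS length in nt (filter stage).
#' @param fraction tail fraction for the high/low bias subsets.
#' @param threshold delta-RSCU cutoff for optimal codons.
#' @param corMethod correlation method for the report.
#' @param nAxes number of correspondence-analysis axes retained.
#' @param caiReference optional CAI weight vector (see [geneIndices()]).
#' @return Invisibly, a named list of the artifact paths (and the in-memory
#'   stage results in attribute `"results"`).
#' @examples
#' sim <- generateGenes(syntheticSpec(nGenes = 60, seed = 3))
#' out <- runPipeline(sim$sequences, tempfile("cub"))
#' names(out)
#' @export
runPipeline <- function(input, outDir, minLenNt = 300, fraction = 0.05,
                        threshold = 0.08,
                        corMethod = c("spearman", "pearson"), nAxes = 4L,
                        caiReference = NULL) {
  corMethod <- match.arg(corMethod)
  stopifnot(fraction > 0, fraction < 0.5, threshold > 0)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seqs <- if (is.character(input)) readCds(input) else input
  tsv <- function(df, file) {
    path <- file.path(outDir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- list()

  flt <- filterCds(seqs, minLenNt = minLenNt)
  paths$filter_report <- tsv(filterReportTable(flt$report),
                             "filter_report.tsv")
  seqs <- flt$sequences
  if (length(seqs) < 3L)
    stop("pipeline stage 'filter': fewer than 3 sequences retained")

  idx <- geneIndices(seqs, caiReference = caiReference,
                     caiReferenceFraction = fraction)
  paths$gene_indices <- tsv(idx, "gene_indices.tsv")

  counts <- countCodons(seqs, dropTerminalStop = TRUE)
  pooled <- pooledCounts(countCodons(seqs))
  rs <- rscu(pooled, includeStops = TRUE)
  aa <- geneticCodeMap()
  pooledTab <- data.frame(amino_acid = aaThreeLetter(aa[names(pooled)]),
                          codon = names(pooled),
                          count = unname(pooled),
                          rscu = round(unname(rs), 4))
  pooledTab <- pooledTab[order(pooledTab$amino_acid, pooledTab$codon), ]
  paths$rscu_pooled <- tsv(pooledTab, "rscu_pooled.tsv")

  neuTab <- data.frame(gene_id = idx$gene_id, gc3 = idx$gc3,
                       gc12 = idx$gc12, gc3s = idx$gc3s,
                       enc_obs = idx$enc, enc_exp = idx$enc_exp,
                       enc_ratio = idx$enc_ratio)
  paths$neutrality <- tsv(neuTab, "neutrality.tsv")
  fit <- neutralityFit(idx$gc3, idx$gc12)
  paths$neutrality_fit <- tsv(neutralityFitTable(fit), "neutrality_fit.tsv")
  paths$enc_ratio_hist <- tsv(encRatioHistogram(idx$enc_ratio),
                              "enc_ratio_hist.tsv")

  rsm <- buildRscuMatrix(counts)
  coa <- correspondenceAnalysis(rsm, nAxes = nAxes)
  paths$coa_genes <- tsv(data.frame(gene_id = idx$gene_id,
                                    rowCoords(coa),
                                    check.names = FALSE), "coa_genes.tsv")
  paths$coa_codons <- tsv(data.frame(codon = rownames(colCoords(coa)),
                                     colCoords(coa), check.names = FALSE),
                          "coa_codons.tsv")
  paths$coa_inertia <- tsv(data.frame(axis = names(inertiaShare(coa)),
                                      inertia_share = inertiaShare(coa),
                                      total_inertia = totalInertia(coa)),
                           "coa_inertia.tsv")

  corIdx <- idx[, c("length_nt", "gc", "gc1", "gc2", "gc3", "gc3s",
                    "a3s", "t3s", "c3s", "g3s", "gravy", "aromo",
                    "enc", "cai")]
  rep <- tryCatch(correlationReport(corIdx, coa, method = corMethod),
                  error = function(e) NULL)
  if (!is.null(rep)) {
    est <- data.frame(variable = rownames(rep$estimate), rep$estimate,
                      check.names = FALSE)
    pvl <- data.frame(variable = rownames(rep$p.value), rep$p.value,
                      check.names = FALSE)
    paths$correlations <- tsv(est, "correlations.tsv")
    paths$correlation_pvalues <- tsv(pvl, "correlation_pvalues.tsv")
  }

  subs <- selectBiasSubsets(idx$gene_id, idx$enc_ratio, fraction = fraction)
  hi <- pooledCounts(counts[match(subs$highIds, idx$gene_id), , drop = FALSE])
  lo <- pooledCounts(counts[match(subs$lowIds, idx$gene_id), , drop = FALSE])
  opt <- optimalCodons(hi, lo, threshold = threshold)
  paths$optimal_codons <- tsv(optimalCodonTable(opt), "optimal_codons.tsv")

  files <- unlist(paths)
  manifest <- data.frame(
    artifact = names(paths),
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    package_version = as.character(packageVersion("codonBias")),
    min_len_nt = minLenNt, fraction = fraction, threshold = threshold,
    cor_method = corMethod, n_axes = nAxes)
  paths$manifest <- tsv(manifest, "manifest.tsv")

  results <- list(filter = flt$report, indices = idx, pooled_rscu = rs,
                  neutrality = fit, coa = coa, correlations = rep,
                  subsets = subs, optimal = opt)
  structure(invisible(paths), results = results)
}
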