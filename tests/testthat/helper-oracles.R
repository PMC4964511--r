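# Independent oracles and small fixture builders. The oracles re-derive the
# statistics from first principles using only base R and the Biostrings
# GENETIC_CODE table, so they share no code path with the package.

# Wright's ENC computed by direct enumeration over amino acids.
oracleEnc <- function(counts) {
  gc <- Biostrings::GENETIC_CODE
  aas <- setdiff(unique(gc), "*")
  fhat <- sapply(aas, function(a) {
    cods <- names(gc)[gc == a]
    if (length(cods) < 2) return(NA_real_)
    x <- counts[cods]
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n < 2) return(NA_real_)
    f <- (n * sum((x / n)^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  })
  k <- sapply(aas, function(a) sum(gc == a))
  classMean <- function(d) {
    v <- fhat[k == d & !is.na(fhat)]
    if (length(v)) mean(v) else NA_real_
  }
  f2 <- classMean(2); f3 <- classMean(3); f4 <- classMean(4); f6 <- classMean(6)
  if (is.na(f2) || is.na(f4)) return(NA_real_)
  if (is.na(f3)) f3 <- 2 / (1 / f2 + 1 / f4)
  if (is.na(f6)) f6 <- f4
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# Classical CA by explicit eigen-decomposition of the standardized residuals.
oracleCa <- function(x) {
  tot <- sum(x)
  P <- x / tot
  r <- rowSums(P); c_ <- colSums(P)
  S <- (P - outer(r, c_)) / sqrt(outer(r, c_))
  ev <- eigen(S %*% t(S), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  keep <- lam > 1e-12
  rowPC <- sweep(ev$vectors[, keep, drop = FALSE], 1, sqrt(r), "/") %*%
    diag(sqrt(lam[keep]), sum(keep))
  list(totalInertia = sum(lam[keep]), rowCoords = rowPC,
       inertia = lam[keep])
}

# chi-square statistic of a contingency-style matrix, by hand
chisqStat <- function(x) {
  tot <- sum(x)
  E <- outer(rowSums(x), colSums(x)) / tot
  sum((x - E)^2 / E)
}

# random codon count vector across the 64 codons
randomCountVector <- function(maxCount = 30) {
  codons <- geneticCodeCodons()
  setNames(sample(0:maxCount, 64, replace = TRUE), codons)
}

# random short CDS-like codon count table for a plausible "small gene":
# a handful of amino acids, small counts
randomGeneCounts <- function() {
  codons <- geneticCodeCodons()
  v <- setNames(integer(64), codons)
  picked <- sample(codons, sample(5:25, 1))
  v[picked] <- sample(0:8, length(picked), replace = TRUE)
  v
}

# a syntactically valid CDS string from interior codons
asCds <- function(...) paste0("ATG", paste0(..., collapse = ""), "TAA")

dss <- function(x) Biostrings::DNAStringSet(x)
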