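#' Per-gene RSCU matrix over the 59 synonymous codons
#'
#' Builds the genes x codons RSCU matrix used for correspondence analysis,
#' over the 59 sense codons of multi-codon families (stop codons, Met and
#' Trp excluded). Families absent from a gene would leave its codons
#' undefined; such entries are imputed with the family-neutral value 1 (one
#' expected count per synonym), which keeps row sums stable and avoids
#' dropping short genes. The number of imputed families per gene is recorded
#' in the `"imputed_families"` attribute.
#'
#' @param counts genes x 64 codon count matrix from [countCodons()].
#' @param code a [GeneticCode-class] object.
#' @return Numeric matrix, genes x 59, with codon column names.
#' @examples
#' m <- countCodons(Biostrings::DNAStringSet(c(a = "AAAAAGAAG", b = "AAAAAA")))
#' buildRscuMatrix(m)[, c("AAA", "AAG")]
#' @export
buildRscuMatrix <- function(counts, code = standardGeneticCode()) {
  stopifnot(is.matrix(counts), nrow(counts) >= 2L)
  fams <- geneticCodeFamilies(code)
  deg <- geneticCodeDegeneracy(code)
  multi <- fams[deg[names(fams)] >= 2L]
  synCodons <- unlist(multi, use.names = FALSE)
  out <- matrix(NA_real_, nrow(counts), length(synCodons),
                dimnames = list(rownames(counts), synCodons))
  imputed <- integer(nrow(counts))
  for (f in multi) {
    sub <- counts[, f, drop = FALSE]
    tot <- rowSums(sub)
    r <- length(f) * sub / tot
    absent <- tot == 0
    r[absent, ] <- 1
    imputed <- imputed + absent
    out[, f] <- r
  }
  attr(out, "imputed_families") <- imputed
  out
}

#' Correspondence analysis result
#'
#' Principal row (gene) and column (codon) coordinates from a classical
#' correspondence analysis, with the share of total inertia carried by each
#' retained axis. Axes are ordered by decreasing inertia; the sign of each
#' axis is fixed by making the codon with the largest absolute loading
#' positive, so results are deterministic.
#'
#' @slot rowCoords genes x axes matrix of principal coordinates.
#' @slot colCoords codons x axes matrix of principal coordinates.
#' @slot inertiaShare fraction of total inertia per retained axis.
#' @slot totalInertia total inertia (chi-square statistic / grand total).
#' @slot rank numeric rank of the centred standardized matrix.
#' @slot rowMasses row masses (weights) used in the decomposition.
#' @export
setClass("CoaResult",
         representation(rowCoords = "matrix", colCoords = "matrix",
                        inertiaShare = "numeric", totalInertia = "numeric",
                        rank = "integer", rowMasses = "numeric"))

setValidity("CoaResult", function(object) {
  msg <- character()
  is_ <- object@inertiaShare
  if (length(is_) && (any(is_ < -1e-12 | is_ > 1 + 1e-12) ||
                      is.unsorted(rev(is_), strictly = FALSE)))
    msg <- c(msg, "inertia shares must be non-increasing fractions")
  if (length(is_) && sum(is_) > 1 + 1e-9)
    msg <- c(msg, "inertia shares must sum to at most 1")
  if (ncol(object@rowCoords) > 0) {
    ctr <- abs(colSums(object@rowMasses * object@rowCoords))
    if (any(ctr > 1e-9))
      msg <- c(msg, "row coordinates must have zero weighted mean per axis")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoaResult", function(object) {
  cat(sprintf("Correspondence analysis: %d genes x %d codons, rank %d\n",
              nrow(object@rowCoords), nrow(object@colCoords), object@rank))
  cat(sprintf("  total inertia %.6f\n", object@totalInertia))
  if (length(object@inertiaShare))
    cat("  axis inertia shares:",
        paste(sprintf("%.3f", object@inertiaShare), collapse = " "), "\n")
})

#' @describeIn CoaResult-class gene principal coordinates.
#' @param object a `CoaResult`.
#' @export
rowCoords <- function(object) object@rowCoords

#' @describeIn CoaResult-class codon principal coordinates.
#' @export
colCoords <- function(object) object@colCoords

#' @describeIn CoaResult-class per-axis inertia fractions.
#' @export
inertiaShare <- function(object) object@inertiaShare

#' @describeIn CoaResult-class total inertia.
#' @export
totalInertia <- function(object) object@totalInertia

#' Correspondence analysis of an RSCU matrix
#'
#' Classical (chi-square metric) correspondence analysis: the matrix is
#' scaled to relative frequencies, row and column masses are taken from its
#' margins, the standardized residual matrix is decomposed by singular
#' values, and principal coordinates are returned for the leading axes.
#' Rank is at most `min(rows, columns) - 1`; a matrix whose rows are all
#' proportional has rank 0, total inertia 0 and no axes.
#'
#' @param x non-negative matrix (typically from [buildRscuMatrix()]).
#' @param nAxes number of axes to retain (default 4); truncated to the rank.
#' @return A [CoaResult-class] object.
#' @examples
#' coa <- correspondenceAnalysis(rbind(a = c(3, 1), b = c(1, 3)))
#' inertiaShare(coa)
#' @export
correspondenceAnalysis <- function(x, nAxes = 4L) {
  stopifnot(is.matrix(x), all(x >= 0), nrow(x) >= 2L)
  tot <- sum(x)
  if (tot <= 0) stop("matrix has zero grand total")
  P <- x / tot
  r <- rowSums(P)
  c_ <- colSums(P)
  keepCol <- c_ > 0
  S <- (P[, keepCol, drop = FALSE] - r %o% c_[keepCol]) /
    sqrt(r %o% c_[keepCol])
  sv <- svd(S)
  tolD <- max(dim(S)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > max(tolD, 1e-12))
  rank <- min(rank, min(nrow(x), sum(keepCol)) - 1L)
  totalInertia <- sum(sv$d[seq_len(rank)]^2)
  nAxes <- min(nAxes, rank)
  axNames <- if (nAxes > 0) paste0("Axis", seq_len(nAxes)) else character()
  if (nAxes == 0L) {
    rowC <- matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL))
    colC <- matrix(0, ncol(x), 0, dimnames = list(colnames(x), NULL))
    share <- numeric()
  } else {
    d <- sv$d[seq_len(nAxes)]
    rowC <- sweep(sv$u[, seq_len(nAxes), drop = FALSE], 1, sqrt(r), "/") %*%
      diag(d, nAxes)
    colFull <- matrix(0, ncol(x), nAxes)
    colFull[keepCol, ] <- sweep(sv$v[, seq_len(nAxes), drop = FALSE], 1,
                                sqrt(c_[keepCol]), "/") %*% diag(d, nAxes)
    # sign convention: the codon with the largest |loading| points positive
    for (k in seq_len(nAxes)) {
      j <- which.max(abs(colFull[, k]))
      if (colFull[j, k] < 0) {
        colFull[, k] <- -colFull[, k]
        rowC[, k] <- -rowC[, k]
      }
    }
    dimnames(rowC) <- list(rownames(x), axNames)
    dimnames(colFull) <- list(colnames(x), axNames)
    colC <- colFull
    share <- d^2 / totalInertia
    names(share) <- axNames
  }
  new("CoaResult", rowCoords = rowC, colCoords = colC,
      inertiaShare = share, totalInertia = totalInertia,
      rank = as.integer(rank), rowMasses = r)
}

#' Pairwise correlation report between indices and ordination axes
#'
#' Pairwise correlations (Spearman rank by default, the robust choice for
#' codon-usage index tables; Pearson by flag) with two-sided p-values,
#' between gene-level indices (length, composition, GRAVY, aromaticity, ENC,
#' CAI, ...) and, optionally, correspondence-analysis axis coordinates.
#' Pairs are computed on pairwise-complete observations; constant columns
#' yield NA coefficients and a warning.
#'
#' @param profiles data.frame of per-gene indices ([geneIndices()] output or
#'   similar); non-numeric columns are ignored.
#' @param coa optional [CoaResult-class]; its row coordinates are appended
#'   as Axis1..AxisK columns (genes matched by position).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list of class `"correlationReport"` with elements `estimate`
#'   and `p.value` (symmetric matrices with unit/zero diagonals), `method`,
#'   and `n` (pairwise sample sizes).
#' @examples
#' df <- data.frame(x = 1:10, y = (1:10)^2)
#' correlationReport(df)$estimate
#' @export
correlationReport <- function(profiles, coa = NULL,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  num <- profiles[vapply(profiles, is.numeric, logical(1))]
  if (!is.null(coa)) {
    ax <- rowCoords(coa)
    stopifnot(nrow(ax) == nrow(num))
    num <- cbind(num, as.data.frame(ax))
  }
  m <- as.matrix(num)
  if (nrow(m) < 3L) stop("need at least 3 genes for correlations")
  p <- ncol(m)
  est <- pv <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  nm <- matrix(0L, p, p, dimnames = dimnames(est))
  constCols <- character()
  for (i in seq_len(p)) {
    est[i, i] <- 1; pv[i, i] <- 0; nm[i, i] <- sum(!is.na(m[, i]))
    for (j in seq_len(p)[-seq_len(i)]) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      nm[i, j] <- nm[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      if (sd(m[ok, i]) == 0 || sd(m[ok, j]) == 0) {
        constCols <- union(constCols,
                           colnames(m)[c(i, j)[c(sd(m[ok, i]) == 0,
                                                 sd(m[ok, j]) == 0)]])
        next
      }
      ct <- suppressWarnings(
        cor.test(m[ok, i], m[ok, j], method = method, exact = FALSE))
      est[i, j] <- est[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  if (length(constCols))
    warning("constant columns, correlations undefined: ",
            paste(constCols, collapse = ", "))
  structure(list(estimate = est, p.value = pv, method = method, n = nm),
            class = "correlationReport")
}

#' @describeIn correlationReport Render the lower triangle with significance
#'   stars (`**` p < 0.01, `*` p < 0.05).
#' @param x a `correlationReport`.
#' @param digits coefficient digits.
#' @export
formatCorrelationReport <- function(x, digits = 3) {
  est <- x$estimate; pv <- x$p.value
  star <- ifelse(is.na(pv), "", ifelse(pv < 0.01, " **",
                                       ifelse(pv < 0.05, " *", "")))
  out <- matrix("", nrow(est), ncol(est), dimnames = dimnames(est))
  low <- lower.tri(est)
  out[low] <- paste0(formatC(est[low], digits = digits, format = "f"),
                     star[low])
  out[is.na(est) & low] <- "NA"
  as.data.frame(out)
}

#' @export
print.correlationReport <- function(x, ...) {
  cat(sprintf("Pairwise %s correlations over %d variables\n",
              x$method, ncol(x$estimate)))
  print(formatCorrelationReport(x), ...)
  invisible(x)
}
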