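#' Read coding sequences from a FASTA file
#'
#' Reads a nucleotide FASTA file of coding sequences (one record per gene),
#' uppercases, maps RNA U to DNA T, and truncates each record name at the
#' first whitespace. Records whose length is not a multiple of 3 are kept
#' (they are tallied and removed later by [filterCds()]).
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] of the sequences.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 demo", "atgaaataa"), fa)
#' readCds(fa)
#' @export
readCds <- function(path) {
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  seqs <- toupper(seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

#' Write coding sequences to FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCds <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Split sequences into codons
#'
#' Decomposes each sequence into consecutive 3-mers read in frame from the
#' first base. A trailing partial codon (length not a multiple of 3) is
#' dropped from the codon list; use [isTriplet()] to detect such records.
#'
#' @param seqs a [Biostrings::DNAStringSet] or character vector.
#' @return A named list of character vectors of codons.
#' @examples
#' cdsCodons(c(g1 = "ATGAAATAA"))
#' @export
cdsCodons <- function(seqs) {
  chr <- as.character(seqs)
  lapply(chr, function(s) {
    n <- nchar(s) %/% 3L
    if (n == 0L) return(character())
    substring(s, seq(1L, by = 3L, length.out = n),
              seq(3L, by = 3L, length.out = n))
  })
}

#' @describeIn cdsCodons TRUE where the sequence length is a multiple of 3.
#' @export
isTriplet <- function(seqs) {
  nchar(as.character(seqs)) %% 3L == 0L
}

#' @describeIn cdsCodons TRUE where the last complete in-frame codon is a
#'   stop codon.
#' @param code a [GeneticCode-class] object.
#' @export
hasTerminalStop <- function(seqs, code = standardGeneticCode()) {
  chr <- as.character(seqs)
  full <- (nchar(chr) %/% 3L) * 3L
  ok <- full >= 3L
  last <- rep(NA_character_, length(chr))
  last[ok] <- substring(chr[ok], full[ok] - 2L, full[ok])
  !is.na(last) & last %in% stopCodons(code)
}

#' Quality-filter report for CDS filtering
#'
#' Tallies produced by [filterCds()]. Each rejected record is attributed to
#' the first rule it fails, in the order: missing start codon, missing
#' terminal stop codon, too short, length not a multiple of 3, exact
#' duplicate. The tallies plus the retained count always sum to the input
#' count.
#'
#' @slot nInput,nNoStart,nNoStop,nTooShort,nNonTriplet,nDuplicate,nRetained
#'   integer tallies.
#' @slot retainedIds character vector of surviving record ids, input order.
#' @export
setClass("FilterReport",
         representation(nInput = "integer", nNoStart = "integer",
                        nNoStop = "integer", nTooShort = "integer",
                        nNonTriplet = "integer", nDuplicate = "integer",
                        nRetained = "integer", retainedIds = "character"))

setValidity("FilterReport", function(object) {
  total <- object@nNoStart + object@nNoStop + object@nTooShort +
    object@nNonTriplet + object@nDuplicate + object@nRetained
  if (total != object@nInput)
    return("rejection tallies plus retained count must equal input count")
  if (object@nRetained != length(object@retainedIds))
    return("nRetained must match length(retainedIds)")
  TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat("CDS filter report\n")
  cat("  input:        ", object@nInput, "\n")
  cat("  no start:     ", object@nNoStart, "\n")
  cat("  no stop:      ", object@nNoStop, "\n")
  cat("  too short:    ", object@nTooShort, "\n")
  cat("  non-triplet:  ", object@nNonTriplet, "\n")
  cat("  duplicate:    ", object@nDuplicate, "\n")
  cat("  retained:     ", object@nRetained, "\n")
})

#' @describeIn FilterReport-class ids of retained records.
#' @param object a `FilterReport`.
#' @export
retainedIds <- function(object) object@retainedIds

#' @describeIn FilterReport-class tallies as a one-row data.frame
#'   (convenient for TSV output).
#' @export
filterReportTable <- function(object) {
  data.frame(n_input = object@nInput, n_no_start = object@nNoStart,
             n_no_stop = object@nNoStop, n_too_short = object@nTooShort,
             n_non_triplet = object@nNonTriplet,
             n_duplicate = object@nDuplicate, n_retained = object@nRetained)
}

#' Quality-filter coding sequences
#'
#' Retains sequences that start with ATG, end with a stop codon (TAA, TAG or
#' TGA), are strictly longer than `minLenNt` nucleotides, have length
#' divisible by 3, and are not an exact duplicate of an earlier record
#' (the first occurrence is kept). Survivor order is preserved. Nothing is
#' raised for rejected records; every rejection is tallied in the report,
#' each record counted once under its first failing rule.
#'
#' Internal (premature) stop codons do not cause rejection; they are left to
#' downstream per-codon handling.
#'
#' @param seqs a [Biostrings::DNAStringSet], e.g. from [readCds()].
#' @param minLenNt minimum length in nucleotides, strict (`> minLenNt`);
#'   default 300, so with triplet structure the effective minimum is 303 nt.
#' @param code a [GeneticCode-class] object.
#' @return A list with elements `sequences` (the retained
#'   [Biostrings::DNAStringSet]) and `report` (a [FilterReport-class]).
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(
#'   good = paste0("ATG", strrep("AAA", 101), "TAA"),
#'   nostart = paste0("AAA", strrep("AAA", 101), "TAA")))
#' filterCds(seqs)$report
#' @export
filterCds <- function(seqs, minLenNt = 300, code = standardGeneticCode()) {
  stopifnot(minLenNt >= 0)
  n <- length(seqs)
  if (n == 0L) {
    rep0 <- new("FilterReport", nInput = 0L, nNoStart = 0L, nNoStop = 0L,
                nTooShort = 0L, nNonTriplet = 0L, nDuplicate = 0L,
                nRetained = 0L, retainedIds = character())
    return(list(sequences = seqs, report = rep0))
  }
  chr <- as.character(seqs)
  len <- nchar(chr)
  noStart <- substring(chr, 1L, 3L) != "ATG"
  noStop <- !hasTerminalStop(seqs, code)
  tooShort <- len <= minLenNt
  nonTriplet <- len %% 3L != 0L
  dup <- duplicated(chr)
  # first-failing-rule attribution
  fate <- rep("retained", n)
  fate[dup] <- "duplicate"
  fate[nonTriplet] <- "non_triplet"
  fate[tooShort] <- "too_short"
  fate[noStop] <- "no_stop"
  fate[noStart] <- "no_start"
  keep <- fate == "retained"
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  report <- new("FilterReport",
                nInput = n,
                nNoStart = sum(fate == "no_start"),
                nNoStop = sum(fate == "no_stop"),
                nTooShort = sum(fate == "too_short"),
                nNonTriplet = sum(fate == "non_triplet"),
                nDuplicate = sum(fate == "duplicate"),
                nRetained = sum(keep),
                retainedIds = ids[keep])
  list(sequences = seqs[keep], report = report)
}
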