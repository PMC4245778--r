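## Both-strand degenerate motif scanning.

## Coerce scan subjects to a named DNAStringSet of concrete A/C/G/T
## sequences; degenerate characters are rejected with a clear error.
.asSubject <- function(x) {
  if (is(x, "DNAString")) x <- DNAStringSet(x)
  if (is.character(x)) {
    x <- toupper(chartr("U", "T", x))
    x <- DNAStringSet(x)
  }
  if (!is(x, "DNAStringSet"))
    stop("subject must be a DNAString(Set) or character vector")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- if (is.null(names(x))) paste0("seq", seq_along(x)) else
      ifelse(nzchar(names(x)), names(x), paste0("seq", seq_along(x)))
  af <- Biostrings::alphabetFrequency(x)
  extra <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(extra > 0))
    stop("sequence '", names(x)[which(extra > 0)[1L]],
         "' contains degenerate or non-DNA characters; ",
         "only A/C/G/T are permitted in scan subjects")
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence: '", names(x)[which(Biostrings::width(x) == 0L)[1L]], "'")
  x
}

.asMotif <- function(motif) {
  if (is(motif, "DegenerateMotif")) motif
  else degenerateMotif(as.character(motif), as.character(motif))
}

## Fast vectorised scanner used in the discovery scoring hot path;
## equivalence with the Biostrings path is asserted in the test suite.
## Sequences are integer-coded (A=1, C=2, G=3, T=4) and each IUPAC code is
## a length-4 logical membership table.
.BASES <- c("A", "C", "G", "T")
.IUPAC_LUT <- lapply(IUPAC_SETS, function(s) .BASES %in% s)

.encodeBases <- function(chars) match(chars, .BASES)

## Returns 1-based start positions of windows of the integer-coded
## sequence `ci` matching the IUPAC pattern.
.iupacScanStartsInt <- function(ci, pattern) {
  m <- nchar(pattern)
  L <- length(ci)
  if (m > L) return(integer())
  pc <- strsplit(pattern, "")[[1]]
  n <- L - m + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(m)) {
    lut <- .IUPAC_LUT[[pc[j]]]
    if (all(lut)) next
    ok <- ok & lut[ci[j:(n + j - 1L)]]
  }
  which(ok)
}

.iupacScanStarts <- function(chars, pattern)
  .iupacScanStartsInt(.encodeBases(chars), pattern)

#' Scan a sequence for a degenerate motif on one or both strands
#'
#' Reports every (possibly overlapping) occurrence of an IUPAC motif in one
#' or more concrete DNA sequences.  Reverse-strand matches are found by
#' scanning for the reverse complement of the motif and are reported on
#' forward coordinates with strand \code{"-"}.  Palindromic motifs (equal to
#' their own reverse complement at the IUPAC level) are reported once per
#' locus with strand \code{"+"}.  Circular sequences are scanned across the
#' origin; a match spanning the junction is reported with its start within
#' the sequence and an end running past it (the enclosing \code{GRanges}
#' carries circular seqinfo).
#'
#' @param subject a \link[Biostrings]{DNAString},
#'   \link[Biostrings]{DNAStringSet} or (named) character vector of
#'   A/C/G/T sequences.  Lowercase is upper-cased and U mapped to T on the
#'   character path; degenerate characters are an error.
#' @param motif a \linkS4class{DegenerateMotif} or IUPAC string.
#' @param strands \code{"both"} (default), \code{"forward"} or
#'   \code{"reverse"}.
#' @param circular treat each subject sequence as circular.
#' @return a \link[GenomicRanges]{GRanges} (1-based, closed intervals) with
#'   metadata column \code{motif}; sorted by sequence, start, then strand
#'   (\code{"+"} first).  A motif longer than the (linear) subject yields an
#'   empty result.
#' @examples
#' scanMotif("CCAAGGAGATCTCCAA", "AAGNNNNNCTCC")
#' @export
scanMotif <- function(subject, motif, strands = c("both", "forward", "reverse"),
                      circular = FALSE) {
  strands <- match.arg(strands)
  subject <- .asSubject(subject)
  motif <- .asMotif(motif)
  pal <- isPalindromic(motif@iupac)
  m <- nchar(motif@iupac)
  pats <- list()
  if (pal) {
    pats[["+"]] <- motif@iupac            # one report per locus
  } else {
    if (strands %in% c("both", "forward")) pats[["+"]] <- motif@iupac
    if (strands %in% c("both", "reverse")) pats[["-"]] <- revcompIupac(motif@iupac)
  }
  out <- list()
  for (i in seq_along(subject)) {
    L <- Biostrings::width(subject)[i]
    sq <- subject[[i]]
    if (circular && m > 1L && m <= L)
      sq <- xscat(sq, subseq(sq, 1L, m - 1L))
    if (m > length(sq)) next
    for (st in names(pats)) {
      mp <- matchPattern(DNAString(pats[[st]]), sq, fixed = FALSE)
      starts <- Biostrings::start(mp)
      if (circular) starts <- starts[starts <= L]
      if (!length(starts)) next
      out[[length(out) + 1L]] <- GRanges(
        seqnames = names(subject)[i],
        ranges = IRanges(start = starts, width = m),
        strand = st, motif = motif@name)
    }
  }
  sl <- setNames(Biostrings::width(subject), names(subject))
  si <- GenomeInfoDb::Seqinfo(seqnames = names(subject), seqlengths = sl,
                              isCircular = rep(circular, length(subject)))
  if (!length(out))
    return(GRanges(seqinfo = si, motif = character()))
  gr <- suppressWarnings(do.call(c, out))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(si)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- si)
  gr <- gr[order(match(as.character(GenomicRanges::seqnames(gr)),
                       names(subject)),
                 GenomicRanges::start(gr),
                 match(as.character(GenomicRanges::strand(gr)), c("+", "-")))]
  gr
}

#' Count motif occurrences per sequence
#'
#' Tabulates both-strand match counts of a set of motifs across a set of
#' sequences; counts equal the number of rows \code{\link{scanMotif}}
#' reports.
#'
#' @inheritParams scanMotif
#' @param motifs a list of \linkS4class{DegenerateMotif} (or IUPAC strings),
#'   e.g. \code{\link{motifRegistry}()}; may be empty.
#' @return integer matrix with one row per sequence, one column per motif.
#' @examples
#' countSites("CCAAGGAGATCTCCAA", motifRegistry())
#' @export
countSites <- function(subject, motifs, circular = FALSE) {
  subject <- .asSubject(subject)
  motifs <- lapply(motifs, .asMotif)
  nm <- vapply(motifs, motifName, character(1))
  counts <- matrix(0L, nrow = length(subject), ncol = length(motifs),
                   dimnames = list(names(subject), nm))
  for (j in seq_along(motifs)) {
    gr <- scanMotif(subject, motifs[[j]], "both", circular = circular)
    if (length(gr)) {
      tab <- table(factor(as.character(GenomicRanges::seqnames(gr)),
                          levels = names(subject)))
      counts[, j] <- as.integer(tab)
    }
  }
  counts
}
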