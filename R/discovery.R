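## Motif inference from m6A position calls: the computational counterpart
## of SMRT methylome analysis.

#' Extract strand-oriented sequence contexts around m6A calls
#'
#' Cuts a window of \code{halfWidth} bases either side of each call and
#' orients it to the call's strand (reverse-strand windows are
#' reverse-complemented), so the methylated base reads as an A at the
#' center column.  Windows truncated by the genome ends are excluded.
#'
#' @param genome \link[Biostrings]{DNAStringSet} of length 1 (or
#'   DNAString / character).
#' @param calls \link[GenomicRanges]{GRanges} of width-1 strand-specific
#'   calls (positions 1-based).
#' @param halfWidth window half-width; must be at least the maximal motif
#'   span under consideration (default 15).
#' @return character vector of oriented contexts, each of width
#'   \code{2 * halfWidth + 1}.
#' @export
extractContexts <- function(genome, calls, halfWidth = 15L) {
  genome <- .asSubject(genome)
  L <- Biostrings::width(genome)[1L]
  pos <- GenomicRanges::start(calls)
  if (length(pos) && (min(pos) < 1L || max(pos) > L))
    stop("call position outside genome")
  strand <- as.character(GenomicRanges::strand(calls))
  keep <- pos - halfWidth >= 1L & pos + halfWidth <= L
  pos <- pos[keep]; strand <- strand[keep]
  if (!length(pos)) return(character())
  v <- Biostrings::Views(genome[[1L]],
                         start = pos - halfWidth, end = pos + halfWidth)
  ctx <- as.character(v)
  rev <- strand == "-"
  if (any(rev))
    ctx[rev] <- as.character(
      reverseComplement(DNAStringSet(ctx[rev])))
  unname(ctx)
}

#' Column-wise IUPAC consensus of aligned contexts
#'
#' For each column, reports the smallest IUPAC code (fewest concrete bases;
#' ties broken by coverage, then alphabetically) whose base set covers at
#' least \code{minFraction} of the observed bases; columns where no code
#' smaller than N achieves that are reported as N.
#'
#' @param contexts character vector of equal-width A/C/G/T strings.
#' @param minFraction minimal coverage for a defined code (default 0.9,
#'   tolerating ~5\% missed calls plus rare false positives).
#' @param minSites minimal number of contexts required (default 5).
#' @return single IUPAC string, one code per column.
#' @export
consensusColumns <- function(contexts, minFraction = 0.9, minSites = 5L) {
  if (length(contexts) < minSites)
    stop("insufficient calls: ", length(contexts), " context(s), need >= ",
         minSites)
  cm <- Biostrings::consensusMatrix(DNAStringSet(contexts))
  cm <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  n <- length(contexts)
  codes <- names(IUPAC_SETS)
  card <- vapply(IUPAC_SETS, length, numeric(1))
  ord <- order(card, codes)
  codes <- codes[ord]
  sets <- IUPAC_SETS[ord]
  out <- vapply(seq_len(ncol(cm)), function(j) {
    freq <- cm[, j] / n
    cov <- vapply(sets, function(s) sum(freq[s]), numeric(1))
    okCard <- card[ord][cov >= minFraction]
    if (!length(okCard)) return("N")
    best <- cov >= minFraction & card[ord] == min(okCard)
    cand <- which(best)
    cand <- cand[order(-cov[cand], codes[cand])]
    codes[cand[1L]]
  }, character(1))
  paste(out, collapse = "")
}

## ---- candidate construction -------------------------------------------

.candidateIupac <- function(left, spacer, right)
  paste0(left, strrep("N", spacer), right)

#' Create an (unscored) MotifCandidate
#'
#' @param left defined 5' IUPAC block (no N).
#' @param spacer number of fully degenerate (N) spacer positions.
#' @param right defined 3' IUPAC block, possibly empty.
#' @return a \linkS4class{MotifCandidate} with NA scores, ready for
#'   \code{\link{scoreCandidate}}.
#' @export
motifCandidate <- function(left, spacer = 0L, right = "")
  .newCandidate(left, spacer, right)

.newCandidate <- function(left, spacer, right) {
  new("MotifCandidate", left = left, spacer = as.integer(spacer),
      right = right,
      methylOffsets = data.frame(offset = integer(), strand = character()),
      sensitivity = NA_real_, specificity = NA_real_, score = NA_real_,
      nOccurrences = NA_integer_, nSupported = NA_integer_,
      nCallsExplained = NA_integer_, note = "")
}

## Canonical orientation: the lexicographically smaller of the motif and
## its reverse complement, so that a motif and its mirror image (the same
## recognition sequence read from the other strand) collapse to one
## candidate.
.canonicalizeCandidate <- function(cand) {
  iu <- .candidateIupac(cand@left, cand@spacer, cand@right)
  rc <- revcompIupac(iu)
  if (rc < iu) {
    if (nzchar(cand@right))
      return(.newCandidate(revcompIupac(cand@right), cand@spacer,
                           revcompIupac(cand@left)))
    return(.newCandidate(revcompIupac(cand@left), 0L, ""))
  }
  cand
}

#' Enumerate bipartite candidates from a consensus string
#'
#' All (left block, spacer, right block) croppings of a column consensus
#' whose defined blocks contain no N, with block and spacer lengths from
#' \code{searchSpace}, anchored so the (central) methylated position falls
#' inside the motif span.  Duplicates are removed.
#'
#' @param consensus IUPAC string, e.g. from \code{\link{consensusColumns}}.
#' @param searchSpace list with integer vectors \code{left} (block lengths,
#'   default 2:6), \code{spacer} (default 0:9) and \code{right} (default
#'   0:6; 0 = no right block).  The defaults follow the structure of
#'   bacterial Type I recognition sequences: short defined blocks flanking
#'   a fully degenerate spacer.
#' @param center column index of the methylated position (default: middle
#'   column).
#' @return list of unscored \linkS4class{MotifCandidate}.
#' @export
enumerateCandidates <- function(consensus,
                                searchSpace = list(left = 2:6, spacer = 0:9,
                                                   right = c(0L, 2:6)),
                                center = NULL) {
  W <- nchar(consensus)
  if (is.null(center)) center <- (W + 1L) %/% 2L
  chars <- strsplit(consensus, "")[[1]]
  out <- list()
  seen <- character()
  for (l1 in searchSpace$left) {
    for (a1 in seq_len(max(0L, W - l1 + 1L))) {
      left <- substr(consensus, a1, a1 + l1 - 1L)
      if (grepl("N", left)) next
      for (g in searchSpace$spacer) {
        for (l2 in searchSpace$right) {
          a2 <- a1 + l1 + g
          e <- a2 + l2 - 1L
          if (l2 > 0L && e > W) next
          right <- if (l2 > 0L) substr(consensus, a2, e) else ""
          if (l2 > 0L && grepl("N", right)) next
          if (l2 == 0L && g > 0L) next   # trailing bare spacer is no motif
          span <- if (l2 > 0L) e else a1 + l1 - 1L
          if (center < a1 || center > span) next
          cand <- .canonicalizeCandidate(.newCandidate(left, g, right))
          key <- .candidateIupac(cand@left, cand@spacer, cand@right)
          if (key %in% seen) next
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out
}

## Frequent-word candidate seeding.  Strand-oriented contexts of a
## non-palindromic motif methylated on both strands form a two-component
## mixture (one component per methylated strand), so a single column-wise
## consensus washes out the defined blocks.  Concrete block words at a
## fixed offset, however, remain frequent within their component; blocks
## reaching blockMinFrac are combined into bipartite candidates.
.wordCandidates <- function(contexts, searchSpace, blockMinFrac = 0.3) {
  W <- nchar(contexts[1L])
  center <- (W + 1L) %/% 2L
  n <- length(contexts)
  lens <- sort(unique(c(searchSpace$left, searchSpace$right[searchSpace$right > 0L])))
  blocks <- list()   # each: list(a, l, word)
  for (l in lens) {
    for (a in seq_len(W - l + 1L)) {
      words <- substr(contexts, a, a + l - 1L)
      tab <- table(words) / n
      for (w in names(tab)[tab >= blockMinFrac])
        blocks[[length(blocks) + 1L]] <- list(a = a, l = l, word = w)
    }
  }
  out <- list()
  seen <- character()
  add <- function(cand) {
    cand <- .canonicalizeCandidate(cand)
    key <- .candidateIupac(cand@left, cand@spacer, cand@right)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      out[[length(out) + 1L]] <<- cand
    }
  }
  for (b1 in blocks) {
    if (!b1$l %in% searchSpace$left) next
    ## single-block candidate covering the center
    if (0L %in% searchSpace$right &&
        center >= b1$a && center <= b1$a + b1$l - 1L)
      add(.newCandidate(b1$word, 0L, ""))
    for (b2 in blocks) {
      if (!b2$l %in% searchSpace$right) next
      g <- b2$a - (b1$a + b1$l)
      if (!g %in% searchSpace$spacer) next
      if (center < b1$a || center > b2$a + b2$l - 1L) next
      add(.newCandidate(b1$word, g, b2$word))
    }
  }
  out
}

## ---- scoring -----------------------------------------------------------

#' Score a motif candidate against a genome and a call set
#'
#' Scans the genome for the candidate (both strands), infers which motif
#' positions are methylated (positions whose mapped genomic site carries a
#' call in at least \code{offsetMinFrac} of occurrences, considering every
#' A-compatible position on the top strand and T-compatible position for
#' the bottom strand), then computes: specificity = fraction of genomic
#' occurrences with at least one supporting call; sensitivity = fraction of
#' calls falling at an inferred methyl offset of some occurrence; score =
#' harmonic mean of the two (0 when both are 0).
#'
#' @param candidate a \linkS4class{MotifCandidate}.
#' @param genome \link[Biostrings]{DNAStringSet} of length 1 (or
#'   DNAString / character).
#' @param calls \link[GenomicRanges]{GRanges} of width-1 calls.
#' @param offsetMinFrac support fraction required to accept a methyl
#'   offset (default 0.3: roughly half of one strand-component's share
#'   after detection losses).
#' @return the candidate with scores filled in; a candidate with zero
#'   genomic occurrences is returned unscored with an explanatory
#'   \code{note} (specificity undefined).
#' @export
scoreCandidate <- function(candidate, genome, calls, offsetMinFrac = 0.3) {
  genome <- .asSubject(genome)
  ci <- .encodeBases(strsplit(as.character(genome[[1L]]), "")[[1]])
  .scoreCandidateFast(candidate, ci,
                      GenomicRanges::start(calls),
                      as.character(GenomicRanges::strand(calls)),
                      offsetMinFrac)
}

## Hot-path scoring on an integer-coded genome.  (pos, strand) pairs are
## packed into integer keys (pos * 2 + [strand == "-"]).
.scoreCandidateFast <- function(candidate, ci, callPos, callStrand,
                                offsetMinFrac = 0.3) {
  iu <- .candidateIupac(candidate@left, candidate@spacer, candidate@right)
  m <- nchar(iu)
  fw <- .iupacScanStartsInt(ci, iu)
  pal <- identical(iu, revcompIupac(iu))
  rv <- if (pal) integer() else .iupacScanStartsInt(ci, revcompIupac(iu))
  occStart <- c(fw, rv)
  occPlus <- rep(c(TRUE, FALSE), c(length(fw), length(rv)))
  nOcc <- length(occStart)
  if (nOcc == 0L) {
    candidate@note <- "no genomic occurrence; specificity undefined"
    return(candidate)
  }
  nCalls <- length(callPos)
  callKey <- callPos * 2L + (callStrand == "-")
  pc <- strsplit(iu, "")[[1]]
  offPlus <- which(vapply(pc, function(ch) .IUPAC_LUT[[ch]][1L], logical(1)))
  offMinus <- which(vapply(pc, function(ch) .IUPAC_LUT[[ch]][4L], logical(1)))
  offs <- c(offPlus, offMinus)
  offStrandMinus <- rep(c(FALSE, TRUE), c(length(offPlus), length(offMinus)))
  nOff <- length(offs)
  keep <- logical(nOff)
  suppMat <- matrix(FALSE, nrow = nOcc, ncol = nOff)
  keyMat <- matrix(0L, nrow = nOcc, ncol = nOff)
  for (k in seq_len(nOff)) {
    off <- offs[k]
    ## genomic position/strand of motif position `off` for each occurrence
    pos <- ifelse(occPlus, occStart + off - 1L, occStart + m - off)
    minus <- ifelse(occPlus, offStrandMinus[k], !offStrandMinus[k])
    key <- pos * 2L + minus
    keyMat[, k] <- key
    hit <- key %in% callKey
    suppMat[, k] <- hit
    keep[k] <- nCalls > 0L && mean(hit) >= offsetMinFrac
  }
  if (!any(keep)) {
    candidate@methylOffsets <- data.frame(offset = integer(),
                                          strand = character())
    candidate@sensitivity <- 0
    candidate@specificity <- 0
    candidate@score <- 0
    candidate@nOccurrences <- as.integer(nOcc)
    candidate@nSupported <- 0L
    candidate@nCallsExplained <- 0L
    return(candidate)
  }
  mo <- data.frame(offset = offs[keep],
                   strand = ifelse(offStrandMinus[keep], "-", "+"))
  mo <- mo[order(mo$offset, mo$strand), , drop = FALSE]
  rownames(mo) <- NULL
  supported <- rowSums(suppMat[, keep, drop = FALSE]) > 0
  specificity <- mean(supported)
  explained <- callKey %in% as.vector(keyMat[, keep])
  sensitivity <- if (nCalls) mean(explained) else 0
  score <- if (sensitivity + specificity == 0) 0 else
    2 * sensitivity * specificity / (sensitivity + specificity)
  candidate@methylOffsets <- mo
  candidate@sensitivity <- sensitivity
  candidate@specificity <- specificity
  candidate@score <- score
  candidate@nOccurrences <- as.integer(nOcc)
  candidate@nSupported <- as.integer(sum(supported))
  candidate@nCallsExplained <- as.integer(sum(explained))
  candidate
}

## Nested candidates tie on score whenever the genome happens to contain
## no unmethylated chance occurrence that discriminates them, so the
## tie-break matters.  Rules, in order: (1) more fully concrete positions
## (a truncation of the true motif, e.g. AGNNNNNCTCC vs AAGNNNNNCTCC,
## loses); (2) shorter span (a spurious partially-degenerate extension
## read off a small consensus, e.g. DGATC vs GATC, loses); (3) higher
## information content (CCWGG beats CCNGG); (4) lexicographic IUPAC.
.candKey <- function(cand) {
  iu <- .candidateIupac(cand@left, cand@spacer, cand@right)
  sizes <- vapply(strsplit(iu, "")[[1]],
                  function(ch) length(IUPAC_SETS[[ch]]), numeric(1))
  list(iupac = iu, concrete = sum(sizes == 1L),
       span = nchar(iu), info = sum(2 - log2(sizes)))
}

.rankCandidates <- function(cands) {
  if (!length(cands)) return(integer())
  keys <- lapply(cands, .candKey)
  score <- vapply(cands, function(x) x@score, numeric(1))
  order(-score,
        -vapply(keys, `[[`, numeric(1), "concrete"),
        vapply(keys, `[[`, numeric(1), "span"),
        -vapply(keys, `[[`, numeric(1), "info"),
        vapply(keys, `[[`, character(1), "iupac"))
}

#' Infer a recognition motif from m6A calls against a genome
#'
#' The discovery pipeline: extract strand-oriented call contexts, seed
#' candidate (left, spacer, right) motifs from (i) croppings of the
#' column-wise IUPAC consensus and (ii) frequent concrete block words at
#' fixed offsets (which survive the two-component strand mixture produced
#' by non-palindromic bipartite motifs), score every candidate against the
#' genome and call set, and rank by F-measure with deterministic
#' tie-breaking (fewer degenerate positions, shorter span, lexicographic).
#'
#' @inheritParams scoreCandidate
#' @inheritParams extractContexts
#' @inheritParams enumerateCandidates
#' @param minSites minimal number of usable calls (default 5).
#' @param minFraction consensus column coverage (default 0.9).
#' @param blockMinFrac word frequency threshold for block seeding
#'   (default 0.3).
#' @param scoreThreshold minimal top score for a confident report
#'   (default 0.5); below it the result is flagged "no confident motif".
#' @return a \linkS4class{MotifDiscovery}.
#' @examples
#' sim <- simulateGenome(4000, motifRegistry()$CpaAII, nPlanted = 12, seed = 3)
#' calls <- simulateMethylome(sim$genome, sim$occurrences,
#'                            motifRegistry()$CpaAII, seed = 3)
#' discoverMotif(sim$genome, calls)
#' @export
discoverMotif <- function(genome, calls, halfWidth = 15L, minSites = 5L,
                          minFraction = 0.9, blockMinFrac = 0.3,
                          offsetMinFrac = 0.3, scoreThreshold = 0.5,
                          searchSpace = list(left = 2:6, spacer = 0:9,
                                             right = c(0L, 2:6))) {
  genome <- .asSubject(genome)
  contexts <- extractContexts(genome, calls, halfWidth)
  if (length(contexts) < minSites)
    stop("insufficient calls: ", length(contexts),
         " usable context(s), need >= ", minSites)
  consensus <- consensusColumns(contexts, minFraction, minSites)
  cands <- c(enumerateCandidates(consensus, searchSpace),
             .wordCandidates(contexts, searchSpace, blockMinFrac))
  ## dedupe across the two seeding routes (both canonicalized already)
  key <- vapply(cands, function(x)
    .candidateIupac(x@left, x@spacer, x@right), character(1))
  cands <- cands[!duplicated(key)]
  ci <- .encodeBases(strsplit(as.character(genome[[1L]]), "")[[1]])
  callPos <- GenomicRanges::start(calls)
  callStrand <- as.character(GenomicRanges::strand(calls))
  scored <- lapply(cands, .scoreCandidateFast, ci = ci,
                   callPos = callPos, callStrand = callStrand,
                   offsetMinFrac = offsetMinFrac)
  droppedIdx <- vapply(scored, function(x) nzchar(x@note), logical(1))
  dropped <- data.frame(
    iupac = vapply(scored[droppedIdx], function(x)
      .candidateIupac(x@left, x@spacer, x@right), character(1)),
    reason = vapply(scored[droppedIdx], function(x) x@note, character(1)))
  scored <- scored[!droppedIdx]
  ord <- .rankCandidates(scored)
  scored <- scored[ord]
  tab <- if (length(scored)) data.frame(
    iupac = vapply(scored, function(x)
      .candidateIupac(x@left, x@spacer, x@right), character(1)),
    left = vapply(scored, function(x) x@left, character(1)),
    spacer = vapply(scored, function(x) x@spacer, integer(1)),
    right = vapply(scored, function(x) x@right, character(1)),
    sensitivity = vapply(scored, function(x) x@sensitivity, numeric(1)),
    specificity = vapply(scored, function(x) x@specificity, numeric(1)),
    score = vapply(scored, function(x) x@score, numeric(1)),
    nOccurrences = vapply(scored, function(x) x@nOccurrences, integer(1)),
    nSupported = vapply(scored, function(x) x@nSupported, integer(1)),
    row.names = NULL)
  else data.frame()
  confident <- length(scored) > 0L && scored[[1L]]@score >= scoreThreshold
  new("MotifDiscovery", candidates = scored, table = tab,
      confident = confident, scoreThreshold = scoreThreshold,
      dropped = dropped)
}

#' @describeIn discoverMotif top-ranked candidate (or NULL when none).
#' @param x a MotifDiscovery.
#' @export
topCandidate <- function(x) {
  stopifnot(is(x, "MotifDiscovery"))
  if (length(x@candidates)) x@candidates[[1L]] else NULL
}

#' @describeIn discoverMotif full IUPAC string of a candidate.
#' @param candidate a MotifCandidate.
#' @export
candidateIupac <- function(candidate)
  .candidateIupac(candidate@left, candidate@spacer, candidate@right)

setMethod("show", "MotifCandidate", function(object) {
  cat(sprintf(
    "MotifCandidate (%s, %d, %s) = 5'-%s-3'\n  sens %.3f  spec %.3f  F %.3f  (%s/%s occurrences supported)\n",
    object@left, object@spacer,
    if (nzchar(object@right)) object@right else "-",
    .candidateIupac(object@left, object@spacer, object@right),
    object@sensitivity, object@specificity, object@score,
    ifelse(is.na(object@nSupported), "?", object@nSupported),
    ifelse(is.na(object@nOccurrences), "?", object@nOccurrences)))
})

setMethod("show", "MotifDiscovery", function(object) {
  cat(sprintf("MotifDiscovery: %d scored candidate(s); %s\n",
              length(object@candidates),
              if (object@confident) "confident" else
                sprintf("no confident motif (top score < %.2f)",
                        object@scoreThreshold)))
  if (nrow(object@table))
    print(head(object@table[, c("iupac", "sensitivity", "specificity",
                                "score", "nOccurrences", "nSupported")], 5L))
})
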