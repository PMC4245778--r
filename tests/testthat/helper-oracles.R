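## Independent oracles used across the suite.  Everything here is written
## from first principles (hand-coded IUPAC tables, per-window loops,
## exhaustive enumeration) and deliberately shares no code with the
## package internals it checks.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracleRevcomp <- function(s)
  paste(rev(unname(ORACLE_COMP[strsplit(s, "")[[1]]])), collapse = "")

## Forward-strand starts of an IUPAC pattern by naive per-window check.
oracleScanStarts <- function(seqStr, iupacStr) {
  sq <- strsplit(seqStr, "")[[1]]
  pats <- ORACLE_IUPAC[strsplit(iupacStr, "")[[1]]]
  m <- length(pats); L <- length(sq)
  if (m > L) return(integer())
  starts <- integer()
  for (s in seq_len(L - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m))
      if (!sq[s + j - 1L] %in% pats[[j]]) { ok <- FALSE; break }
    if (ok) starts <- c(starts, s)
  }
  starts
}

## Both-strand matches as data.frame(start, strand), palindromes reported
## once on "+".
oracleScanBoth <- function(seqStr, iupacStr) {
  fw <- oracleScanStarts(seqStr, iupacStr)
  out <- data.frame(start = fw,
                    strand = rep("+", length(fw)))
  if (iupacStr != oracleRevcomp(iupacStr)) {
    rv <- oracleScanStarts(seqStr, oracleRevcomp(iupacStr))
    out <- rbind(out, data.frame(start = rv,
                                 strand = rep("-", length(rv))))
  }
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

randomIupac <- function(n, degenProb = 0.3) {
  codes <- names(ORACLE_IUPAC)
  paste(ifelse(runif(n) < degenProb,
               sample(codes, n, replace = TRUE),
               sample(c("A", "C", "G", "T"), n, replace = TRUE)),
        collapse = "")
}

## Standard genetic code, written out for oracle use.
ORACLE_CODE <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  eg <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                    stringsAsFactors = FALSE)   # b1 slowest: TCAG-major
  codons <- paste0(eg$b1, eg$b2, eg$b3)
  setNames(aa, codons)
})

oracleTranslate <- function(s) {
  n <- nchar(s)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(ORACLE_CODE[codons]), collapse = "")
}

oracleSynonyms <- function(codon) {
  aa <- ORACLE_CODE[[codon]]
  sort(setdiff(names(ORACLE_CODE)[ORACLE_CODE == aa], codon))
}

## Exhaustive minimal silent ablation: enumerate all synonymous codon
## combinations of a (short) cds, require zero both-strand matches of the
## motif, return the minimal substitution count (NA when infeasible).
oracleKillMin <- function(cds, iupacStr) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  optList <- lapply(codons, function(cd) c(cd, oracleSynonyms(cd)))
  grid <- expand.grid(lapply(optList, seq_along), KEEP.OUT.ATTRS = FALSE)
  best <- NA_integer_
  for (g in seq_len(nrow(grid))) {
    newCodons <- vapply(seq_len(n), function(j) optList[[j]][[grid[g, j]]],
                        character(1))
    trial <- paste(newCodons, collapse = "")
    if (nrow(oracleScanBoth(trial, iupacStr))) next
    cost <- sum(strsplit(trial, "")[[1]] != strsplit(cds, "")[[1]])
    if (is.na(best) || cost < best) best <- cost
  }
  best
}

## Minimal Hamming distance to create a motif match: per-offset, per-strand
## count of positions whose base falls outside the pattern set.
oracleCreateMin <- function(seqStr, iupacStr) {
  sq <- strsplit(seqStr, "")[[1]]
  L <- length(sq)
  pats <- list(iupacStr)
  if (iupacStr != oracleRevcomp(iupacStr))
    pats <- c(pats, oracleRevcomp(iupacStr))
  best <- Inf
  for (p in pats) {
    sets <- ORACLE_IUPAC[strsplit(p, "")[[1]]]
    m <- length(sets)
    for (o in seq_len(L - m + 1L)) {
      cost <- 0L
      for (j in seq_len(m))
        if (!sq[o + j - 1L] %in% sets[[j]]) cost <- cost + 1L
      if (cost < best) best <- cost
    }
  }
  best
}

## Exhaustive context-supported candidate enumeration for discovery:
## every (left, spacer, right) reading of every context at every placement
## covering the center, canonicalized by reverse complement.
oracleContextCandidates <- function(contexts, leftLens = 2:6,
                                    spacers = 0:9,
                                    rightLens = c(0L, 2:6)) {
  W <- nchar(contexts[1L])
  center <- (W + 1L) %/% 2L
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (ctx in contexts) {
    for (l1 in leftLens) {
      for (a1 in seq_len(W - l1 + 1L)) {
        left <- substr(ctx, a1, a1 + l1 - 1L)
        for (g in spacers) {
          for (l2 in rightLens) {
            if (l2 == 0L && g > 0L) next
            a2 <- a1 + l1 + g
            e <- if (l2 > 0L) a2 + l2 - 1L else a1 + l1 - 1L
            if (e > W) next
            if (center < a1 || center > e) next
            right <- if (l2 > 0L) substr(ctx, a2, e) else ""
            iu <- paste0(left, strrep("N", g), right)
            rc <- oracleRevcomp(iu)
            key <- if (rc < iu) rc else iu
            if (!is.null(seen[[key]])) next
            seen[[key]] <- TRUE
            if (rc < iu) {
              if (nzchar(right))
                out[[length(out) + 1L]] <- list(left = oracleRevcomp(right),
                                                spacer = g,
                                                right = oracleRevcomp(left))
              else
                out[[length(out) + 1L]] <- list(left = oracleRevcomp(left),
                                                spacer = 0L, right = "")
            } else {
              out[[length(out) + 1L]] <- list(left = left, spacer = g,
                                              right = right)
            }
          }
        }
      }
    }
  }
  out
}

## Ranking rule applied independently: score desc, concrete positions
## desc, span asc, information content desc, lexicographic.
oracleRankKey <- function(iu, score) {
  sizes <- vapply(strsplit(iu, "")[[1]],
                  function(ch) length(ORACLE_IUPAC[[ch]]), numeric(1))
  list(score = score, concrete = sum(sizes == 1), span = nchar(iu),
       info = sum(2 - log2(sizes)), iu = iu)
}

## TRUE when key a outranks key b.
oracleOutranks <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$concrete != b$concrete) return(a$concrete > b$concrete)
  if (a$span != b$span) return(a$span < b$span)
  if (a$info != b$info) return(a$info > b$info)
  a$iu < b$iu
}

## Exhaustive minimal silent ablation restricted to the codons overlapping
## the (single) site; the whole trial sequence must end up match-free.
oracleKillMinLocal <- function(cds, iupacStr) {
  mt <- oracleScanBoth(cds, iupacStr)
  stopifnot(nrow(mt) == 1L)
  s <- mt$start[1L]; e <- s + nchar(iupacStr) - 1L
  n <- nchar(cds) %/% 3L
  codStart <- 3L * seq_len(n) - 2L
  idx <- which(codStart + 2L >= s & codStart <= e)
  codons <- substring(cds, codStart, codStart + 2L)
  optList <- lapply(codons[idx], function(cd) c(cd, oracleSynonyms(cd)))
  grid <- expand.grid(lapply(optList, seq_along), KEEP.OUT.ATTRS = FALSE)
  best <- NA_integer_
  for (g in seq_len(nrow(grid))) {
    trial <- strsplit(cds, "")[[1]]
    for (j in seq_along(idx)) {
      cd <- optList[[j]][[grid[g, j]]]
      trial[codStart[idx[j]]:(codStart[idx[j]] + 2L)] <-
        strsplit(cd, "")[[1]]
    }
    trialStr <- paste(trial, collapse = "")
    if (nrow(oracleScanBoth(trialStr, iupacStr))) next
    cost <- sum(trial != strsplit(cds, "")[[1]])
    if (is.na(best) || cost < best) best <- cost
  }
  best
}
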