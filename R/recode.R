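## Translation-preserving sequence editing: exhaustive scrub recoding,
## minimal site ablation, minimal site creation.

.splitChars <- function(x) strsplit(x, "")[[1]]

.asCdsString <- function(x) {
  if (is(x, "DNAString")) x <- as.character(x)
  if (is(x, "DNAStringSet")) x <- as.character(x)[1L]
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single string or DNAString")
  x <- toupper(chartr("Uu", "TT", x))
  if (!nzchar(x)) stop("empty sequence")
  if (grepl("[^ACGT]", x))
    stop("sequence contains non-A/C/G/T characters")
  x
}

.translateString <- function(s) {
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("length not divisible by 3 in frame")
  if (n == 0L) return("")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("invalid codon: ", codons[which(is.na(aa))[1L]])
  paste(aa, collapse = "")
}

#' Translate a coding sequence
#'
#' Standard-code translation of the in-frame span; stop codons render as
#' \code{*}.
#'
#' @param cds coding sequence (string or \link[Biostrings]{DNAString});
#'   U is mapped to T.
#' @param frame 0-based offset of the first complete codon.
#' @return protein string.
#' @examples
#' translateCds("GCAAGTTATGCTCCA")  # "ASYAP"
#' @export
translateCds <- function(cds, frame = 0L) {
  cds <- .asCdsString(cds)
  n <- nchar(cds) - frame
  if (n %% 3L != 0L)
    stop("length not divisible by 3 in frame (", n, " nt after offset ",
         frame, ")")
  .translateString(substr(cds, frame + 1L, nchar(cds)))
}

#' Synonymous alternatives of a codon
#'
#' All codons encoding the same amino acid, excluding the input; empty for
#' Met (ATG) and Trp (TGG).
#'
#' @param codon a 3-letter codon (DNA; U mapped to T).
#' @return sorted character vector of codons.
#' @examples
#' synonymousOptions("AGT")  # the other five Ser codons, TCT among them
#' synonymousOptions("GCT")  # GCA, GCC, GCG
#' @export
synonymousOptions <- function(codon) {
  codon <- .asCdsString(codon)
  if (nchar(codon) != 3L) stop("'codon' must have length 3")
  aa <- Biostrings::GENETIC_CODE[codon]
  if (is.na(aa)) stop("invalid codon: ", codon)
  sort(setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE == aa], codon))
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b strings of equal length.
#' @return integer count of differing positions.
#' @examples
#' hammingDist("AGT", "TCT")  # 2
#' @export
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  sum(.splitChars(a) != .splitChars(b))
}

## ---- RecodePlan construction and accessors ----------------------------

.mkPlan <- function(input, output, frame = 0L, coding = TRUE) {
  inp <- .splitChars(input)
  out <- .splitChars(output)
  pos <- which(inp != out)
  new("RecodePlan", input = input, output = output,
      substitutions = data.frame(pos = as.integer(pos), from = inp[pos],
                                 to = out[pos]),
      frame = as.integer(frame), coding = coding)
}

#' Build and validate a recode plan from an explicit substitution list
#'
#' Constructs a \linkS4class{RecodePlan} from single-nucleotide
#' substitutions; for coding plans, validity checks that translation is
#' preserved.
#'
#' @param input input sequence (string or DNAString).
#' @param substitutions data.frame with columns \code{pos} (1-based),
#'   \code{from}, \code{to}.
#' @param frame 0-based offset of the first complete codon.
#' @param coding enforce translation preservation (default TRUE).
#' @return a \linkS4class{RecodePlan}.
#' @export
recodePlan <- function(input, substitutions, frame = 0L, coding = TRUE) {
  input <- .asCdsString(input)
  out <- .splitChars(input)
  out[substitutions$pos] <- substitutions$to
  plan <- new("RecodePlan", input = input, output = paste(out, collapse = ""),
              substitutions = data.frame(pos = as.integer(substitutions$pos),
                                         from = substitutions$from,
                                         to = substitutions$to),
              frame = as.integer(frame), coding = coding)
  plan
}

#' @rdname recodePlan
#' @param replacements data.frame with columns \code{codon} (1-based codon
#'   index) and \code{to} (replacement codon); used to express published
#'   codon-level edits, e.g. AGT -> TCT at codon 2.
#' @export
codonReplacements <- function(input, replacements, frame = 0L) {
  input <- .asCdsString(input)
  out <- .splitChars(input)
  for (i in seq_len(nrow(replacements))) {
    ci <- replacements$codon[i]
    at <- frame + 3L * (ci - 1L)
    if (at + 3L > nchar(input)) stop("codon index ", ci, " out of range")
    out[(at + 1L):(at + 3L)] <- .splitChars(toupper(chartr("U", "T",
                                                   replacements$to[i])))
  }
  .mkPlan(input, paste(out, collapse = ""), frame = frame, coding = TRUE)
}

#' @rdname recodePlan
#' @param plan a RecodePlan.
#' @export
nSubstitutions <- function(plan) nrow(plan@substitutions)

#' @rdname recodePlan
#' @export
maxUnalteredRun <- function(plan) {
  same <- .splitChars(plan@input) == .splitChars(plan@output)
  if (all(!same)) return(0L)
  r <- rle(same)
  max(r$lengths[r$values])
}

#' @rdname recodePlan
#' @export
nCodonsAltered <- function(plan) {
  if (!nrow(plan@substitutions)) return(0L)
  pos <- plan@substitutions$pos
  pos <- pos[pos > plan@frame &
               pos <= plan@frame + 3L * ((nchar(plan@input) - plan@frame) %/% 3L)]
  length(unique((pos - plan@frame - 1L) %/% 3L))
}

#' @rdname recodePlan
#' @export
recodedSequence <- function(plan) plan@output

#' @rdname recodePlan
#' @export
substitutions <- function(plan) plan@substitutions

setMethod("show", "RecodePlan", function(object) {
  cat(sprintf(
    "RecodePlan: %d substitution(s), %d codon(s) altered, max unaltered run %d nt%s\n",
    nSubstitutions(object), nCodonsAltered(object), maxUnalteredRun(object),
    if (object@coding) " (translation preserved)" else ""))
})

## ---- shared scanning helpers ------------------------------------------

## All matches of a motif list on a character vector, both strands.
## Returns data.frame(start, end, strand, motif).
.allMatches <- function(chars, motifs) {
  out <- list()
  for (mot in motifs) {
    iu <- mot@iupac
    m <- nchar(iu)
    fw <- .iupacScanStarts(chars, iu)
    if (length(fw))
      out[[length(out) + 1L]] <- data.frame(start = fw, end = fw + m - 1L,
                                            strand = "+", motif = mot@name)
    if (!isPalindromic(iu)) {
      rv <- .iupacScanStarts(chars, revcompIupac(iu))
      if (length(rv))
        out[[length(out) + 1L]] <- data.frame(start = rv, end = rv + m - 1L,
                                              strand = "-", motif = mot@name)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), motif = character()))
  df <- do.call(rbind, out)
  df[order(df$start, df$motif, df$strand), , drop = FALSE]
}

## Matches in `chars` that are absent (same motif/start/strand) in `ref`.
.newMatches <- function(chars, refChars, motifs) {
  cur <- .allMatches(chars, motifs)
  ref <- .allMatches(refChars, motifs)
  key <- function(df) paste(df$motif, df$start, df$strand)
  cur[!key(cur) %in% key(ref), , drop = FALSE]
}

.protectList <- function(protect, targets = list()) {
  if (is.null(protect)) return(list())
  protect <- lapply(protect, .asMotif)
  tIu <- vapply(targets, function(m) m@iupac, character(1))
  protect[!vapply(protect, function(m) m@iupac %in% tIu, logical(1))]
}

## Codon bookkeeping: codon i (1-based) covers positions
## frame + 3(i-1) + 1 ... frame + 3i.
.codonStarts <- function(L, frame) {
  n <- (L - frame) %/% 3L
  if (n < 1L) integer() else frame + 3L * (seq_len(n) - 1L) + 1L
}

.codonAt <- function(chars, starts, i)
  paste(chars[starts[i]:(starts[i] + 2L)], collapse = "")

## ---- scrub recoding ----------------------------------------------------

#' Scrub-recode a coding sequence to defeat every possible recognition site
#'
#' Silently mutates a coding sequence so that every window of
#' \code{k} nucleotides contains at least one substitution (equivalently,
#' the longest run of consecutive unaltered nucleotides is at most
#' \code{k - 1}), defeating any unknown recognition sequence of length
#' \code{k} or more while preserving the encoded protein.  Among feasible
#' plans the recoder alters as many nucleotides as possible (the point of a
#' scrub is maximal divergence from the restricted parent), preferring
#' higher-usage synonymous codons and breaking remaining ties with a seeded
#' RNG.  No motif in \code{protect} gains a new match.
#'
#' @param cds coding sequence (string or DNAString).
#' @param k minimal defeated site length (>= 2; default 6, since most RM
#'   recognition sequences are at least 6 bp).
#' @param codonUsage optional named numeric vector of codon weights used as
#'   a preference among synonymous choices (default uniform).
#' @param protect list of \linkS4class{DegenerateMotif} that must not gain
#'   a new match (default: the built-in registry, so recoding never
#'   introduces a known restriction site).
#' @param seed integer seed for tie-breaking.
#' @param frame 0-based offset of the first complete codon; positions
#'   outside complete codons are immutable but still count toward runs.
#' @return a \linkS4class{RecodePlan} with
#'   \code{\link{maxUnalteredRun}} <= \code{k - 1}.
#' @export
scrubRecode <- function(cds, k = 6L, codonUsage = NULL,
                        protect = motifRegistry(), seed = 1L, frame = 0L) {
  cds <- .asCdsString(cds)
  if (k < 2L) stop("'k' must be >= 2")
  chars <- .splitChars(cds)
  L <- length(chars)
  starts <- .codonStarts(L, frame)
  if (!length(starts)) stop("no complete codon in frame")
  tail <- L - (starts[length(starts)] + 2L)
  if (frame >= k || tail >= k)
    stop("immutable head/tail of length >= k")
  nCod <- length(starts)
  usage <- Biostrings::GENETIC_CODE
  uw <- setNames(rep(1, length(usage)), names(usage))
  if (!is.null(codonUsage)) uw[names(codonUsage)] <- codonUsage
  ## per-codon options and change patterns
  opts <- vector("list", nCod)
  for (i in seq_len(nCod)) {
    orig <- .codonAt(chars, starts, i)
    cand <- c(orig, synonymousOptions(orig))
    opts[[i]] <- lapply(cand, function(cd) {
      p <- .splitChars(cd) != .splitChars(orig)
      list(codon = cd, pattern = p, nAlt = sum(p), usage = uw[[cd]])
    })
  }
  withSeed(seed, {
    ## DP over trailing-run states 0..k-1; value = (nAlt, usage),
    ## lexicographic max; exact ties resolved by seeded coin flip.
    NEG <- -Inf
    val <- matrix(NEG, nrow = k, ncol = 2L)       # row r+1 = run length r
    bk <- vector("list", nCod)
    r0 <- frame
    val[r0 + 1L, ] <- c(0, 0)
    for (i in seq_len(nCod)) {
      nv <- matrix(NEG, nrow = k, ncol = 2L)
      nb <- matrix(NA_integer_, nrow = k, ncol = 2L)  # prev state, option
      for (r in 0:(k - 1L)) {
        if (val[r + 1L, 1L] == NEG) next
        for (oi in seq_along(opts[[i]])) {
          o <- opts[[i]][[oi]]
          rr <- r
          ok <- TRUE
          for (pp in o$pattern) {
            if (pp) rr <- 0L else {
              rr <- rr + 1L
              if (rr >= k) { ok <- FALSE; break }
            }
          }
          if (!ok) next
          v1 <- val[r + 1L, 1L] + o$nAlt
          v2 <- val[r + 1L, 2L] + o$usage
          better <- v1 > nv[rr + 1L, 1L] ||
            (v1 == nv[rr + 1L, 1L] && v2 > nv[rr + 1L, 2L])
          tie <- v1 == nv[rr + 1L, 1L] && v2 == nv[rr + 1L, 2L]
          if (better || (tie && runif(1) < 0.5)) {
            nv[rr + 1L, ] <- c(v1, v2)
            nb[rr + 1L, ] <- c(r, oi)
          }
        }
      }
      val <- nv
      bk[[i]] <- nb
    }
    final <- which(val[, 1L] > NEG & (seq_len(k) - 1L) + tail <= k - 1L)
    if (!length(final)) {
      ## locate an offending stretch: consecutive codons without
      ## synonymous options spanning >= k nucleotides
      fixed <- vapply(seq_len(nCod), function(i) length(opts[[i]]) == 1L,
                      logical(1))
      r <- rle(fixed)
      ends <- cumsum(r$lengths)
      iv <- which(r$values & r$lengths * 3L >= k)
      if (length(iv)) {
        i2 <- ends[iv[1L]]
        i1 <- i2 - r$lengths[iv[1L]] + 1L
        stop(sprintf(
          "scrub infeasible: positions [%d,%d] are a run of codons without synonymous options longer than k-1 = %d",
          starts[i1], starts[i2] + 2L, k - 1L))
      }
      stop("scrub infeasible: no substitution pattern keeps every ",
           k, "-nt window altered")
    }
    best <- final[order(-val[final, 1L], -val[final, 2L])][1L]
    ## backtrack
    choice <- integer(nCod)
    st <- best - 1L
    for (i in rev(seq_len(nCod))) {
      choice[i] <- bk[[i]][st + 1L, 2L]
      st <- bk[[i]][st + 1L, 1L]
    }
    out <- chars
    for (i in seq_len(nCod))
      out[starts[i]:(starts[i] + 2L)] <-
        .splitChars(opts[[i]][[choice[i]]]$codon)
    ## repair pass: undo any newly created protected site by re-optioning
    ## an overlapping codon (run bound and translation re-verified)
    prot <- .protectList(protect)
    if (length(prot)) {
      for (iter in seq_len(25L)) {
        nm <- .newMatches(out, chars, prot)
        if (!nrow(nm)) break
        s <- nm$start[1L]; e <- nm$end[1L]
        codIdx <- which(starts + 2L >= s & starts <= e)
        fixed <- FALSE
        for (ci in codIdx) {
          for (oi in seq_along(opts[[ci]])) {
            if (oi == choice[ci]) next
            trial <- out
            trial[starts[ci]:(starts[ci] + 2L)] <-
              .splitChars(opts[[ci]][[oi]]$codon)
            same <- .splitChars(cds) == trial
            runOk <- !any(rle(same)$lengths[rle(same)$values] >= k)
            if (all(!same)) runOk <- TRUE
            if (!runOk) next
            if (nrow(.newMatches(trial, chars, prot)) < nrow(nm)) {
              out <- trial
              choice[ci] <- oi
              fixed <- TRUE
              break
            }
          }
          if (fixed) break
        }
        if (!fixed)
          stop("scrub cannot avoid creating a protected site at [",
               s, ",", e, "]")
      }
      if (nrow(.newMatches(out, chars, prot)))
        stop("scrub cannot avoid creating protected sites")
    }
    .mkPlan(cds, paste(out, collapse = ""), frame = frame, coding = TRUE)
  })
}

## ---- site ablation -----------------------------------------------------

#' Ablate recognition sites with a minimal number of silent substitutions
#'
#' Removes every (both-strand) match of the target motifs from a coding
#' sequence using synonymous substitutions only.  For each site, all
#' combinations of synonymous codons overlapping the site are enumerated in
#' order of increasing substitution count, so the per-site edit is minimal;
#' no protected motif gains a new match.
#'
#' @inheritParams scrubRecode
#' @param motifs list of target \linkS4class{DegenerateMotif} (or IUPAC
#'   strings) whose matches must be removed.
#' @param protect motifs that must not gain a new match (default: built-in
#'   registry minus the targets).
#' @return a \linkS4class{RecodePlan}; the identity plan when the sequence
#'   contains no target match.
#' @examples
#' killSites("GCAAGTTATGCTCCA", list(motifRegistry()$CpaAII))
#' @export
killSites <- function(cds, motifs, protect = motifRegistry(), frame = 0L,
                      codonUsage = NULL, seed = 1L) {
  cds <- .asCdsString(cds)
  motifs <- lapply(motifs, .asMotif)
  prot <- .protectList(protect, motifs)
  chars0 <- .splitChars(cds)
  L <- length(chars0)
  starts <- .codonStarts(L, frame)
  usage <- setNames(rep(1, length(Biostrings::GENETIC_CODE)),
                    names(Biostrings::GENETIC_CODE))
  if (!is.null(codonUsage)) usage[names(codonUsage)] <- codonUsage
  out <- chars0
  withSeed(seed, {
    for (sweep in seq_len(50L)) {
      mt <- .allMatches(out, motifs)
      if (!nrow(mt)) break
      s <- mt$start[1L]; e <- mt$end[1L]
      codIdx <- which(starts + 2L >= s & starts <= e)
      if (!length(codIdx))
        stop("cannot ablate site [", s, ",", e,
             "]: no codon overlaps it in frame")
      optList <- lapply(codIdx, function(ci) {
        orig <- .codonAt(out, starts, ci)
        c(orig, synonymousOptions(orig))
      })
      grid <- expand.grid(lapply(optList, seq_along), KEEP.OUT.ATTRS = FALSE)
      cost <- numeric(nrow(grid))
      uscore <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        cst <- 0L; us <- 0
        for (j in seq_along(codIdx)) {
          cd <- optList[[j]][[grid[g, j]]]
          cst <- cst + sum(.splitChars(cd) !=
                             out[starts[codIdx[j]]:(starts[codIdx[j]] + 2L)])
          us <- us + usage[[cd]]
        }
        cost[g] <- cst; uscore[g] <- us
      }
      ord <- order(cost, -uscore, seq_len(nrow(grid)))
      done <- FALSE
      for (g in ord) {
        if (cost[g] == 0L) next
        trial <- out
        for (j in seq_along(codIdx))
          trial[starts[codIdx[j]]:(starts[codIdx[j]] + 2L)] <-
            .splitChars(optList[[j]][[grid[g, j]]])
        mt2 <- .allMatches(trial, motifs)
        stillThere <- any(mt2$start <= e & mt2$end >= s)
        if (stillThere || nrow(mt2) > nrow(mt) - 1L) next
        if (length(prot) && nrow(.newMatches(trial, chars0, prot))) next
        out <- trial
        done <- TRUE
        break
      }
      if (!done)
        stop("cannot ablate site [", s, ",", e, "] of motif ", mt$motif[1L],
             ": no synonymous edit removes it",
             if (length(prot)) " without creating a protected site" else "")
    }
    if (nrow(.allMatches(out, motifs)))
      stop("site ablation did not converge")
    .mkPlan(cds, paste(out, collapse = ""), frame = frame, coding = TRUE)
  })
}

## ---- site creation -----------------------------------------------------

#' Introduce a recognition site with a minimal number of substitutions
#'
#' Finds the placement (all alignment offsets, both strands) where the
#' motif can be written into the sequence with the fewest substitutions and
#' applies it.  When \code{frame} is supplied the sequence is treated as
#' coding and all substitutions must be synonymous.
#'
#' @param seq sequence (string or DNAString).
#' @param motif \linkS4class{DegenerateMotif} or IUPAC string.
#' @param frame NULL for unconstrained editing, else the 0-based offset of
#'   the first complete codon (synonymous substitutions only).
#' @return a \linkS4class{RecodePlan} (zero substitutions when the motif is
#'   already present).
#' @examples
#' createSite("AACGAGATCTCC", "AAGNNNNNCTCC")  # one substitution
#' @export
createSite <- function(seq, motif, frame = NULL) {
  seq <- .asCdsString(seq)
  motif <- .asMotif(motif)
  chars <- .splitChars(seq)
  L <- length(chars)
  m <- nchar(motif@iupac)
  if (m > L) stop("motif is longer than the sequence")
  ## already present?
  if (nrow(.allMatches(chars, list(motif))))
    return(.mkPlan(seq, seq, frame = if (is.null(frame)) 0L else frame,
                   coding = !is.null(frame)))
  pats <- list(`+` = motif@iupac)
  if (!isPalindromic(motif@iupac)) pats[["-"]] <- revcompIupac(motif@iupac)
  best <- NULL
  for (st in names(pats)) {
    sets <- IUPAC_SETS[.splitChars(pats[[st]])]
    for (o in seq_len(L - m + 1L)) {
      win <- o:(o + m - 1L)
      if (is.null(frame)) {
        mism <- which(!mapply(function(b, s) b %in% s, chars[win], sets))
        cost <- length(mism)
        if (is.null(best) || cost < best$cost) {
          trial <- chars
          trial[win[mism]] <- vapply(sets[mism], function(s) sort(s)[1L],
                                     character(1))
          best <- list(cost = cost, out = trial)
        }
      } else {
        starts <- .codonStarts(L, frame)
        codIdx <- which(starts + 2L >= o & starts <= o + m - 1L)
        covered <- unlist(lapply(codIdx, function(ci)
          starts[ci]:(starts[ci] + 2L)))
        fixedPos <- setdiff(win, covered)
        if (any(!mapply(function(b, s) b %in% s,
                        chars[fixedPos], sets[match(fixedPos, win)])))
          next  # immutable positions conflict with the motif here
        optList <- lapply(codIdx, function(ci) {
          orig <- .codonAt(chars, starts, ci)
          c(orig, synonymousOptions(orig))
        })
        grid <- expand.grid(lapply(optList, seq_along),
                            KEEP.OUT.ATTRS = FALSE)
        for (g in seq_len(nrow(grid))) {
          trial <- chars
          for (j in seq_along(codIdx))
            trial[starts[codIdx[j]]:(starts[codIdx[j]] + 2L)] <-
              .splitChars(optList[[j]][[grid[g, j]]])
          if (!all(mapply(function(b, s) b %in% s, trial[win], sets))) next
          cost <- sum(trial != chars)
          if (is.null(best) || cost < best$cost)
            best <- list(cost = cost, out = trial)
        }
      }
      if (!is.null(best) && best$cost == 0L) break
    }
  }
  if (is.null(best))
    stop("coding constraint makes every placement of motif '",
         motif@name, "' infeasible")
  .mkPlan(seq, paste(best$out, collapse = ""),
          frame = if (is.null(frame)) 0L else frame,
          coding = !is.null(frame))
}
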