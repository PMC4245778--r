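## Seeded generators: genomes with planted motif occurrences, SMRT-style
## m6A call sets, coding sequences, and construct panels.

#' Simulate a genome with planted occurrences of a degenerate motif
#'
#' Draws a random genome at a given GC content and overwrites
#' \code{nPlanted} non-overlapping windows with concrete realizations of the
#' motif (random strand, degenerate positions sampled uniformly).  The
#' returned occurrence list is obtained by re-scanning the finished genome,
#' so it reports every occurrence --- planted or arising by chance --- and
#' every reported interval matches the motif.
#'
#' @param genomeLength genome size in bp (>= 10 x motif length).
#' @param motif a \linkS4class{DegenerateMotif}.
#' @param nPlanted number of forced occurrences.
#' @param gcFraction genome GC content (default 0.3, AT-rich as typical for
#'   clostridial genomes).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param id name for the generated sequence.
#' @return list with elements \code{genome} (a named
#'   \link[Biostrings]{DNAStringSet} of length 1), \code{occurrences} (a
#'   \link[GenomicRanges]{GRanges} from \code{\link{scanMotif}}) and
#'   \code{planted} (the forced \link[GenomicRanges]{GRanges}).
#' @export
simulateGenome <- function(genomeLength, motif, nPlanted = 0L,
                           gcFraction = 0.3, seed = 1L, id = "simgenome") {
  motif <- .asMotif(motif)
  m <- nchar(motif@iupac)
  if (m > genomeLength)
    stop("motif is longer than the genome")
  if (genomeLength < 10L * m)
    stop("'genomeLength' must be at least 10 x motif length")
  if (gcFraction < 0 || gcFraction > 1)
    stop("'gcFraction' must lie in [0, 1]")
  withSeed(seed, {
    p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
           G = gcFraction / 2, T = (1 - gcFraction) / 2)
    chars <- sample(names(p), genomeLength, replace = TRUE, prob = p)
    starts <- integer()
    strands <- character()
    if (nPlanted > 0L) {
      ## non-overlapping placement by rejection
      avail <- seq_len(genomeLength - m + 1L)
      tries <- 0L
      while (length(starts) < nPlanted) {
        tries <- tries + 1L
        if (tries > 200L * nPlanted)
          stop("could not place ", nPlanted, " non-overlapping occurrences")
        s <- sample(avail, 1L)
        if (!length(starts) || all(abs(s - starts) >= m)) {
          starts <- c(starts, s)
          strands <- c(strands, sample(c("+", "-"), 1L))
        }
      }
      ord <- order(starts)
      starts <- starts[ord]; strands <- strands[ord]
      pc <- strsplit(motif@iupac, "")[[1]]
      for (i in seq_along(starts)) {
        word <- vapply(pc, function(ch) {
          set <- IUPAC_SETS[[ch]]
          if (length(set) == 1L) set else sample(set, 1L)
        }, character(1))
        if (strands[i] == "-")
          word <- rev(chartr(.IUPAC_FROM, .IUPAC_TO, word))
        chars[starts[i]:(starts[i] + m - 1L)] <- word
      }
    }
    genome <- DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- id
    planted <- if (length(starts))
      GRanges(id, IRanges(start = starts, width = m), strand = strands)
    else GRanges()
    list(genome = genome,
         occurrences = scanMotif(genome, motif, "both"),
         planted = planted)
  })
}

## Map a motif's methyl offsets onto genomic (position, strand) pairs for a
## set of occurrences.  occStart/occStrand are parallel vectors; returns a
## data.frame with one row per (occurrence, offset).
.methylPositions <- function(occStart, occStrand, motifLength, methylOffsets) {
  if (!nrow(methylOffsets))
    return(data.frame(occ = integer(), pos = integer(), strand = character()))
  out <- lapply(seq_len(nrow(methylOffsets)), function(k) {
    off <- methylOffsets$offset[k]
    ostr <- methylOffsets$strand[k]
    plus <- occStrand == "+"
    pos <- ifelse(plus, occStart + off - 1L,
                  occStart + motifLength - off)      # mirrored on '-'
    strand <- ifelse(plus, ostr, ifelse(ostr == "+", "-", "+"))
    data.frame(occ = seq_along(occStart), pos = as.integer(pos),
               strand = strand)
  })
  do.call(rbind, out)
}

#' Simulate SMRT-style m6A position calls for a methylated genome
#'
#' Every methylatable adenine dictated by the motif's methyl offsets (both
#' strands, every occurrence) is called with probability
#' \code{detectionProb}; background false-positive calls are added at rate
#' \code{fpRate} per bp, placed on randomly chosen adenines (strand-aware)
#' not already called.  Detection is coupled across runs: with a fixed seed,
#' lowering \code{detectionProb} can only remove true calls, never add or
#' exchange them.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} of length 1 (or
#'   DNAString / character).
#' @param occurrences \link[GenomicRanges]{GRanges} of motif occurrences
#'   (e.g. from \code{\link{simulateGenome}}).
#' @param motif the planted \linkS4class{DegenerateMotif}; must carry
#'   methyl offsets.
#' @param detectionProb per-adenine call probability in [0, 1].
#' @param fpRate background false calls per bp (>= 0).
#' @param seed integer seed.
#' @param scoreRange range of fake call confidence scores.
#' @return \link[GenomicRanges]{GRanges} of width-1, strand-specific calls
#'   with a \code{score} metadata column, sorted by position.
#' @export
simulateMethylome <- function(genome, occurrences, motif,
                              detectionProb = 0.95, fpRate = 0, seed = 1L,
                              scoreRange = c(30L, 200L)) {
  genome <- .asSubject(genome)
  motif <- .asMotif(motif)
  if (!nrow(motif@methylOffsets))
    stop("motif '", motif@name, "' has no methyl offsets; cannot simulate ",
         "a methylome from it")
  if (detectionProb < 0 || detectionProb > 1)
    stop("'detectionProb' must lie in [0, 1]")
  if (fpRate < 0) stop("'fpRate' must be >= 0")
  L <- Biostrings::width(genome)[1L]
  id <- names(genome)[1L]
  if (length(occurrences) &&
      (min(GenomicRanges::start(occurrences)) < 1L ||
       max(GenomicRanges::end(occurrences)) > L))
    stop("occurrences lie outside the genome")
  mp <- .methylPositions(GenomicRanges::start(occurrences),
                         as.character(GenomicRanges::strand(occurrences)),
                         nchar(motif@iupac), motif@methylOffsets)
  ## deterministic site order for detection coupling
  mp <- unique(mp[order(mp$pos, mp$strand), c("pos", "strand")])
  withSeed(seed, {
    u <- if (nrow(mp)) runif(nrow(mp)) else numeric()
    called <- mp[u < detectionProb, , drop = FALSE]
    nFp <- rpois(1L, fpRate * L)
    fp <- NULL
    if (nFp > 0L) {
      chars <- strsplit(as.character(genome[[1L]]), "")[[1]]
      aPlus <- which(chars == "A")
      aMinus <- which(chars == "T")
      pool <- data.frame(
        pos = c(aPlus, aMinus),
        strand = rep(c("+", "-"), c(length(aPlus), length(aMinus))))
      ## background noise is off-motif: exclude every methylatable site
      pool <- pool[!paste(pool$pos, pool$strand) %in%
                     paste(mp$pos, mp$strand), , drop = FALSE]
      nFp <- min(nFp, nrow(pool))
      fp <- pool[sample.int(nrow(pool), nFp), , drop = FALSE]
    }
    calls <- rbind(called, fp)
    calls <- calls[order(calls$pos, calls$strand), , drop = FALSE]
    score <- if (nrow(calls))
      as.numeric(sample(scoreRange[1L]:scoreRange[2L], nrow(calls),
                        replace = TRUE))
    else numeric()
    GRanges(rep(id, nrow(calls)),
            IRanges(start = calls$pos, width = rep(1L, nrow(calls))),
            strand = calls$strand, score = score,
            seqlengths = setNames(L, id))
  })
}

#' Simulate a deletion-derivative transformability panel
#'
#' Emulates the deletion-mapping experiment: a parent vector carries one
#' contiguous restriction-sensitive region; derivatives that fully retain it
#' are attenuated by \code{attenuation}-fold relative to the control, all
#' others transform at control level.  Multiplicative log-normal noise of
#' \code{noiseDex} decades is applied to test constructs.
#'
#' @param parentLength parent coordinate system length (bp).
#' @param trueRegion length-2 integer vector \code{c(start, end)} (1-based,
#'   inclusive) of the restriction-sensitive region.
#' @param retained named list; one element per test construct giving its
#'   retained intervals as a 2-column matrix / data.frame of
#'   \code{start, end} pairs (1-based, inclusive) or an
#'   \link[IRanges]{IRanges}.
#' @param controlEfficiency control transformation efficiency
#'   (transformants per microgram).
#' @param attenuation fold-reduction applied when the region is fully
#'   retained (> 1).
#' @param noiseDex sd of log10 multiplicative noise (0 = noise-free).
#' @param seed integer seed.
#' @param controlId id given to the synthetic control construct.
#' @return a \linkS4class{TransformabilityPanel}.
#' @export
simulatePanel <- function(parentLength, trueRegion, retained,
                          controlEfficiency = 3.7e4, attenuation = 1e4,
                          noiseDex = 0, seed = 1L, controlId = "control") {
  if (!length(retained)) stop("empty construct list")
  if (attenuation <= 1) stop("'attenuation' must be > 1")
  region <- IRanges(start = trueRegion[1L], end = trueRegion[2L])
  if (IRanges::start(region) < 1L || IRanges::end(region) > parentLength)
    stop("'trueRegion' must lie within the parent")
  if (is.null(names(retained)))
    names(retained) <- paste0("construct", seq_along(retained))
  withSeed(seed, {
    ## the control is the unmodified backbone: it carries none of the
    ## studied parent region
    constructs <- list(construct(controlId, IRanges(),
                                 efficiency = controlEfficiency,
                                 role = "control"))
    for (nm in names(retained)) {
      ir <- .asRetained(retained[[nm]])
      covered <- sum(IRanges::width(IRanges::intersect(ir, region)))
      restricted <- covered == IRanges::width(region)
      eff <- if (restricted) controlEfficiency / attenuation
             else controlEfficiency
      if (noiseDex > 0) eff <- eff * 10^rnorm(1L, 0, noiseDex)
      constructs[[length(constructs) + 1L]] <-
        construct(nm, ir, efficiency = eff, role = "test",
                  control = controlId)
    }
    transformabilityPanel(parentLength, constructs)
  })
}

#' Generate a random coding sequence
#'
#' Samples \code{nCodons} sense codons from a codon-usage table (uniform
#' over the 61 sense codons by default), so the result is translatable with
#' no internal stop codons.
#'
#' @param nCodons number of codons (>= 1).
#' @param codonUsage named numeric vector of codon weights; stop codons and
#'   zero-weight codons are excluded.  Default: uniform.
#' @param seed integer seed.
#' @return a coding sequence as a single character string of length
#'   \code{3 * nCodons}.
#' @export
randomCds <- function(nCodons, codonUsage = NULL, seed = 1L) {
  if (nCodons < 1L) stop("'nCodons' must be >= 1")
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  if (is.null(codonUsage)) codonUsage <- setNames(rep(1, length(sense)), sense)
  codonUsage <- codonUsage[names(codonUsage) %in% sense & codonUsage > 0]
  if (!length(codonUsage))
    stop("degenerate codon usage table: no sense codon has positive weight")
  withSeed(seed, {
    paste(sample(names(codonUsage), nCodons, replace = TRUE,
                 prob = codonUsage), collapse = "")
  })
}
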