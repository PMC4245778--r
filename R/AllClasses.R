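## S4 classes for the central data objects.

#' DegenerateMotif: an IUPAC-encoded recognition sequence
#'
#' Represents a restriction/modification recognition sequence over the
#' 15-letter IUPAC nucleotide alphabet, optionally annotated with the
#' positions of methylated adenines on each strand.  A bipartite Type I
#' motif such as CpaAII (5'-AAGNNNNNCTCC-3') is encoded with its spacer as
#' N's; methylation offsets are 1-based positions within the motif, with
#' strand \code{"+"} marking an adenine on the written strand and \code{"-"}
#' an adenine on the complementary strand (i.e. a T at that position of the
#' written strand).
#'
#' @slot name character label (e.g. \code{"CpaAII"}).
#' @slot iupac recognition sequence over the IUPAC alphabet.
#' @slot methylOffsets data.frame with columns \code{offset} (1-based
#'   position within the motif) and \code{strand} (\code{"+"}/\code{"-"});
#'   zero rows when the methylated positions are unknown or not m6A.
#'
#' @seealso [degenerateMotif()], [motifRegistry()], [scanMotif()]
#' @export
setClass("DegenerateMotif",
  representation(name = "character", iupac = "character",
                 methylOffsets = "data.frame"))

setValidity("DegenerateMotif", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single string")
  if (length(object@iupac) != 1L || is.na(object@iupac) ||
      nchar(object@iupac) < 1L)
    msg <- c(msg, "'iupac' must be a non-empty string")
  else {
    bad <- setdiff(strsplit(object@iupac, "")[[1]], names(IUPAC_SETS))
    if (length(bad))
      msg <- c(msg, paste0("invalid IUPAC character(s): ",
                           paste(unique(bad), collapse = ", ")))
  }
  mo <- object@methylOffsets
  if (!all(c("offset", "strand") %in% names(mo)))
    msg <- c(msg, "'methylOffsets' needs columns 'offset' and 'strand'")
  else if (nrow(mo)) {
    if (!all(mo$strand %in% c("+", "-")))
      msg <- c(msg, "methylOffsets$strand must be '+' or '-'")
    if (!all(mo$offset >= 1L & mo$offset <= nchar(object@iupac)))
      msg <- c(msg, "methylOffsets$offset out of motif bounds")
    else {
      chars <- strsplit(object@iupac, "")[[1]]
      for (i in seq_len(nrow(mo))) {
        set <- IUPAC_SETS[[chars[mo$offset[i]]]]
        need <- if (mo$strand[i] == "+") "A" else "T"
        if (!need %in% set)
          msg <- c(msg, sprintf(
            "methyl offset %d (%s) points at IUPAC code '%s' which cannot be %s",
            mo$offset[i], mo$strand[i], chars[mo$offset[i]],
            if (need == "A") "an adenine on the top strand"
            else "an adenine on the bottom strand"))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' MotifCandidate: a bipartite motif hypothesis with support scores
#'
#' A candidate recognition motif decomposed as a defined left block, a fully
#' degenerate spacer of N's and an optional defined right block, together
#' with the methylated-position offsets inferred from the data and the
#' scores measuring how well it explains a set of m6A calls: sensitivity
#' (fraction of calls falling at a methylatable position of some genomic
#' occurrence), specificity (fraction of genomic occurrences carrying at
#' least one supporting call) and their harmonic mean (F-measure).
#'
#' @slot left defined 5' block (IUPAC, no N).
#' @slot spacer number of N positions between the blocks.
#' @slot right defined 3' block (IUPAC, no N; may be empty).
#' @slot methylOffsets data.frame(offset, strand) as for
#'   \linkS4class{DegenerateMotif}; inferred during scoring.
#' @slot sensitivity,specificity,score numeric in [0, 1]; NA before scoring.
#' @slot nOccurrences,nSupported,nCallsExplained integer support counts.
#' @slot note character; non-empty when the candidate was discarded
#'   (e.g. no genomic occurrence).
#' @seealso [discoverMotif()], [scoreCandidate()]
#' @export
setClass("MotifCandidate",
  representation(left = "character", spacer = "integer", right = "character",
                 methylOffsets = "data.frame",
                 sensitivity = "numeric", specificity = "numeric",
                 score = "numeric", nOccurrences = "integer",
                 nSupported = "integer", nCallsExplained = "integer",
                 note = "character"))

setValidity("MotifCandidate", function(object) {
  msg <- character()
  if (nchar(object@left) < 1L) msg <- c(msg, "'left' block must be non-empty")
  if (grepl("N", object@left) || grepl("N", object@right))
    msg <- c(msg, "defined blocks must not contain N")
  if (object@spacer < 0L) msg <- c(msg, "'spacer' must be >= 0")
  for (s in c("sensitivity", "specificity", "score")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, paste0("'", s, "' must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' MotifDiscovery: ranked result of motif inference from m6A calls
#'
#' @slot candidates list of scored \linkS4class{MotifCandidate}, ranked.
#' @slot table data.frame summary (one row per candidate, ranked).
#' @slot confident TRUE when the top score reaches the reporting threshold.
#' @slot scoreThreshold the threshold used.
#' @slot dropped data.frame of discarded candidates and reasons.
#' @seealso [discoverMotif()]
#' @export
setClass("MotifDiscovery",
  representation(candidates = "list", table = "data.frame",
                 confident = "logical", scoreThreshold = "numeric",
                 dropped = "data.frame"))

#' RecodePlan: an ordered set of translation-preserving substitutions
#'
#' The result of the recoding operations: the input sequence, the recoded
#' output, and the list of single-nucleotide substitutions that transforms
#' one into the other.  For coding plans the translation of the output is
#' guaranteed equal to the translation of the input over the in-frame span.
#'
#' @slot input,output DNA sequences as plain strings (A/C/G/T).
#' @slot substitutions data.frame with columns \code{pos} (1-based),
#'   \code{from}, \code{to}; every row is a real change.
#' @slot frame 0-based offset of the first complete codon (coding plans).
#' @slot coding logical; TRUE when the plan is constrained to be synonymous.
#' @seealso [recodePlan()], [scrubRecode()], [killSites()], [createSite()]
#' @export
setClass("RecodePlan",
  representation(input = "character", output = "character",
                 substitutions = "data.frame", frame = "integer",
                 coding = "logical"))

setValidity("RecodePlan", function(object) {
  msg <- character()
  inp <- strsplit(object@input, "")[[1]]
  out <- strsplit(object@output, "")[[1]]
  if (length(inp) != length(out))
    return("input and output must have equal length")
  sub <- object@substitutions
  if (!all(c("pos", "from", "to") %in% names(sub)))
    return("substitutions needs columns pos/from/to")
  if (nrow(sub)) {
    if (any(sub$from == sub$to))
      msg <- c(msg, "every substitution must be a real change (from != to)")
    if (any(sub$pos < 1L | sub$pos > length(inp)))
      msg <- c(msg, "substitution position out of bounds")
    else {
      if (!all(inp[sub$pos] == sub$from))
        msg <- c(msg, "'from' bases disagree with the input sequence")
      if (!all(out[sub$pos] == sub$to))
        msg <- c(msg, "'to' bases disagree with the output sequence")
    }
  }
  changed <- which(inp != out)
  if (!setequal(changed, sub$pos))
    msg <- c(msg, "substitution list does not account for all changed positions")
  if (isTRUE(object@coding)) {
    f <- object@frame
    n <- length(inp)
    span <- f + 3L * ((n - f) %/% 3L)
    if (span >= f + 3L) {
      tin <- .translateString(substr(object@input, f + 1L, span))
      tout <- .translateString(substr(object@output, f + 1L, span))
      if (tin != tout)
        msg <- c(msg, "coding plan does not preserve translation")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct: a deletion derivative with a measured transformation efficiency
#'
#' Describes a plasmid derivative by the intervals of the parent coordinate
#' system it retains, together with its measured electrotransformation
#' efficiency (transformants per microgram of plasmid DNA).  An efficiency
#' of 0 encodes "no transformants detected"; NA encodes missing data.
#'
#' @slot id construct label.
#' @slot retained disjoint, sorted \link[IRanges]{IRanges} on the parent
#'   coordinate system (1-based).
#' @slot efficiency transformants per microgram (>= 0, 0 = not detected).
#' @slot role \code{"test"} or \code{"control"}.
#' @slot control id of the construct's stated control (NA = panel default).
#' @seealso [construct()], [transformabilityPanel()], [localizeRegion()]
#' @export
setClass("Construct",
  representation(id = "character", retained = "IRanges",
                 efficiency = "numeric", role = "character",
                 control = "character"))

setValidity("Construct", function(object) {
  msg <- character()
  if (!object@role %in% c("test", "control"))
    msg <- c(msg, "'role' must be 'test' or 'control'")
  r <- object@retained
  if (length(r)) {
    if (is.unsorted(IRanges::start(r)))
      msg <- c(msg, "'retained' intervals must be sorted by start")
    if (length(r) > 1L &&
        any(IRanges::start(r)[-1L] <= IRanges::end(r)[-length(r)]))
      msg <- c(msg, "'retained' intervals must be disjoint")
    if (any(IRanges::start(r) < 1L))
      msg <- c(msg, "'retained' intervals must start at >= 1")
  }
  if (!is.na(object@efficiency) && object@efficiency < 0)
    msg <- c(msg, "'efficiency' must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' TransformabilityPanel: a set of constructs measured on one parent vector
#'
#' @slot parentLength length (bp) of the parent coordinate system.
#' @slot constructs list of \linkS4class{Construct}; at least one control.
#' @seealso [transformabilityPanel()], [simulatePanel()], [localizeRegion()]
#' @export
setClass("TransformabilityPanel",
  representation(parentLength = "integer", constructs = "list"))

setValidity("TransformabilityPanel", function(object) {
  msg <- character()
  if (!length(object@constructs))
    return("panel must contain at least one construct")
  if (!all(vapply(object@constructs, is, logical(1), "Construct")))
    return("all panel members must be Construct objects")
  roles <- vapply(object@constructs, function(x) x@role, character(1))
  if (!any(roles == "control"))
    msg <- c(msg, "panel must contain at least one control construct")
  ids <- vapply(object@constructs, function(x) x@id, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "construct ids must be unique")
  for (x in object@constructs)
    if (length(x@retained) && max(IRanges::end(x@retained)) > object@parentLength)
      msg <- c(msg, paste0("construct '", x@id, "' exceeds parent bounds"))
  if (length(msg)) msg else TRUE
})

#' LocalizationResult: inferred restriction-sensitive region
#'
#' @slot candidate \link[IRanges]{IRanges} of candidate region(s): the
#'   intersection of what all restricted constructs retain, minus everything
#'   any permissive construct retains.
#' @slot consistent FALSE when the panel admits no single-region explanation.
#' @slot phenotypes data.frame of per-construct phenotype calls.
#' @slot witnesses character explanation per construct / inconsistency.
#' @seealso [localizeRegion()]
#' @export
setClass("LocalizationResult",
  representation(candidate = "IRanges", consistent = "logical",
                 phenotypes = "data.frame", witnesses = "character"))
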