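## Degenerate-alphabet core: IUPAC expansion, complement, motif objects.

## Concrete base sets for the 15 IUPAC nucleotide codes, from Biostrings.
IUPAC_SETS <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

## chartr() maps for IUPAC complementation: A<->T, C<->G, R<->Y, K<->M,
## B<->V, D<->H; S, W, N are self-complementary.
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Expand an IUPAC code to its concrete base set
#'
#' @param code a single IUPAC nucleotide letter (e.g. \code{"W"}).
#' @return character vector of concrete bases, e.g. \code{c("A", "T")}.
#' @examples
#' expandIupac("W")  # A or T, as in the Dcm site 5'-CCWGG-3'
#' expandIupac("N")
#' @export
expandIupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("'code' must be a single character")
  set <- IUPAC_SETS[[toupper(code)]]
  if (is.null(set))
    stop("invalid IUPAC nucleotide code: '", code, "'")
  set
}

#' Number of concrete sequences matched by a degenerate motif
#'
#' The product over motif positions of the cardinality of each position's
#' IUPAC base set; e.g. 5'-AAGNNNNNCTCC-3' matches 4^5 = 1024 concrete
#' 12-mers.
#'
#' @param motif a \linkS4class{DegenerateMotif} or IUPAC string.
#' @return integer count.
#' @export
motifCardinality <- function(motif) {
  iu <- if (is(motif, "DegenerateMotif")) motif@iupac else motif
  chars <- strsplit(toupper(iu), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC nucleotide code: '", bad[1L], "'")
  prod(vapply(chars, function(ch) length(IUPAC_SETS[[ch]]), numeric(1)))
}

#' Reverse complement of an IUPAC string
#'
#' Complementation respects degenerate pairing (N<->N, W<->W, R<->Y, ...);
#' applying the function twice returns the input.
#'
#' @param x IUPAC string.
#' @return the reverse-complemented IUPAC string.
#' @examples
#' revcompIupac("AAGNNNNNCTCC")  # GGAGNNNNNCTT
#' @export
revcompIupac <- function(x) {
  if (!is.character(x) || length(x) != 1L)
    stop("'x' must be a single string")
  x <- toupper(x)
  bad <- setdiff(strsplit(x, "")[[1]], names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC nucleotide code: '", bad[1L], "'")
  paste(rev(strsplit(chartr(.IUPAC_FROM, .IUPAC_TO, x), "")[[1]]),
        collapse = "")
}

#' Is a motif palindromic at the IUPAC level?
#'
#' A motif equal to its own reverse complement (e.g. CGCG, GATC, CCWGG)
#' occurs identically on both strands; scanning reports one match per locus.
#'
#' @param motif a \linkS4class{DegenerateMotif} or IUPAC string.
#' @return logical.
#' @export
isPalindromic <- function(motif) {
  iu <- toupper(if (is(motif, "DegenerateMotif")) motif@iupac else motif)
  identical(iu, revcompIupac(iu))
}

#' Create a DegenerateMotif
#'
#' @param name motif label.
#' @param iupac recognition sequence over the IUPAC alphabet.
#' @param methylOffsets NULL, or a data.frame with columns \code{offset}
#'   (1-based position within the motif) and \code{strand}
#'   (\code{"+"}/\code{"-"}) marking methylated adenines.
#' @return a \linkS4class{DegenerateMotif}.
#' @examples
#' degenerateMotif("CpaAII", "AAGNNNNNCTCC",
#'                 data.frame(offset = c(2L, 10L), strand = c("+", "-")))
#' @export
degenerateMotif <- function(name, iupac, methylOffsets = NULL) {
  if (is.null(methylOffsets))
    methylOffsets <- data.frame(offset = integer(), strand = character())
  methylOffsets$offset <- as.integer(methylOffsets$offset)
  new("DegenerateMotif", name = as.character(name),
      iupac = toupper(as.character(iupac)),
      methylOffsets = methylOffsets[, c("offset", "strand")])
}

#' @describeIn degenerateMotif motif label accessor
#' @param x a DegenerateMotif.
#' @export
motifName <- function(x) x@name

#' @describeIn degenerateMotif IUPAC string accessor
#' @export
iupac <- function(x) x@iupac

#' @describeIn degenerateMotif methylated-position accessor
#' @export
methylOffsets <- function(x) x@methylOffsets

#' @rdname degenerateMotif
#' @aliases reverseComplement,DegenerateMotif-method
#' @param ... ignored.
#' @export
setMethod("reverseComplement", "DegenerateMotif", function(x, ...) {
  L <- nchar(x@iupac)
  mo <- x@methylOffsets
  if (nrow(mo)) {
    mo <- data.frame(offset = L - mo$offset + 1L,
                     strand = ifelse(mo$strand == "+", "-", "+"))
    mo <- mo[order(mo$offset), , drop = FALSE]
    rownames(mo) <- NULL
  }
  degenerateMotif(x@name, revcompIupac(x@iupac), mo)
})

setMethod("show", "DegenerateMotif", function(object) {
  mo <- object@methylOffsets
  moTxt <- if (nrow(mo))
    paste0("; m6A at ", paste0(mo$offset, "(", mo$strand, ")", collapse = ", "))
  else ""
  cat(sprintf("DegenerateMotif '%s': 5'-%s-3' (%d concrete %d-mer%s%s)\n",
              object@name, object@iupac, motifCardinality(object@iupac),
              nchar(object@iupac),
              if (motifCardinality(object@iupac) == 1) "" else "s", moTxt))
})

#' Built-in registry of recognition motifs relevant to C. pasteurianum
#'
#' The host's known restriction-modification recognition sequences plus the
#' E. coli Dcm site relevant to donor-strain methylation:
#' \itemize{
#'   \item CpaAII 5'-AAGNNNNNCTCC-3', the bipartite Type I motif; m6A
#'     offsets default to position 2 on the top strand and the bottom-strand
#'     adenine opposite position 10 --- a modelling choice, as the
#'     methylated positions within the real motif are not published.
#'   \item CpaAI 5'-CGCG-3' (Type II, m5C-protected; no m6A offsets).
#'   \item CpaI 5'-GATC-3' (Type II; Dam-style m6A on both strands).
#'   \item Dcm 5'-CCWGG-3' (E. coli cytosine methyltransferase; no m6A).
#' }
#'
#' @return named list of \linkS4class{DegenerateMotif}.
#' @export
motifRegistry <- function() {
  list(
    CpaAII = degenerateMotif("CpaAII", "AAGNNNNNCTCC",
      data.frame(offset = c(2L, 10L), strand = c("+", "-"))),
    CpaAI = degenerateMotif("CpaAI", "CGCG"),
    CpaI = degenerateMotif("CpaI", "GATC",
      data.frame(offset = c(2L, 3L), strand = c("+", "-"))),
    Dcm = degenerateMotif("Dcm", "CCWGG")
  )
}

#' Read / write motif sets as TSV
#'
#' Columns: \code{name}, \code{iupac}, \code{methyl_offsets} (semicolon
#' separated \code{offset:strand} pairs, e.g. \code{"2:+;10:-"}; empty for
#' none).
#'
#' @param path file path.
#' @return \code{readMotifs}: named list of \linkS4class{DegenerateMotif}.
#' @export
readMotifs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "iupac") %in% names(df)))
    stop("motif TSV needs columns 'name' and 'iupac'")
  out <- lapply(seq_len(nrow(df)), function(i) {
    mo <- NULL
    if ("methyl_offsets" %in% names(df) && nzchar(df$methyl_offsets[i]) &&
        !is.na(df$methyl_offsets[i])) {
      parts <- strsplit(strsplit(df$methyl_offsets[i], ";")[[1]], ":")
      mo <- data.frame(offset = as.integer(vapply(parts, `[`, "", 1L)),
                       strand = vapply(parts, `[`, "", 2L))
    }
    degenerateMotif(df$name[i], df$iupac[i], mo)
  })
  names(out) <- df$name
  out
}

#' @rdname readMotifs
#' @param motifs named list of \linkS4class{DegenerateMotif}.
#' @export
writeMotifs <- function(motifs, path) {
  df <- data.frame(
    name = vapply(motifs, motifName, character(1)),
    iupac = vapply(motifs, iupac, character(1)),
    methyl_offsets = vapply(motifs, function(m) {
      mo <- m@methylOffsets
      if (!nrow(mo)) "" else paste0(mo$offset, ":", mo$strand, collapse = ";")
    }, character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
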