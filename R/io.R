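## Formats: FASTA sequences, m6A calls (GFF3 'modified_base' dialect and
## TSV), construct panels (JSON).
##
## Conventions: in-memory coordinates are 1-based closed (IRanges/GRanges
## native); GFF3 and the calls TSV are 1-based; panel JSON and BED are
## 0-based half-open.

#' Read / write DNA sequences as FASTA
#'
#' Reading normalizes lowercase to uppercase and U to T (published codon
#' changes are often printed as RNA); degenerate characters are rejected
#' with the offending record named, since scan subjects must be concrete.
#' An empty file yields an empty set with a warning.
#'
#' @param path file path.
#' @return \code{readFasta}: a named \link[Biostrings]{DNAStringSet}.
#' @export
readFasta <- function(path) {
  raw <- readBStringSet(path)
  if (!length(raw)) {
    warning("empty FASTA file: ", path)
    return(DNAStringSet())
  }
  txt <- toupper(chartr("Uu", "TT", as.character(raw)))
  bad <- grepl("[^ACGT]", txt)
  if (any(bad))
    stop("record '", names(raw)[bad][1L],
         "' contains degenerate or non-DNA characters")
  out <- DNAStringSet(txt)
  names(out) <- names(raw)
  out
}

#' @rdname readFasta
#' @param x a \link[Biostrings]{DNAStringSet} (or named character vector).
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path)
  invisible(path)
}

#' Read / write m6A position calls
#'
#' Two dialects: GFF3 \code{modified_base} records (1-based column 4;
#' attributes carry \code{modification=m6A}) and a plain TSV with columns
#' \code{seqid}, \code{position} (1-based), \code{strand}, \code{score}.
#' Round trips through either dialect preserve position, strand and score.
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by extension), \code{"gff3"} or
#'   \code{"tsv"}.
#' @return \code{readCalls}: a \link[GenomicRanges]{GRanges} of width-1
#'   calls with a \code{score} column.
#' @export
readCalls <- function(path, dialect = c("auto", "gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
               else "tsv"
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "modified_base"]
    if (any(GenomicRanges::width(gr) != 1L))
      stop("modified_base records must have width 1")
    mcols(gr) <- DataFrame(score = as.numeric(gr$score))
    return(sort(gr))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seqid", "position", "strand", "score")
  if (!all(need %in% names(df)))
    stop("calls TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$position < 1L))
    stop("call position must be >= 1 (1-based TSV dialect)")
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  sort(GRanges(df$seqid, IRanges(start = df$position, width = 1L),
               strand = df$strand, score = as.numeric(df$score)))
}

#' @rdname readCalls
#' @param calls a \link[GenomicRanges]{GRanges} of width-1 calls.
#' @export
writeCalls <- function(calls, path, dialect = c("auto", "gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
               else "tsv"
  if (dialect == "gff3") {
    gr <- calls
    gr$type <- "modified_base"
    gr$source <- "RMscout"
    gr$modification <- "m6A"
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    df <- data.frame(seqid = as.character(GenomicRanges::seqnames(calls)),
                     position = GenomicRanges::start(calls),
                     strand = as.character(GenomicRanges::strand(calls)),
                     score = calls$score)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write construct panels as JSON
#'
#' Schema: \code{\{parent_length, constructs: [\{id, retained: [[s, e], ...],
#' efficiency, role, control\}]\}} with \code{retained} intervals 0-based
#' half-open (converted to 1-based closed in memory).  \code{efficiency}
#' null encodes missing data; 0 encodes "not detected".
#'
#' @param path file path.
#' @return \code{readPanel}: a \linkS4class{TransformabilityPanel}.
#' @export
readPanel <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  constructs <- lapply(js$constructs, function(cj) {
    iv <- cj$retained
    ir <- if (length(iv)) {
      m <- do.call(rbind, lapply(iv, unlist))
      IRanges(start = m[, 1L] + 1L, end = m[, 2L])   # half-open -> closed
    } else IRanges()
    construct(cj$id, ir,
              efficiency = if (is.null(cj$efficiency)) NA_real_
                           else cj$efficiency,
              role = if (is.null(cj$role)) "test" else cj$role,
              control = if (is.null(cj$control)) NA_character_
                        else cj$control)
  })
  transformabilityPanel(js$parent_length, constructs)
}

#' @rdname readPanel
#' @param panel a \linkS4class{TransformabilityPanel}.
#' @export
writePanel <- function(panel, path) {
  constructs <- lapply(panel@constructs, function(x) {
    iv <- lapply(seq_along(x@retained), function(i)
      c(IRanges::start(x@retained)[i] - 1L, IRanges::end(x@retained)[i]))
    list(id = x@id, retained = iv,
         efficiency = if (is.na(x@efficiency)) NULL else x@efficiency,
         role = x@role,
         control = if (is.na(x@control)) NULL else x@control)
  })
  jsonlite::write_json(list(parent_length = panel@parentLength,
                            constructs = constructs),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Published oligonucleotide sequences used for vector construction
#'
#' The synthetic oligonucleotides of the shuttle-vector construction work
#' (annealed linkers, SOE and screening primers), shipped as a FASTA
#' fixture.  Notably, \code{CpaAII-anneal.S}/\code{.AS} carry an engineered
#' CpaAII recognition site (AAGGAGATCTCC) used to introduce the site into a
#' permissive vector.
#'
#' @return named \link[Biostrings]{DNAStringSet}.
#' @export
oligoSequences <- function() {
  readFasta(system.file("extdata", "construction_oligos.fasta",
                        package = "RMscout", mustWork = TRUE))
}

#' Export intervals as BED (0-based half-open)
#'
#' @param ranges an \link[IRanges]{IRanges} or
#'   \link[GenomicRanges]{GRanges}.
#' @param path file path.
#' @param seqname chromosome label used for bare IRanges.
#' @export
writeBed <- function(ranges, path, seqname = "parent") {
  if (is(ranges, "IRanges"))
    ranges <- GRanges(seqname, ranges)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ranges)),
                   start = GenomicRanges::start(ranges) - 1L,
                   end = GenomicRanges::end(ranges))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
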