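## End-to-end driver: simulation -> discovery -> scanning -> recoding ->
## localization, with a reproducibility manifest.

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order and writes per-stage artifacts
#' plus a JSON report and a manifest (parameters, seed, package version)
#' sufficient to reproduce the outputs byte for byte.  Stages are selected
#' by supplying their configuration blocks:
#'
#' \describe{
#'   \item{simulate}{\code{list(genomeLength, motif, nPlanted, gcFraction,
#'     detectionProb, fpRate)}: generate a genome and methylome (written as
#'     FASTA and GFF3).}
#'   \item{discover}{\code{list(genome=, calls=, ...)} or empty to use the
#'     simulated data; extra entries are passed to
#'     \code{\link{discoverMotif}}.}
#'   \item{scan}{\code{list(sequences = FASTA path | DNAStringSet,
#'     motifs = list)}: per-sequence site counts (default motif registry).}
#'   \item{recode}{\code{list(cds, action = "scrub"|"kill"|"create",
#'     ...)}: recoding of a coding sequence.}
#'   \item{localize}{\code{list(panel = JSON path |
#'     TransformabilityPanel, hi, lo)}.}
#' }
#'
#' @param config named list of stage blocks as above.
#' @param outputDir directory for artifacts (created if needed).
#' @param seed global integer seed; stage seeds derive from it.
#' @return (invisibly) the report list; also written as
#'   \code{report.json}.
#' @export
runPipeline <- function(config, outputDir = tempfile("rmscout_run_"),
                        seed = 1L) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed)
  stage <- "manifest"
  tryCatch({
    sim <- NULL
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sc <- config$simulate
      motif <- if (is.null(sc$motif)) motifRegistry()$CpaAII
               else .asMotif(sc$motif)
      sim <- simulateGenome(sc$genomeLength, motif,
                            nPlanted = sc$nPlanted %||% 0L,
                            gcFraction = sc$gcFraction %||% 0.3,
                            seed = seed)
      calls <- simulateMethylome(sim$genome, sim$occurrences, motif,
                                 detectionProb = sc$detectionProb %||% 0.95,
                                 fpRate = sc$fpRate %||% 0,
                                 seed = seed + 1L)
      sim$calls <- calls
      writeFasta(sim$genome, file.path(outputDir, "genome.fasta"))
      writeCalls(calls, file.path(outputDir, "calls.gff3"))
      report$simulate <- list(genomeLength = sc$genomeLength,
                              motif = motif@iupac,
                              nOccurrences = length(sim$occurrences),
                              nCalls = length(calls))
    }
    if (!is.null(config$discover)) {
      stage <- "discover"
      dc <- config$discover
      genome <- if (!is.null(dc$genome)) {
        if (is.character(dc$genome)) readFasta(dc$genome) else dc$genome
      } else sim$genome
      calls <- if (!is.null(dc$calls)) {
        if (is.character(dc$calls)) readCalls(dc$calls) else dc$calls
      } else sim$calls
      if (is.null(genome) || is.null(calls))
        stop("discover stage needs a genome and calls (or a simulate stage)")
      extra <- dc[setdiff(names(dc), c("genome", "calls"))]
      disc <- do.call(discoverMotif, c(list(genome = genome, calls = calls),
                                       extra))
      report$discover <- list(
        confident = disc@confident,
        top = if (length(disc@candidates))
          candidateIupac(topCandidate(disc)) else NA,
        candidates = head(disc@table, 10L))
    }
    if (!is.null(config$scan)) {
      stage <- "scan"
      sc <- config$scan
      seqs <- if (is.character(sc$sequences)) readFasta(sc$sequences)
              else sc$sequences
      motifs <- sc$motifs %||% motifRegistry()
      counts <- countSites(seqs, motifs)
      write.table(data.frame(id = rownames(counts), counts,
                             check.names = FALSE),
                  file.path(outputDir, "site_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$scan <- list(counts = as.data.frame(counts))
    }
    if (!is.null(config$recode)) {
      stage <- "recode"
      rc <- config$recode
      action <- rc$action %||% "scrub"
      plan <- switch(action,
        scrub = scrubRecode(rc$cds, k = rc$k %||% 6L, seed = seed),
        kill = killSites(rc$cds, rc$motifs, seed = seed),
        create = createSite(rc$cds, rc$motif, frame = rc$frame),
        stop("unknown recode action: ", action))
      report$recode <- list(action = action,
                            nSubstitutions = nSubstitutions(plan),
                            nCodonsAltered = nCodonsAltered(plan),
                            maxUnalteredRun = maxUnalteredRun(plan),
                            substitutions = plan@substitutions,
                            output = plan@output)
    }
    if (!is.null(config$localize)) {
      stage <- "localize"
      lc <- config$localize
      panel <- if (is.character(lc$panel)) readPanel(lc$panel) else lc$panel
      loc <- localizeRegion(panel, hi = lc$hi %||% 1e2, lo = lc$lo %||% 1e1)
      writeBed(loc@candidate, file.path(outputDir, "candidate_region.bed"))
      report$localize <- list(
        candidate = if (length(loc@candidate))
          data.frame(start = IRanges::start(loc@candidate),
                     end = IRanges::end(loc@candidate)) else NULL,
        consistent = loc@consistent,
        phenotypes = loc@phenotypes)
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(
    package = "RMscout",
    version = as.character(utils::packageVersion("RMscout")),
    seed = seed,
    stages = names(config),
    parameters = .serializableConfig(config))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Reduce a config to JSON-serializable parameter records.
.serializableConfig <- function(x) {
  if (is.list(x) && !is.object(x)) return(lapply(x, .serializableConfig))
  if (is(x, "DegenerateMotif")) return(x@iupac)
  if (is(x, "DNAStringSet") || is(x, "DNAString")) return("<sequence>")
  if (is(x, "TransformabilityPanel")) return("<panel>")
  if (is(x, "GRanges")) return("<calls>")
  if (is.atomic(x)) return(x)
  "<object>"
}
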