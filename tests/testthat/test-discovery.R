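reg <- motifRegistry()

test_that("context extraction orients calls so the methylated base is a central A", {
  g <- Biostrings::DNAStringSet(c(g = paste0(strrep("C", 20), "ATG",
                                             strrep("C", 20))))
  fwd <- GenomicRanges::GRanges("g", IRanges::IRanges(21, 21), strand = "+")
  ctx <- extractContexts(g, fwd, halfWidth = 5)
  expect_length(ctx, 1L)
  expect_identical(substr(ctx, 6, 6), "A")
  ## reverse call over the T (paired adenine on the bottom strand)
  rev <- GenomicRanges::GRanges("g", IRanges::IRanges(22, 22), strand = "-")
  ctx2 <- extractContexts(g, rev, halfWidth = 5)
  expect_identical(substr(ctx2, 6, 6), "A")
  ## truncated windows are excluded
  edge <- GenomicRanges::GRanges("g", IRanges::IRanges(3, 3), strand = "+")
  expect_length(extractContexts(g, edge, halfWidth = 15), 0L)
  out <- GenomicRanges::GRanges("g", IRanges::IRanges(99, 99), strand = "+")
  expect_error(extractContexts(g, out, halfWidth = 5), "outside")
})

test_that("consensus columns pick the smallest covering IUPAC code", {
  expect_identical(consensusColumns(rep("ACGTA", 6)), "ACGTA")
  half <- c(rep("A", 5), rep("T", 5))
  expect_identical(consensusColumns(half), "W")
  quarter <- c("A", "C", "G", "T", "A", "C", "G", "T")
  expect_identical(consensusColumns(quarter), "N")
  ## 95/5 split: single base covers >= 0.9
  mostly <- c(rep("G", 19), "T")
  expect_identical(consensusColumns(mostly), "G")
  expect_error(consensusColumns(c("A", "A")), "insufficient")
})

test_that("candidate enumeration crops the consensus into bipartite motifs", {
  cons <- paste0(strrep("N", 9), "AAGNNNNNCTCC", strrep("N", 10))
  ## center = column 16 (the second A of AAG sits at column 11; the
  ## methylated A of the bottom strand is the center here by construction)
  cands <- enumerateCandidates(cons, center = 11L)
  ius <- vapply(cands, candidateIupac, character(1))
  expect_true("AAGNNNNNCTCC" %in% ius)
  ## all-N consensus has nothing to offer
  expect_length(enumerateCandidates(strrep("N", 31)), 0L)
  ## contiguous (spacer 0) candidates are part of the search space
  cons2 <- paste0(strrep("N", 13), "GATC", strrep("N", 14))
  ius2 <- vapply(enumerateCandidates(cons2, center = 15L),
                 candidateIupac, character(1))
  expect_true("GATC" %in% ius2)
})

test_that("scoring is exact in the noise-free limit and penalises partial motifs", {
  sim <- simulateGenome(6000, reg$CpaAII, nPlanted = 12, seed = 21)
  calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                             detectionProb = 1, fpRate = 0, seed = 21)
  true <- scoreCandidate(motifCandidate("AAG", 5L, "CTCC"),
                         sim$genome, calls)
  expect_equal(true@sensitivity, 1)
  expect_equal(true@specificity, 1)
  expect_equal(true@score, 1)
  expect_equal(true@nOccurrences, length(sim$occurrences))
  ## the left block alone matches many unmethylated loci
  partial <- scoreCandidate(motifCandidate("AAG"), sim$genome, calls)
  nAAG <- nrow(oracleScanBoth(as.character(sim$genome[[1]]), "AAG"))
  expect_equal(partial@nOccurrences, nAAG)
  expect_lt(partial@specificity, 1)
  expect_lt(partial@score, 1)
  ## no calls: zero sensitivity, zero score
  none <- scoreCandidate(true, sim$genome,
                         GenomicRanges::GRanges(seqnames = character(),
                                                ranges = IRanges::IRanges(),
                                                strand = character()))
  expect_equal(none@sensitivity, 0)
  expect_equal(none@score, 0)
  ## a motif absent from the genome is discarded with a reason
  absent <- scoreCandidate(motifCandidate("GCGCGC", 2L, "GCGCGC"),
                           sim$genome, calls)
  expect_match(absent@note, "no genomic occurrence")
})

test_that("discovery recovers a planted contiguous motif and the bipartite motif", {
  ## Dam-like palindromic GATC
  simP <- simulateGenome(3000, reg$CpaI, nPlanted = 15, seed = 31)
  callsP <- simulateMethylome(simP$genome, simP$occurrences, reg$CpaI,
                              detectionProb = 1, fpRate = 0, seed = 31)
  dP <- discoverMotif(simP$genome, callsP)
  expect_identical(candidateIupac(topCandidate(dP)), "GATC")
  expect_true(dP@confident)
  ## bipartite CpaAII under the standard simulation conditions
  simB <- simulateGenome(10000, reg$CpaAII, nPlanted = 20, seed = 7)
  callsB <- simulateMethylome(simB$genome, simB$occurrences, reg$CpaAII,
                              detectionProb = 0.95, fpRate = 1e-4, seed = 7)
  dB <- discoverMotif(simB$genome, callsB)
  top <- topCandidate(dB)
  expect_identical(candidateIupac(top), "AAGNNNNNCTCC")
  expect_identical(top@left, "AAG")
  expect_identical(top@spacer, 5L)
  expect_identical(top@right, "CTCC")
  ## both strand offsets are recovered
  expect_identical(top@methylOffsets$offset, c(2L, 10L))
  expect_identical(top@methylOffsets$strand, c("+", "-"))
})

test_that("pure false-positive call sets yield no confident motif", {
  sim <- simulateGenome(8000, reg$CpaAII, nPlanted = 0, seed = 41)
  calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                             detectionProb = 0, fpRate = 3e-3, seed = 41)
  expect_gte(length(calls), 10L)
  d <- discoverMotif(sim$genome, calls)
  expect_false(d@confident)
  if (length(d@candidates))
    expect_lt(topCandidate(d)@score, 0.5)
})

test_that("insufficient calls raise an error", {
  sim <- simulateGenome(2000, reg$CpaAII, nPlanted = 1, seed = 51)
  calls <- simulateMethylome(sim$genome, sim$occurrences[1], reg$CpaAII,
                             detectionProb = 1, fpRate = 0, seed = 51)
  expect_error(discoverMotif(sim$genome, calls, minSites = 10L),
               "insufficient")
})

test_that("discovery equals the exhaustive context-supported argmax on small inputs", {
  sim <- simulateGenome(800, reg$CpaAII, nPlanted = 6, seed = 61)
  calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                             detectionProb = 1, fpRate = 1e-3, seed = 61)
  expect_lte(length(calls), 30L)
  hw <- 12L
  d <- discoverMotif(sim$genome, calls, halfWidth = hw)
  ## independent exhaustive enumeration of every context-supported
  ## candidate, scored with the package's scorer (the shared scoring rule)
  contexts <- extractContexts(sim$genome, calls, halfWidth = hw)
  cands <- oracleContextCandidates(contexts)
  best <- NULL
  for (cd in cands) {
    mc <- motifCandidate(cd$left, as.integer(cd$spacer), cd$right)
    sc <- scoreCandidate(mc, sim$genome, calls)
    if (nzchar(sc@note)) next
    k <- oracleRankKey(candidateIupac(sc), sc@score)
    if (is.null(best) || oracleOutranks(k, best)) best <- k
  }
  expect_identical(candidateIupac(topCandidate(d)), best$iu)
  expect_equal(topCandidate(d)@score, best$score)
})

test_that("lowering the detection probability never raises the true motif's sensitivity", {
  for (s in c(71, 72, 73)) {
    sim <- simulateGenome(6000, reg$CpaAII, nPlanted = 12, seed = s)
    sens <- sapply(c(1, 0.9, 0.7, 0.5), function(p) {
      calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                                 detectionProb = p, fpRate = 5e-4, seed = s)
      mc <- motifCandidate("AAG", 5L, "CTCC")
      scoreCandidate(mc, sim$genome, calls)@sensitivity
    })
    expect_true(all(diff(sens) <= 1e-12),
                info = paste("seed", s, ":", paste(round(sens, 4),
                                                   collapse = " >= ")))
  }
})
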