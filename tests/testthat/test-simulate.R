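reg <- motifRegistry()

test_that("simulated genomes contain the planted occurrences and are reproducible", {
  sim <- simulateGenome(10000, reg$CpaAII, nPlanted = 20, seed = 1)
  expect_gte(length(sim$occurrences), 20L)
  sq <- as.character(sim$genome[[1]])
  ## every reported interval matches the motif per the naive oracle
  exp <- oracleScanBoth(sq, "AAGNNNNNCTCC")
  expect_equal(GenomicRanges::start(sim$occurrences), exp$start)
  expect_equal(as.character(GenomicRanges::strand(sim$occurrences)),
               exp$strand)
  again <- simulateGenome(10000, reg$CpaAII, nPlanted = 20, seed = 1)
  expect_identical(as.character(again$genome), as.character(sim$genome))
  other <- simulateGenome(10000, reg$CpaAII, nPlanted = 20, seed = 2)
  expect_false(identical(as.character(other$genome),
                         as.character(sim$genome)))
  expect_error(simulateGenome(8, reg$CpaAII), "longer")
})

test_that("with no planting the occurrence list is chance occurrences only", {
  sim <- simulateGenome(2000, reg$CpaI, nPlanted = 0, seed = 3)
  exp <- oracleScanBoth(as.character(sim$genome[[1]]), "GATC")
  expect_equal(length(sim$occurrences), nrow(exp))
  expect_length(sim$planted, 0L)
})

test_that("noise-free methylome calls are exactly the methylatable adenines", {
  sim <- simulateGenome(5000, reg$CpaAII, nPlanted = 10, seed = 4)
  calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                             detectionProb = 1, fpRate = 0, seed = 4)
  ## expected positions computed independently from the occurrence list:
  ## top-strand A at offset 2, bottom-strand A opposite offset 10
  st <- GenomicRanges::start(sim$occurrences)
  sd <- as.character(GenomicRanges::strand(sim$occurrences))
  expPlus <- c(st[sd == "+"] + 1L, st[sd == "-"] + 2L)       # offset 2 / mirrored 10
  expMinus <- c(st[sd == "+"] + 9L, st[sd == "-"] + 10L)
  expKey <- sort(unique(c(paste(expPlus, "+"), paste(expMinus, "-"))))
  gotKey <- sort(paste(GenomicRanges::start(calls),
                       as.character(GenomicRanges::strand(calls))))
  expect_identical(gotKey, expKey)
  none <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                            detectionProb = 0, fpRate = 0, seed = 4)
  expect_length(none, 0L)
})

test_that("a motif without methyl offsets is a configuration error", {
  sim <- simulateGenome(1000, reg$CpaAI, nPlanted = 2, seed = 1)
  expect_error(simulateMethylome(sim$genome, sim$occurrences, reg$CpaAI),
               "methyl offsets")
})

test_that("detected-call counts follow the stated binomial rate", {
  p <- 0.9
  total <- 0L; n <- 0L
  for (s in 1:25) {
    sim <- simulateGenome(4000, reg$CpaAII, nPlanted = 10, seed = s)
    calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                               detectionProb = p, fpRate = 0, seed = s)
    total <- total + length(calls)
    n <- n + 2L * length(sim$occurrences)
  }
  ## aggregate count within the 99% normal approximation of Binomial(n, p)
  mu <- n * p
  sdv <- sqrt(n * p * (1 - p))
  expect_gt(total, mu - 2.58 * sdv)
  expect_lt(total, mu + 2.58 * sdv)
})

test_that("false positives are strand-consistent adenines at the stated rate", {
  sim <- simulateGenome(5000, reg$CpaAII, nPlanted = 0, seed = 6)
  calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                             detectionProb = 1, fpRate = 2e-3, seed = 6)
  expect_gt(length(calls), 0L)
  sq <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  pos <- GenomicRanges::start(calls)
  sd <- as.character(GenomicRanges::strand(calls))
  expect_true(all(sq[pos[sd == "+"]] == "A"))
  expect_true(all(sq[pos[sd == "-"]] == "T"))
})

test_that("noise-free panels attenuate exactly the region-retaining constructs", {
  pan <- simulatePanel(7000, c(3000, 3333),
                       list(full = cbind(2990, 3350),
                            half = cbind(1, 3150),
                            none = cbind(3400, 7000)),
                       controlEfficiency = 3.7e4, attenuation = 1e4,
                       noiseDex = 0, seed = 1)
  eff <- sapply(pan@constructs, function(x) x@efficiency)
  names(eff) <- sapply(pan@constructs, function(x) x@id)
  expect_equal(unname(eff["full"]), 3.7e4 / 1e4)
  expect_equal(unname(eff["half"]), 3.7e4)   # partial retention is permissive
  expect_equal(unname(eff["none"]), 3.7e4)
  again <- simulatePanel(7000, c(3000, 3333),
                         list(full = cbind(2990, 3350),
                              half = cbind(1, 3150),
                              none = cbind(3400, 7000)),
                         controlEfficiency = 3.7e4, attenuation = 1e4,
                         noiseDex = 0.2, seed = 9)
  again2 <- simulatePanel(7000, c(3000, 3333),
                          list(full = cbind(2990, 3350),
                               half = cbind(1, 3150),
                               none = cbind(3400, 7000)),
                          controlEfficiency = 3.7e4, attenuation = 1e4,
                          noiseDex = 0.2, seed = 9)
  expect_identical(sapply(again@constructs, function(x) x@efficiency),
                   sapply(again2@constructs, function(x) x@efficiency))
  expect_error(simulatePanel(7000, c(3000, 3333), list(), seed = 1), "empty")
})

test_that("random coding sequences are translatable and honour the usage table", {
  cds <- randomCds(112, seed = 1)
  expect_equal(nchar(cds), 336L)
  prot <- translateCds(cds)
  expect_false(grepl("\\*", prot))
  expect_identical(prot, oracleTranslate(cds))
  expect_identical(randomCds(50, seed = 2), randomCds(50, seed = 2))
  ## usage excluding Ser/Ala codons yields none of either amino acid
  gc <- Biostrings::GENETIC_CODE
  keep <- names(gc)[!gc %in% c("S", "A", "*")]
  cds2 <- randomCds(200, codonUsage = setNames(rep(1, length(keep)), keep),
                    seed = 3)
  expect_false(grepl("[SA]", translateCds(cds2)))
  expect_error(randomCds(10, codonUsage = c(TAA = 1)), "degenerate")
})
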