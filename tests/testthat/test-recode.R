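reg <- motifRegistry()

test_that("translation follows the standard code", {
  expect_identical(translateCds("GCAAGTTATGCTCCA"), "ASYAP")
  expect_identical(translateCds("ATG"), "M")
  expect_identical(translateCds("TAA"), "*")
  expect_identical(translateCds("AUGGCU"), "MA")   # RNA handled as DNA
  expect_error(translateCds("ACGT"), "divisible")
  set.seed(3)
  for (i in 1:20) {
    cds <- randomCds(sample(5:40, 1), seed = i)
    expect_identical(translateCds(cds), oracleTranslate(cds))
  }
})

test_that("synonymous options come from the codon table", {
  expect_setequal(synonymousOptions("AGT"),
                  c("AGC", "TCA", "TCC", "TCG", "TCT"))
  expect_true("TCT" %in% synonymousOptions("AGT"))   # the published Ser swap
  expect_length(synonymousOptions("ATG"), 0L)        # Met is unique
  expect_setequal(synonymousOptions("GCT"), c("GCA", "GCC", "GCG"))
  expect_true("GCC" %in% synonymousOptions("GCT"))   # the published Ala swap
  expect_error(synonymousOptions("AXT"))
  set.seed(5)
  for (cd in sample(names(Biostrings::GENETIC_CODE), 20))
    expect_setequal(synonymousOptions(cd), oracleSynonyms(cd))
})

test_that("hamming distance counts differing positions", {
  expect_equal(hammingDist("AGT", "TCT"), 2L)
  expect_equal(hammingDist("GCT", "GCC"), 1L)
  expect_equal(hammingDist("AAA", "AAA"), 0L)
  expect_error(hammingDist("AA", "AAA"), "mismatch")
})

test_that("scrub recoding bounds the unaltered run and preserves translation", {
  gc <- Biostrings::GENETIC_CODE
  noMW <- names(gc)[!gc %in% c("M", "W", "*")]
  cds <- substr(randomCds(112, codonUsage = setNames(rep(1, length(noMW)),
                                                     noMW), seed = 10),
                1, 334)
  plan <- scrubRecode(cds, k = 6, seed = 10)
  expect_lte(maxUnalteredRun(plan), 5L)
  expect_identical(translateCds(substr(recodedSequence(plan), 1, 333)),
                   translateCds(substr(cds, 1, 333)))
  ## the scrub introduces no known restriction site that was absent before
  before <- countSites(cds, reg)
  after <- countSites(recodedSequence(plan), reg)
  expect_true(all(after <= before))
})

test_that("scrub is infeasible over runs of single-codon amino acids", {
  err <- tryCatch(scrubRecode("ATGTGGATGTGG", k = 6), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "\\[1,12\\]")
})

test_that("a huge k makes the scrub alter every codon that can be altered", {
  cds <- "ATGGCTAGTTGGCCA"   # M A S W P: M and W are unalterable
  plan <- scrubRecode(cds, k = 1000, seed = 1)
  sub <- substitutions(plan)
  altered <- unique((sub$pos - 1L) %/% 3L + 1L)
  expect_setequal(altered, c(2L, 3L, 5L))
  expect_identical(translateCds(recodedSequence(plan)), "MASWP")
})

test_that("scrub run bound holds across random coding sequences", {
  for (s in 1:5) {
    cds <- randomCds(60, seed = 100 + s)
    plan <- try(scrubRecode(cds, k = 6, seed = s), silent = TRUE)
    if (inherits(plan, "try-error")) next   # rare Met/Trp pile-ups
    expect_lte(maxUnalteredRun(plan), 5L)
    expect_identical(translateCds(recodedSequence(plan)), translateCds(cds))
  }
})

test_that("site ablation is minimal on the published toy frame", {
  toy <- "GCAAGTTATGCTCCA"   # codons GCA AGT TAT GCT CCA
  hit <- scanMotif(toy, reg$CpaAII)
  expect_equal(GenomicRanges::start(hit), 3L)   # 0-based [2,14)
  expect_equal(GenomicRanges::end(hit), 14L)
  plan <- killSites(toy, list(reg$CpaAII))
  expect_identical(translateCds(recodedSequence(plan)), "ASYAP")
  expect_length(scanMotif(recodedSequence(plan), reg$CpaAII), 0L)
  expect_equal(nSubstitutions(plan), oracleKillMin(toy, "AAGNNNNNCTCC"))
  expect_equal(nSubstitutions(plan), 1L)
})

test_that("ablation minimality matches the exhaustive oracle on random instances", {
  n <- 0
  for (s in 1:60) {
    if (n >= 5) break
    cds <- randomCds(12, seed = 200 + s)
    for (mot in list(reg$CpaI, reg$CpaAI)) {
      mt <- oracleScanBoth(cds, iupac(mot))
      if (nrow(mt) != 1L) next
      oracleMin <- oracleKillMinLocal(cds, iupac(mot))
      if (is.na(oracleMin)) next
      plan <- killSites(cds, list(mot), protect = NULL)
      expect_equal(nSubstitutions(plan), oracleMin, info = paste(s, iupac(mot)))
      expect_identical(translateCds(recodedSequence(plan)),
                       translateCds(cds))
      expect_length(scanMotif(recodedSequence(plan), mot), 0L)
      n <- n + 1
    }
  }
  expect_gte(n, 3)
})

test_that("a sequence without target matches yields the identity plan", {
  cds <- "ATGGGATTTCCC"
  plan <- killSites(cds, list(reg$CpaAII))
  expect_equal(nSubstitutions(plan), 0L)
  expect_identical(recodedSequence(plan), cds)
})

test_that("infeasible ablation names the offending site", {
  ## the site spans only Met/Trp codons: no synonymous escape exists
  err <- tryCatch(killSites("ATGTGGATGTGG",
                            list(degenerateMotif("toy", "GGATG"))),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "cannot ablate")
})

test_that("the published three-substitution edit is a valid ablation plan", {
  toy <- "GCAAGTTATGCTCCA"
  plan <- codonReplacements(toy, data.frame(codon = c(2L, 4L),
                                            to = c("TCT", "GCC")))
  expect_equal(nSubstitutions(plan), 3L)
  expect_equal(hammingDist("AGT", "TCT") + hammingDist("GCT", "GCC"), 3L)
  expect_identical(translateCds(recodedSequence(plan)), "ASYAP")
  expect_length(scanMotif(recodedSequence(plan), reg$CpaAII), 0L)
  ## an invalid (non-synonymous) replacement is rejected
  expect_error(codonReplacements(toy, data.frame(codon = 2L, to = "GGG")),
               "translation")
})

test_that("site creation is Hamming-minimal over all placements", {
  plan <- createSite("AACGAGATCTCC", "AAGNNNNNCTCC")
  expect_equal(nSubstitutions(plan), 1L)
  expect_equal(substitutions(plan)$pos, 3L)   # 0-based position 2
  expect_identical(substitutions(plan)$to, "G")
  ## already present: nothing to do
  done <- createSite("CCAAGGAGATCTCCAA", "AAGNNNNNCTCC")
  expect_equal(nSubstitutions(done), 0L)
  ## random non-coding sequences against the per-offset Hamming oracle
  set.seed(23)
  for (i in 1:15) {
    sq <- randomDna(sample(20:60, 1))
    m <- randomIupac(sample(4:8, 1), degenProb = 0.2)
    plan <- createSite(sq, m)
    expect_equal(nSubstitutions(plan), oracleCreateMin(sq, m),
                 info = paste(sq, m))
    expect_gte(length(scanMotif(recodedSequence(plan), m)), 1L)
  }
})

test_that("coding site creation keeps substitutions synonymous", {
  set.seed(29)
  found <- 0
  for (i in 1:20) {
    cds <- randomCds(8, seed = 300 + i)
    plan <- try(createSite(cds, reg$CpaAI, frame = 0), silent = TRUE)
    if (inherits(plan, "try-error")) next
    expect_identical(translateCds(recodedSequence(plan)), translateCds(cds))
    expect_gte(length(scanMotif(recodedSequence(plan), reg$CpaAI)), 1L)
    found <- found + 1
  }
  expect_gte(found, 5)
})
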