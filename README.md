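# RMscout

Characterising and defeating bacterial restriction–modification (RM)
barriers to plasmid transformation.

Host RM systems are the most common reason a shuttle vector that
transforms one bacterium at 10⁴ transformants/µg fails almost completely
in another: an endonuclease cleaves incoming DNA wherever its recognition
sequence occurs unmethylated. For *Clostridium pasteurianum* — a
glycerol-to-butanol fermenter whose genetic toolkit this workflow was
built around — the responsible system is CpaAII, a Type I enzyme with the
bipartite recognition sequence 5′-AAGNNNNNCTCC-3′, alongside the known
Type II systems CpaAI (5′-CGCG-3′) and CpaI (5′-GATC-3′).

RMscout is an R package for everyone who has to work around such a
barrier — strain engineers designing shuttle vectors, and
methylome/sequence analysts characterising the host:

* **Degenerate motif scanning** (`scanMotif`, `countSites`): all
  (overlapping) matches of an IUPAC motif, both strands, linear or
  circular sequences, with palindrome deduplication.
* **Motif discovery from m6A calls** (`discoverMotif` and the
  `extractContexts` → `consensusColumns` / frequent-word seeding →
  `scoreCandidate` pipeline): infers a possibly bipartite recognition
  motif from strand-specific N6-methyladenine position calls against a
  genome — the level of output an SMRT methylome analysis produces.
  Candidates (left block, N-spacer, right block) are scored by
  specificity (fraction of genomic occurrences supported by a call),
  sensitivity (fraction of calls explained) and their harmonic mean
  F = 2·s·p/(s+p), with methylated offsets inferred from the data on
  both strands.
* **Translation-preserving recoding** (`killSites`, `createSite`,
  `scrubRecode`): remove every match of a motif with a provably minimal
  number of silent substitutions, introduce a site with minimal
  substitutions, or scrub a CDS so no window of ≥ k nt is left unaltered
  (max unaltered run ≤ k−1), defeating any unknown recognition sequence
  of length ≥ k.
* **Restriction-region localization** (`callPhenotype`,
  `localizeRegion`): classify deletion derivatives as
  restricted/permissive from transformation efficiencies
  (fold-reduction thresholds hi = 10², lo = 10¹) and intersect/subtract
  their retained intervals to pin down the causal region.
* **Simulators** (`simulateGenome`, `simulateMethylome`,
  `simulatePanel`, `randomCds`): seeded generators for every input, with
  ground truth, used throughout the test suite.

The package is Bioconductor-shaped: sequences are `Biostrings` objects,
calls and matches are `GRanges`, intervals are `IRanges`, and the central
results (`DegenerateMotif`, `MotifCandidate`, `RecodePlan`, `Construct`,
`LocalizationResult`) are S4 classes with validity checks.

## Worked example

Simulate a 10 kb genome with 20 planted CpaAII sites, call its methylome
at 95% detection with background false positives, and recover the motif:

```r
library(RMscout)
reg <- motifRegistry()
reg$CpaAII
#> DegenerateMotif 'CpaAII': 5'-AAGNNNNNCTCC-3' (1024 concrete 12-mers; m6A at 2(+), 10(-))

sim <- simulateGenome(10000, reg$CpaAII, nPlanted = 20, seed = 7)
calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                           detectionProb = 0.95, fpRate = 1e-4, seed = 7)
length(sim$occurrences); length(calls)
#> [1] 21
#> [1] 38

disc <- discoverMotif(sim$genome, calls)
disc
#> MotifDiscovery: 88 scored candidate(s); confident
#>          iupac sensitivity specificity     score nOccurrences nSupported
#> 1 AAGNNNNNCTCC   0.9473684   1.0000000 0.9729730           21         21
#> 2  AGNNNNNCTCC   0.9473684   1.0000000 0.9729730           21         21
#> 3  AAGNNNNNCTC   0.9473684   0.9130435 0.9298893           23         21
#> 4 AAGNNNNNNTCC   0.9473684   0.9130435 0.9298893           23         21
#> 5 AANNNNNNCTCC   0.9473684   0.8400000 0.8904594           25         21
```

The top candidate is the planted motif: all 21 genomic occurrences (20
planted plus one arising by chance) carry supporting calls
(specificity 1.0), and 36 of the 38 calls fall at its methylatable
offsets (sensitivity 0.947 — two calls are simulated background noise).
Truncations of the motif tie on score here but rank below it.

Ablate the single CpaAII site from a (reconstructed) coding frame with
the fewest possible silent substitutions:

```r
plan <- killSites("GCAAGTTATGCTCCA", list(reg$CpaAII))
plan
#> RecodePlan: 1 substitution(s), 1 codon(s) altered, max unaltered run 12 nt (translation preserved)
substitutions(plan)
#>   pos from to
#> 1   3    A  C
recodedSequence(plan)
#> [1] "GCCAGTTATGCTCCA"
```

One synonymous change (GCA→GCC, Ala) destroys the AAG half-site; the
protein ASYAP is unchanged. Scanning the published annealing oligo that
engineered a CpaAII site into a permissive vector:

```r
countSites(oligoSequences()["CpaAII-anneal.S"], reg)
#>                 CpaAII CpaAI CpaI Dcm
#> CpaAII-anneal.S      1     1    1   1

foldChange(1.6e3, 3.7e0, rounded = TRUE)   # recoded vs restricted parent
#> [1] 432
```

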