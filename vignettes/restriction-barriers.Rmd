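---
title: "Characterising and defeating a restriction barrier: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising and defeating a restriction barrier: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RMscout)
```

# The problem

Restriction–modification (RM) systems are the most common cause of
transformation recalcitrance in bacteria.  A host endonuclease cleaves
incoming DNA wherever its recognition sequence occurs unmethylated, and a
single site on a shuttle vector can depress electrotransformation by four
orders of magnitude.  *Clostridium pasteurianum*, a glycerol-to-butanol
fermenter of real biotechnological interest, carries — besides the known
Type II systems CpaI (5'-GATC-3') and CpaAI (5'-CGCG-3') — a Type I system,
CpaAII, with the bipartite recognition sequence 5'-AAGNNNNNCTCC-3'.
RMscout implements the full computational workflow around such a barrier:

1. **Localization** — given a panel of vector deletion derivatives with
   measured transformation efficiencies, infer the minimal region of the
   parent that carries the restriction determinant.
2. **Motif discovery** — given strand-specific N6-methyladenine (m6A)
   position calls against a genome (the level of output an SMRT methylome
   analysis produces), infer the recognition motif of the responsible
   methyltransferase, including bipartite Type I motifs.
3. **Scanning** — count and locate degenerate recognition sites on any
   sequence, both strands, linear or circular.
4. **Recoding** — edit a coding sequence without changing its protein:
   remove every match of a named motif with the fewest possible silent
   substitutions, introduce a site with the fewest substitutions, or
   "scrub" the sequence so that no window of a chosen length is left
   unaltered, defeating any unknown recognition sequence of at least that
   length.
5. **Simulation** — generate every input the pipeline consumes, with known
   ground truth, so the algorithms can be validated end to end.

# Conventions

All in-memory coordinates are **1-based, closed intervals**, the native
convention of `IRanges`/`GRanges`, so every interval in this package
composes directly with the Bioconductor ecosystem.  At file boundaries the
format's own convention rules: GFF3 is written and read 1-based; BED and
the panel-JSON interval lists are 0-based half-open.  Sequences read from
FASTA are upper-cased and U is mapped to T (published codon changes are
often printed as RNA); degenerate letters in *subject* sequences are
rejected at load, since a scan subject must be concrete for strand
bookkeeping to be meaningful.

A motif and its reverse complement denote the same recognition sequence
read from opposite strands.  `scanMotif` therefore reports reverse-strand
matches on forward coordinates, suppresses the duplicate report for
motifs that are palindromic at the IUPAC level, and the discovery module
collapses candidate motifs to a canonical orientation (the
lexicographically smaller of the pair).

# Phenotype calling and localization

A construct is called **restricted** when its efficiency is at least
`hi`-fold below its stated control (default `hi = 1e2`), **permissive**
when at most `lo`-fold below (default `lo = 1e1`, which also covers any
improvement), and **indeterminate** in between.  The printed efficiencies
of the vector panel differ by at least two orders of magnitude between the
restricted and permissive groups in every comparison, so the default band
reproduces all 21 published classifications (see
`transformabilityData()`); "no transformants detected" is encoded as
efficiency 0 and called restricted with infinite fold-reduction.  The
*stated control* matters: deletion derivatives are compared against the
unmodified control vector measured alongside them, while recoded vectors
are compared against their restricted parents (the published comparison is
a fold *increase*); using one global control would push a
~12-fold-improved construct into the indeterminate band.

Localization assumes a **single contiguous causal region**: a construct is
restricted if and only if it fully retains that region.  Under this model
the candidate region is

> (intersection of the retained intervals of all restricted constructs)
> minus (union of the retained intervals of all permissive constructs),

computed with `IRanges` set algebra.  Violations — an empty candidate, or
a permissive construct fully retaining the candidate — are reported as an
inconsistency with per-construct witnesses rather than resolved, matching
the observed biology: one of the two identical CpaAII sites on the
ClosTron vectors escaped restriction, which a single-motif model cannot
explain.  A known limitation of the subtraction rule is that a permissive
construct retaining *part* of the causal region over-prunes the candidate;
the model therefore assumes permissive retention is region-free (the
published overlapping fragments shared only 20–30 bp).

# Motif discovery from m6A calls

## Model

Calls are width-1, strand-specific genomic positions.  Around every call a
window of `halfWidth` (default 15, comfortably above the maximal 16 bp
span of the search space) is cut and oriented to the call's strand, so the
methylated base reads as an A at the centre column.  Candidate motifs are
(left block, N-spacer, right block) triples with left block 2–6 bp, spacer
0–9 and right block absent or 2–6 bp — the documented structure of
bacterial Type I recognition sequences, which also embeds contiguous
Type II motifs as the spacer-0/no-right-block corner.

## Seeding

Two candidate sources are combined:

* **Consensus croppings.**  A per-column IUPAC consensus (smallest code
  covering at least `minFraction = 0.9` of bases; the 0.9 tolerates the
  simulator's default 5% missed calls) is cropped at every admissible
  block/spacer geometry anchored on the centre column.
* **Frequent block words.**  For every window offset and block length,
  concrete words occurring in at least `blockMinFrac = 0.3` of contexts
  are collected and combined pairwise into bipartite candidates.

The second source is what makes bipartite discovery work.  A
non-palindromic motif methylated on both strands produces **two context
populations** — one aligned on the top-strand adenine, one on the
bottom-strand adenine — and a single column-wise consensus of that mixture
washes out both defined blocks (each is present in only ~half the rows).
Within its own component, however, each block word remains frequent at its
fixed offset; 0.3 is roughly half of one component's share after detection
losses, far above the ~1.6% background frequency of a random 3-mer at a
fixed offset.  Consensus croppings remain valuable for palindromic motifs
(e.g. GATC), whose oriented contexts form a single aligned population.

## Scoring

A candidate's methylated offsets are not assumed but **inferred**: every
A-compatible position (top strand) and T-compatible position (bottom
strand) of the motif is mapped through all genomic occurrences, and
offsets supported by calls in at least `offsetMinFrac = 0.3` of
occurrences are kept.  This matters because a candidate assembled from
oriented contexts knows only the offset of the centre adenine; the
bottom-strand offset of a Type I motif has to come from the data, and
without it the true motif's sensitivity could not exceed ~0.5.

With inferred offsets `mo`:

* specificity = fraction of genomic occurrences (both strands) with at
  least one supporting call at an offset in `mo`;
* sensitivity = fraction of all calls that fall at an offset in `mo` of
  some occurrence;
* score = harmonic mean (F-measure), 0 when both are 0.

A candidate with zero genomic occurrences has undefined specificity and is
discarded with an explanatory note.  A top score below
`scoreThreshold = 0.5` flags the result "no confident motif" — under pure
background noise no candidate explains both directions of the F-measure.

## Ranking and ties

Nested candidates tie on score exactly when the genome contains no
unmethylated chance occurrence that discriminates them — common on
10 kb-scale genomes, where a truncation like AGNNNNNCTCC may match nothing
beyond the true AAGNNNNNCTCC sites.  The ranking therefore is: score
descending, then **more fully-concrete positions** (truncations lose),
then **shorter span** (spurious partially-degenerate extensions such as
DGATC, read off a small-sample consensus, lose), then higher information
content (CCWGG beats CCNGG), then lexicographic.  All ties are resolved
deterministically; discovery involves no RNG.

The exhaustive alternative — scoring *every* candidate readable from any
context at any admissible geometry — is retained as a test oracle and
checked to agree with the seeded search on small inputs (sub-kilobase
genomes, tens of calls).

# Translation-preserving recoding

`translate`/`synonymousOptions` use the standard genetic code from
Biostrings.  Three editors return a `RecodePlan` (input, output,
substitution list) whose validity object proves every claimed invariant:
substitutions are real changes, they reconstruct the output, and coding
plans preserve the translation.

* **`killSites`** removes every both-strand match of the target motifs.
  Per site, all combinations of synonymous codons overlapping the match
  are enumerated in order of increasing substitution count, so the
  per-site edit is provably minimal (the same search a brute-force oracle
  performs); multi-site sequences are handled site by site with global
  re-scanning, so minimality is per-site for interacting sites.  By
  default the plan may not create a new match of any registry motif
  (`protect`), the point of recoding being to avoid host restriction.
* **`createSite`** minimises Hamming distance over all placements and both
  orientations; with a reading frame supplied, only synonymous codon
  combinations are admitted.
* **`scrubRecode`** guarantees that every window of `k` nucleotides
  (default 6, since most RM recognition sequences are at least 6 bp)
  contains a substitution — equivalently, the longest unaltered run is at
  most `k − 1` — while preserving the protein.  The engine is a dynamic
  programme over codons whose state is the trailing unaltered run length.
  The objective *maximises the number of altered nucleotides* subject to
  the hard run bound: a scrub exists to maximise divergence from the
  restricted parent, and this choice also gives the natural behaviour in
  the degenerate large-`k` limit (every alterable codon is altered).
  Codon usage (uniform by default; no usage table is published for this
  host) and a seeded coin are tie-breaks only.  Runs of single-codon amino
  acids (Met/Trp) longer than `k − 1` make the scrub infeasible and are
  reported with their 1-based interval.  A repair pass re-options codons
  if the scrub would create a protected site.

The published ablation of the CpaAII site — codons 521 (AGU→UCU, Ser) and
523 (GCU→GCC, Ala), three silent substitutions — is representable and
validated in the reconstructed 5-codon frame, but whether three was
*minimal* in the real vector is unknowable without the unpublished ltrA
sequence; the package verifies validity and count, not the published
edit's optimality (on the reconstructed frame a single substitution
suffices, and `killSites` finds it).

# The simulators: what they emulate, and what they do not

`simulateGenome` draws an i.i.d. genome at a chosen GC content (default
0.30, AT-rich as typical for clostridial genomes) and overwrites
non-overlapping windows with concrete realizations of the planted motif on
random strands; the returned occurrence list comes from re-scanning the
finished genome, so chance occurrences are included in the ground truth.
`simulateMethylome` is a **position-call-level** model: every methylatable
adenine dictated by the motif's offsets is called with probability
`detectionProb` (default 0.95), and false calls are placed on off-motif
adenines at `fpRate` per bp.  Detection draws one uniform per site in
deterministic site order, so with a fixed seed a lower `detectionProb`
yields a strict subset of calls — the property behind the monotonicity
tests.  There is no read-level simulation: no inter-pulse-duration
kinetics, no coverage model, no per-call quality correlated with context,
and no m5C (which real SMRT calling at ordinary coverage also misses).
Passing the recovery tests therefore demonstrates correctness of the
inference given calls, not robustness to upstream base-calling artefacts.

The CpaAII methyl offsets themselves are a modelling choice — the
methylated positions within the real motif are unpublished — set to the
second adenine of AAG on the top strand and the bottom-strand adenine
opposite the T of CTCC, consistent with Type I systems methylating
adenines on both strands.

`simulatePanel` assigns control-level efficiency to every construct except
those fully retaining the causal region, which are attenuated
`attenuation`-fold (default 1e4, the printed contrast between the
restricted parent and its control), with optional log-normal noise in
log10 space because measured efficiencies span orders of magnitude.  The
control construct represents the unmodified backbone and retains none of
the studied region.

# Problem sizes and determinism

The standard validation run plants 20 motif occurrences in a 10 kb genome
at detection 0.95 and 1e-4 false calls per bp, and requires exact recovery
of the planted motif in at least 19 of 20 seeds; oracle-equivalence checks
use 800 bp genomes with ≲30 calls for the exhaustive discovery argmax,
1000 random sequence/motif pairs (length ≤ 200) for the scanner, and
≤12-codon frames for recoding minimality.  These sizes were chosen so the
whole suite exercises every route at full strictness while remaining quick
to run on a laptop.  Every stochastic component takes an explicit seed and
restores the caller's RNG state; `runPipeline` writes a manifest of all
parameters and produces byte-identical reports under a fixed seed.

# Known limitations

* Discovery reports a ranked list, not a unique answer: the published
  observation that only one of two identical CpaAII sites was restricted
  suggests the true specificity may be more stringent than the motif the
  methylome supports, and no call-level method can resolve that.
* The localization model is single-region by design; multi-determinant
  panels surface as inconsistencies with witnesses.
* `killSites` minimality is per site; overlapping sites are resolved
  greedily.
* The scrub DP treats the protect constraint by post-hoc repair rather
  than inside the recursion; pathological protect sets could in principle
  fail repair and error out rather than search exhaustively.

# A compact end-to-end run

```{r pipeline, eval = FALSE}
reg <- motifRegistry()
sim <- simulateGenome(10000, reg$CpaAII, nPlanted = 20, seed = 7)
calls <- simulateMethylome(sim$genome, sim$occurrences, reg$CpaAII,
                           detectionProb = 0.95, fpRate = 1e-4, seed = 7)
disc <- discoverMotif(sim$genome, calls)
topCandidate(disc)

## ablate the discovered motif from a coding sequence with minimal edits
cds <- "GCAAGTTATGCTCCA"
plan <- killSites(cds, list(reg$CpaAII))
plan
```
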