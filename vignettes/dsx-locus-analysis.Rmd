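---
title: "Analysing an alternatively spliced doublesex locus with dsxSplice"
author: "dsxSplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing an alternatively spliced doublesex locus with dsxSplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsxSplice)
```

## The biological setting

Insect *doublesex* (*dsx*) genes sit at the bottom of the somatic
sex-determination cascade and are regulated by sex-specific alternative
splicing: common exons encode the DM DNA-binding domain (OD1) and the
shared part of the oligomerization domain (OD2), while alternative
female- and male-specific exons supply different C-termini. In the
mosquito *Aedes aegypti* the locus is unusually informative: it spans
roughly 450 kb, its two female-specific exons (5a and 5b) are used
combinatorially, and the splice sites flanking exon 5b deviate strongly
from the genomic consensus, pointing at positive splicing regulation
through clustered cis-elements.

`dsxSplice` packages the computations such a locus study needs:

1. gene-model handling and junction-window extraction;
2. splice-site strength statistics and weak-site classification;
3. degenerate cis-element scanning with bipartite region summaries;
4. per-intron repeat-element densities;
5. microsynteny quality;
6. partitioned pairwise dN/dS (Nei--Gojobori + Jukes--Cantor);
7. ground-truth synthetic data generators for all of the above.

## Junction windows and splice-site strength

A `GeneModel` stores classified exons in transcription order; introns
and the four junction windows derive from it. The windows follow the
classic junction-table layout: 6 exonic nt before the donor, the first
16 intronic nt, the last 16 intronic nt (ending at the terminal
dinucleotide), and the first 6 nt of the next exon. On the minus strand
all windows are read off the reverse complement, so a donor always sits
at the transcriptional 5' end of its intron; this is covered by a
strand-mirroring property test.

Acceptor strength is the pyrimidine count over the **first 12** of the
16 acceptor positions. The acceptor consensus has the form
`YYYYYYYYYYYYNYag/G`: twelve Y positions, a free position, another Y we
do not count, and the terminal `ag`. Counting 12 positions (not 16, not
14) is the definition that reproduces the published per-intron counts
of the *Ae. aegypti* locus (12, 10, 9, 11, 5, 8, 11), which is why it
is fixed in `scoreAcceptor()`:

```{r}
jx <- aedsxJunctions()
scoreAcceptor(jx$acceptor_intronic[!is.na(jx$acceptor_intronic)])[, -1]
```

Donor strength is the number of positions matching the degenerate
donor consensus. The junction-table form `GTRAGT` is the default; the
common literature variant `GTRAGY` differs only at position six and is
selectable (`scoreDonor(..., consensus = "GTRAGY")`). `N` bases never
match a consensus position and never count as pyrimidines.

### Weak-site classification

The genome-wide acceptor consensus for *Ae. aegypti* was tabulated from
4688 random introns as 8.02 ± 2.15 pyrimidines; `consensusStats()`
carries such published figures, `consensusFromIntrons()` recomputes
them from windows. A site is called weak when:

* acceptor: terminal dinucleotide is not `AG`, **or** the pyrimidine
  count falls below `mean - kSd * sd` (default `kSd = 1`, i.e. 5.87 for
  the *Aedes* consensus);
* donor: it does not start with `GT`, **or** fewer than
  `donorMinMatch = 4` of six consensus positions match.

The thresholds are tunable because no universal cutoff exists; the
defaults are the loosest integer-free rules that call exactly the two
sites flagged in the motivating locus (the 5/12, GT-terminus acceptor
preceding exon 5b and the 3/6 donor `gtactg` at its end) and nothing
else. Sample (n−1) standard deviation is used throughout; at n = 4688
the distinction from the population form is far below reporting
precision.

## Cis-element scanning

The bundled catalogue holds the five classic *dsx* splicing regulators
as IUPAC consensuses: dsxRE (`TCWWCAATCAACA`, the 13-nt TRA/TRA-2
binding repeat), NvdsxRE (`KGAAGATW`, the 8-nt hymenopteran repeat),
RBP1 types A/B (`DCADCTTTA`, `ATCYNNA`) and the TRA-2 intronic
splicing silencer (`CAAGR`). The 20-bp lepidopteran CE1 element is not
bundled because its sequence is not part of the catalogue source; users
supply it if needed.

`scanMotifs()` reports a hit wherever at most `maxMismatch` positions
violate the per-position IUPAC sets; overlapping hits are all reported
and `N` in the subject is always a violation. Matching itself is
delegated to `Biostrings::matchPattern()` and then re-checked with the
strict rule; the test suite holds the scanner position-exact against a
naive sliding-window oracle over a thousand random
(sequence, motif, mismatch) triples. Defaults are zero mismatches and
forward strand only, matching how such elements are annotated on the
sense strand of a pre-mRNA; both knobs are open, and reproducing
published *Aedes* TRA/TRA-2 hits (which deviate from the *Drosophila*
consensus in their first four bases) requires `maxMismatch >= 1` or a
locus-specific catalogue entry.

Purine-rich elements (PRE) have no published consensus, so
`detectPurineRuns()` reports *candidate* PREs as maximal A/G runs
(default: pure runs of at least 10 nt; a relaxed fraction mode merges
qualifying windows). `summarizeRegions()` quantifies "exclusively
present in one exon" with a per-motif Fisher exact test on hit-bearing
versus non-hit start positions in two designated regions --- the
simplest defensible formalization of a qualitative claim --- plus the
closed-form chance expectation
`(L - m + 1) * prod(|set_i| / 4)` per region.

## Repeat densities

`intronRepeatStats()` computes, per intron, the number of overlapping
repeat features (each counted once, any ≥ 1 bp overlap) per kb
(NoRE/kb) and the percentage of intron nucleotides covered by repeats
(REbp). Coverage is the union of clipped intervals, so REbp is bounded
by 100% and invariant under splitting an annotation row into abutting
pieces (NoRE/kb deliberately is not -- both behaviours are tested). A
`sumCoverage` switch reproduces raw clipped summation for comparison
with tools that do not merge overlaps. Group comparison reports
arithmetic means for sex-specific versus non-sex-specific introns and
flags descriptive deviations (default: outside a factor of 2 of the
reference mean); no significance test is attached because deviation of
single introns from a group mean is not a well-posed test problem.

## Microsynteny quality

Synteny quality is the percentage of conserved genes among the genes
of two compared regions. The published arithmetic for the
*dsx*-containing regions of *Ae. aegypti* and *Anopheles gambiae* (10
homologues, 16 genes, 62%) is only consistent with counting each
conserved pair once against a 16-gene total; a literal "conserved genes
in both regions over all genes in both regions" reading would count 20
conserved genes out of 26. Both conventions are exposed
(`pairs_over_printed_total`, the default, with
`nTotal = |A| + |B| - |pairs|` when not supplied; and the symmetric
`pairs_over_combined_total`), and neither is asserted to be the
original intent beyond reproducing the printed figure.
`orderConservation()` counts discordant pair order (inversions) and
flags strand flips, supporting rearrangement descriptions such as a
phosphodiesterase gene lying inside intron 2 in opposite orientation.

## Partitioned pairwise dN/dS

The Nei--Gojobori machinery is implemented from first principles and is
the package's analytical core:

* **Sites** (`codonSites()`): each codon position contributes a
  synonymous fraction = synonymous one-step changes / admissible
  one-step changes at that position. Changes creating stop codons are
  excluded from the denominator by default (the convention of dominant
  modern implementations); `strict = TRUE` restores the original
  3-change denominator. The genetic code is a table argument and
  swappable.
* **Differences** (`codonDifferences()`): for codons differing at k
  positions, all k! orderings of single-step changes are walked;
  orderings passing through a stop are excluded, falling back to all
  orderings when none survive. `sd + nd = k` always.
* **Distances**: `pS = Sd/S`, `pN = Nd/N`, corrected with
  Jukes--Cantor `d = -(3/4) ln(1 - (4/3) p)`; `p >= 3/4` is reported as
  `saturated`, not silently clamped.
* **Pairs and partitions** (`pairwiseNG86()`, `partitionSummary()`):
  codon sites with a gap, `N`, or a stop in either sequence are
  excluded pair-wise (the deletion convention is not universal across
  tools; pairwise deletion keeps the most data). Partition coordinates
  are 1-based inclusive CDS ranges, each divisible by three. The
  partition mean is the *mean of per-pair ratios* over `ok` pairs --
  matching the "mean pairwise ratio" convention -- with the
  ratio-of-means reported alongside; `dS = 0` pairs are excluded and
  counted rather than treated as infinite.

The test suite pins every layer to independent oracles: exhaustive
one-step enumeration over all 61 sense codons, an independent
path-enumeration oracle for differences, and a literal second
implementation for 20-codon toys.

No numeric claim is made about published dN/dS figures for the real
15-taxon dipteran alignment: those sequences live behind accession
downloads. Instead, recovery is demonstrated on simulated data with
known truth (below).

## What the generators emulate -- and what they do not

Every generator takes a mandatory seed and is a pure function of
(config, seed); re-runs are byte-identical, which is itself under test.

* `simulateLocus()` builds a contig with configured exon/intron sizes
  and classes, acceptor windows with per-position Bernoulli(p)
  pyrimidine content and configurable terminal dinucleotide, and donors
  matching `GTRAGT` at a configured number of positions. With
  p = 0.668 and 4688 windows, the recovered consensus mean is 8.02 --
  the Binomial(12, p) expectation. Note the binomial model has a
  standard deviation of about 1.6 at that mean; real intron collections
  are overdispersed (pyrimidine content varies *between* introns),
  which this generator intentionally does not model, so the consensus
  *sd* of real data is not a recovery target.
* `plantMotifs()` inserts uniform draws from a motif's IUPAC expansion
  at recorded, non-overlapping offsets: recall and false-positive rates
  are then exactly checkable. Backgrounds are uniform-composition by
  default so chance-hit expectations have a closed form; an AT-rich
  background (the *Aedes* genome is AT-rich) can be supplied through
  the base-composition argument of the expectation instead.
* `simulateRepeats()` drops Poisson-count, exponential-length elements
  into introns -- the statistical structure the density metrics assume,
  not a sequence model of transposons.
* `simulateCodonAlignment()` evolves a star phylogeny ancestor by
  single-nucleotide events, rejecting stops and accepting
  non-synonymous proposals with probability ω. The acceptance
  probability is a simulation device for tuning realized dN/dS, not a
  claim about mutation-selection dynamics; there is no rate
  heterogeneity, no transition/transversion bias and no tree structure
  beyond the star. Within those limits, pairwise estimates recover ω
  to ±0.1 at 300 codons (20 replicates) and two partitions simulated
  at ω = 0.05 vs 0.4 rank correctly in ≥ 19/20 replicates.

Passing these tests therefore shows the *computations* are correct on
data satisfying their assumptions; it does not validate the biological
assumptions on real genomes.

## Problem sizes and numerical choices

The shipped test and acceptance workloads use: 4688 simulated acceptor
windows (the size of the published consensus tabulation), 1000 random
scanner triples and 1000 repeat fixtures for oracle equivalence, 200
seeded backgrounds for chance-hit calibration, 100 introns of 50 kb for
density recovery, and 8-taxon alignments of 2 × 100--150 codons over 20
replicates for selection ordering -- sizes at which every stochastic
check sits comfortably inside 3-standard-error bands.

Other numerical conventions: reported integer percentages and
one-decimal fold ratios use `round()` (half-to-even), which reproduces
the conventional printed values for this locus (62.5 → 62,
58.87 → 59, 5.294 → 5.3, 64.46 → 64); coordinates are 1-based
inclusive in R objects and at GFF3/TSV boundaries, 0-based half-open
only in BED output; windows truncated by short flanking features are
flagged and excluded from scoring rather than silently padded; a
junction-table row's acceptor belongs to the intron *following* that
row's exon (so the weak acceptor preceding exon 5b appears in the exon
5a row).

## End-to-end pipelines

`runJunctionPipeline()`, `runMotifScan()`, `runRepeatStats()`,
`runSynteny()`, `runDnds()` and `runSimulateLocus()` wire the stages
into file-to-file runs: plain TSV/JSON outputs plus a run report with
record counts and md5 checksums, so identical inputs are verifiably
idempotent. They are ordinary R functions; scripted use is a
one-liner per stage, as in `scripts/acceptance.R`.

```{r}
fx <- tempfile()
loc <- simulateLocus(list(
  seed = 1L,
  exons = data.frame(exon_id = c("e1", "e5a", "e5b", "e2"),
                     size = c(100L, 120L, 110L, 90L),
                     class = c("common", "female_specific",
                               "female_specific", "common")),
  intronSizes = c(150L, 208L, 120L),
  acceptorP = c(0.9, 0.3, 0.9), donorFidelity = c(6L, 6L, 3L)))
files <- writeLocus(loc, fx)
scored <- runJunctionPipeline(files[["genome"]], files[["gff3"]],
                              files[["class_map"]],
                              outDir = file.path(fx, "out"))
scored[, c("intron_id", "y_count", "terminal", "donor_match",
           "acceptor_weak", "donor_weak")]
```

## Known limitations

* The splice-site model is count-based by design; it is not a PWM or
  MaxEnt model and does not locate branch points.
* The scanner verifies and maps catalogue elements; it does not
  discover motifs de novo.
* Repeat discovery and homology inference are upstream inputs, not
  package functionality.
* dN/dS is pairwise counting only: no tree-aware or site-specific
  selection inference.
* The synthetic generators trade realism for analytic tractability, as
  detailed above.
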