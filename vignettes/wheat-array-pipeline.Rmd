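---
title: "Methods: marker classification, linkage and consensus mapping, and introgression detection"
author: "IntroMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker classification, linkage and consensus mapping, and introgression detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IntroMap)
```

IntroMap implements the downstream analysis of a high-density SNP
genotyping screen of hexaploid wheat and its relatives: per-marker
performance classification, physical chromosome assignment from aneuploid
stocks, doubled-haploid (DH) linkage-map construction, consensus-map
merging, principal-coordinate ordination, and the detection of alien
introgression segments as rare-haplotype blocks. A seeded synthetic-data
generator provides every input the pipeline consumes, so each stage can be
validated against a known truth.

## Genotype calls and containers

All panel data live in a `CallMatrix`: markers × accessions over the
five-state alphabet `AA`, `AB`, `BB`, `NN`, `NC`. `NN` is the
null-homozygote cluster of an off-target variant (a probe whose target
locus is absent from some genomes — common in wide wheat crosses); `NC` is
a failed call. Mapping populations use parent-coded `DhPopulation` calls
`A`/`B`, with `H` marking residual heterozygosity. A DH line is expected
homozygous, so `H` calls are treated as missing by every mapping stage;
the generator's heterozygosity-rate knob (`simConfig(hetRate = )`)
defaults to 0.

## Marker performance classification

Array genotyping software defines six marker categories on
intensity-cluster properties. At the call level — the only observable this
package consumes — the same categories are re-expressed on genotype-class
counts, applied in a fixed decision order (`classifyMarker()`):

1. **CRBT** — call rate below `callrateMin` (default 0.80, the threshold
   appropriate for panels containing wild relatives whose call rates run
   far below elite material). Cluster-quality criteria that require
   intensities are necessarily dropped.
2. **OTV** — a null-homozygote cluster plus at least two ordinary
   genotype classes.
3. **MHR** — a single called class (monomorphic).
4. **PHR** — all three ordinary classes with at least `minMinorHom`
   (default 2) minor homozygotes.
5. **NMH** — two classes, one the heterozygote; or all three classes
   short of the minor-homozygote quorum.
6. A codominant `AA`/`BB` pair meeting the quorum is also **PHR** — in
   inbred wheat panels the heterozygote cluster is legitimately absent,
   and such markers are codominant and polymorphic by any reading.
   Everything else (notably a lone minor homozygote with no heterozygote
   support) is the residual class **Other**.

Minor-allele ties (equal homozygote counts) break lexicographically, `AA`
before `BB`. Only PHR, NMH and OTV are "useful" for downstream work;
`usefulTotal()` and `percentShare()` reproduce the reporting arithmetic.
Polymorphism between accession groups (`countPolymorphic()`) is counted on
useful markers: more than one distinct called genotype among the pooled
accessions, no-calls ignored — a single individual with a distinct call
already counts. Reported percentages round half away from zero to one
decimal throughout.

## Physical assignment from aneuploid stocks

Nullisomic/tetrasomic stocks lack one chromosome pair; terminal-deletion
stocks lack the distal part of one arm. A marker whose locus sits on the
missing segment cannot hybridize and returns `NC` — or `NN`, which is
treated as absence (hemizygous null) since the lesion removes the locus.
Tetrasomic dosage compensation is ignored: calls carry no dosage.

The assignment rule (`assignByNulliTetra()`) is deliberately strict, since
the underlying screen never published its threshold: a marker must be
called in ≥ 90% of euploid references, absent in *every* stock of exactly
one lesion, and called in every other stock. Markers absent under zero or
two-plus lesions stay unassigned; with no 3B nullisomic stock in the
classical panel, 3B markers simply remain unassigned by this source.
Deletion stocks refine localization (`assignByDeletion()`): absence in a
stock retaining the proximal fraction ρ of an arm places the marker distal
to ρ, presence places it proximal, so nested deletions bound the marker to
`[max ρ(absent), min ρ(present)]` in retained-fraction coordinates (0 =
centromere, 1 = telomere). Contradictory patterns unassign the marker.
`reconcilePhysical()` combines sources: agreement wins, conflict unassigns
and is logged, and a lone source speaks with priority nulli/tetra >
deletion > survey-contig annotation.

## Doubled-haploid linkage maps

`buildMap()` runs the full frame-map procedure:

* **Missing filter** — markers with *strictly more* than `maxMissing`
  (default 20%) missing data are removed; exactly 20% survives.
* **Binning** — two markers co-segregate when their calls are identical or
  exactly complementary on all pairwise-complete lines (|correlation| = 1),
  with at least `minBinOverlap` (default 10) informative lines to keep
  sparse overlaps from producing spurious bins. Bins are connected
  components of this relation; unique-pattern markers (singleton bins) are
  removed, mirroring saturated-array practice where a pattern seen once is
  most likely an artefact.
* **Representatives** — least missing data, ties broken by a seeded draw.
* **Distortion filter** — a 1-df chi-square of A:B against the 1:1 DH
  expectation on each representative; `p < alpha` (default 0.05) removes
  the representative *and its whole bin*.
* **Grouping** — an edge between representatives requires both LOD ≥ 6
  and rf ≤ 0.3 (two-point, phase chosen so r ≤ 0.5); linkage groups are
  the connected components, singletons are reported unlinked.
* **Ordering** — the objective is SARF, the sum of adjacent recombination
  fractions. Two initial orders are built — greedy insertion seeded from
  the most distant pair, and a principal-coordinate seriation of the
  Kosambi distance matrix — and each is refined by exhaustive rippling of
  a sliding window of `rippleWindow` (default 5) markers to a fixed point;
  the lower final SARF wins. Two seeds are used because greedy insertion
  occasionally folds a long group in a way window-local moves cannot
  undo, while the spectral seed is nearly always globally correct but
  locally sloppy; the combination attains the exhaustive SARF optimum on
  every small group we can enumerate.
* **Distances** — cumulative Kosambi distances,
  d = 25·ln((1+2r)/(1−2r)) cM, of the adjacent fractions; adjacent
  fractions are clamped below 0.5 (at 0.49) to guard the pole in sparse
  groups.
* **Orientation and assignment** — a group's chromosome is the majority
  vote of its members' physical evidence (ties unassign); fragments of one
  chromosome are merged and re-ordered; a group is flipped when its
  short-arm markers sit below its long-arm ones.
* **Reintegration** — every bin member enters the final map at its
  representative's cM; dropped representatives remove their bins.

Summaries report average chromosome length at integer cM and marker
spacing at one decimal — the conventional precisions for these
statistics — via `mapSummaryStats()` and `stageCounts()`, which work
equally on published table inputs.

## Consensus maps

`consensusChromosome()` assigns each marker a consensus chromosome:
majority over component maps; a two-way tie falls back to aneuploid
evidence, then survey annotation (either must name one of the tied
candidates); otherwise a seeded random pick, so duplicate resolution is
reproducible under the global seed.

`mergeMaps()` is an unweighted, order-respecting merge: every ordered pair
in every component contributes a precedence edge (co-located markers
contribute none), opposing pairs keep the direction supported by more
components (ties keep the larger cM separation), residual cycles — the
pairwise majority need not be transitive — are broken by a minimum-weight
feedback arc set, and the deleted-edge count is reported (zero for
conflict-free inputs). Because linkage-group orientation is only defined
up to reversal, each component chromosome is first rescaled to the mean
component span and flipped if its shared markers run against the first
component carrying them. Positions are a least-absolute-deviation fit —
per-marker medians of the rescaled component positions made monotone along
the topological order by L1 isotonic regression (pool-adjacent-violators
with weighted medians). No interval or weighting parameters exist by
design: the simplest order-respecting unweighted merge is the baseline
against which anything more elaborate would need to justify itself.

## Ordination and introgression segments

Pairwise similarity is the share of identical called genotypes among
markers called in both accessions (`similarityMatrix()`); pairs with no
co-called marker are flagged undefined. "Shared" is read as *identical
calls*, the only reading under which two different lines score below 1;
`NN` counts as an ordinary genotype here. Principal coordinates
(`classicalMds()`) embed d = 1 − s by classical MDS; negative eigenvalues
(the similarity need not be Euclidean) are truncated and reported.

For graphical genotypes, calls are recoded per marker by frequency rank
(`recodeGenotypes()`): modal class 3, rarest 1, anything between 2,
frequency ties broken lexicographically with the smaller symbol taking the
higher code. Accessions are clustered by UPGMA on mean absolute code
difference (`clusterAccessions()`); the linkage and metric are this
package's choice — UPGMA at an interval-scale metric is the default of
most graphical-genotype heatmap tools.

`detectSegments()` scans each chromosome's bins for a consistent carrier
set: an accession is a carrier in a bin when ≥ 90% of its scored loci
carry code 1, and a bin supports a segment when the carriers number at
least `carriersMin` (default 2) and the remaining accessions jointly carry
code 3 at ≥ 90% of their scored cells. Maximal runs of ≥ `minBins`
(default 4 — the smallest block published with confidence spans 4 bins) of
consecutive bins with an *identical* carrier set are reported with their
cM span, bin and marker counts. Carriers are identified directly per bin
rather than seeded from dendrogram clades: on panels where blocks are
detectable at all the two approaches agree, and the direct rule is exactly
testable. The complement condition is aggregated over cells, not enforced
per accession, so a single stray call does not veto a bin. The pipeline
excludes CRBT markers before calling segments — below-threshold markers
are half no-call and half noise, and no analysis keeps them.

## The synthetic-data generator

The generator emulates, under one integer seed with deterministic
sub-streams:

* **DH populations** — gametes as an interference-free Markov chain along
  each chromosome with per-interval switch probability
  `inverseKosambi(Δd)`, so estimated maps are Kosambi-consistent with the
  generating truth by construction (explicit chiasma-interference
  simulation is out of scope). Missing calls are injected independently
  per call — real missingness is weakly marker-correlated, but only a 20%
  filter threshold is documented, not a missingness model. Distortion
  resamples chosen markers at a shifted allele frequency, independent of
  neighbours, which makes the chi-square test's power analytic.
* **Panels** — each marker drawn from one of the six performance classes;
  the default class mixture is the category spectrum of a polyploid wheat
  array screen (6.5% PHR, 54.9% NMH, 5.2% OTV, 17.6% MHR, 2.9% CRBT,
  12.8% Other). Class rules are *enforced* by construction, so truth
  classes are exact and the classifier's confusion matrix is diagonal at
  zero noise. Between-group divergence is a group-level allele-frequency
  shift with alternating sign.
* **Aneuploid screens** — a uniform euploid background (`AA`) with the
  lesion's markers set to `NC`; centromeres default to 0.45 of the
  chromosome length.
* **Introgressions** — a donor genotype written over the chosen
  accessions at every marker inside a cM span; markers where the donor
  equals the only existing class stay monomorphic and carry no signal.

True maps place markers on a 0.1-cM grid with several markers per
position, because binning — and everything downstream of it — only makes
sense on data with true co-segregation. What the generator does *not*
emulate: intensity-space cluster geometry, homoeologous cross-
hybridization, read-level noise, genotyping-batch effects, or
population structure beyond the group-shift model. Passing tests therefore
demonstrate the correctness of the algorithms under their stated
assumptions, not robustness to every artefact of real array data.

## Validation problem sizes and numerical choices

The package validates itself on: a 3-chromosome, 200-marker, 150-line DH
population (order recovery |Kendall τ| and map-length error), 10 000
unlinked simulated markers at 100 lines (distortion-test size — unlinked,
because the test's size is a marginal property and linkage only reduces
the effective number of draws), exhaustive SARF enumeration for groups of
≤ 7 markers, a complete six-chromosome nullisomic panel, a 1000-marker
two-subpopulation ordination, and implanted 30-cM donor blocks in 3 of 60
lines on a narrow (monomorphic-dominated) panel — the regime in which
rare-haplotype blocks are observable at all. Floating-point comparisons in
ordering use a 10⁻¹² slack; SARF optima are compared by objective value,
since distinct orders can tie exactly. cM is stored and written at 0.1
precision throughout, matching the resolution at which such maps are
reported.

## Known limitations

Two-point estimation only (no multipoint likelihood, no EM for dominant
markers); DH designs only; the consensus merge is a simplified
order-respecting LAD fit, not an iterative interval-programming consensus;
the segment caller assumes a dominant shared background haplotype and will
not find blocks in highly admixed panels; and physical evidence is
consumed as given — no cytogenetic breakpoint estimation.
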