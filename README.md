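# IntroMap

Downstream analysis for ultra-high-density SNP genotyping arrays in
hexaploid wheat (*Triticum aestivum*) and its secondary and tertiary gene
pools. Wheat breeding leans on introgression of chromosome segments from
wild relatives (rye 1RS on 1BS, *Ae. ventricosa* on 7DL carrying *Pch1*,
...), but tracking those segments — and the linkage drag they bring —
requires dense, validated markers and genetic maps. This package
implements the analysis stages that turn raw array genotype calls into
those resources, for anyone working with polyploid SNP-array data:

* **Marker QC** — classification of every marker into the six standard
  performance categories: Poly High Resolution (PHR), No Minor Homozygote
  (NMH), Off-Target Variant (OTV, with a null-allele cluster), Mono High
  Resolution (MHR), Call Rate Below Threshold (CRBT), and Other; call
  rates, polymorphism counts between accession groups, and
  codominant/dominant/partially-codominant accounting.
* **Physical assignment** — chromosome (and arm-interval) localization of
  markers from nullisomic/tetrasomic and terminal-deletion aneuploid
  stocks: a marker absent in exactly one lesion maps to that lesion.
* **Linkage maps** — doubled-haploid two-point mapping: missing filter,
  co-segregation binning, segregation-distortion χ² filter, grouping at
  LOD ≥ 6 and rf ≤ 0.3, seriation with window-5 rippling minimizing the
  sum of adjacent recombination fractions (SARF), Kosambi distances
  d = 25·ln((1+2r)/(1−2r)) cM, and reintegration of binned markers.
* **Consensus map** — majority-rule consensus chromosomes and an
  unweighted, order-respecting merge of component maps (precedence graph,
  minimal cycle-breaking, order-constrained least-absolute-deviation
  positions).
* **Structure & introgression** — pairwise genotype similarity
  s(a,b) = identical calls / co-called markers, principal-coordinate
  (classical MDS) ordination, frequency-rank genotype coding
  (3 = modal, 1 = rarest), UPGMA clustering, and detection of alien
  introgression segments as runs of map bins where a fixed carrier set
  holds the rare haplotype.
* **Synthetic data** — a seeded generator for every input above (DH
  populations with Kosambi-consistent recombination, six-class marker
  panels, aneuploid screens, implanted donor blocks), so each stage is
  testable against a known truth.

See the methods vignette (`vignettes/wheat-array-pipeline.Rmd`) for the
models, parameter defaults and design decisions.

## Worked example

The bundled demo configuration simulates a 3-chromosome truth map, a
50-accession panel with a 30-cM donor block implanted in three lines on
1B, an aneuploid screen, and three DH populations, then runs every stage:

```r
library(IntroMap)
cfg <- readPipelineConfig(system.file("extdata", "demo_config.yaml",
                                      package = "IntroMap"))
out <- runPipeline(cfg)

out$qc$categoryCounts
#>   PHR   NMH   OTV   MHR  CRBT Other
#>    20     0     0   116     4    10

s <- out$maps$AxC$summary
sprintf("AxC frame: %d markers, %.1f cM, avg chromosome %d cM, one marker every %.1f cM",
        s$counts$frameMapped, s$totalLength, s$avgChromosomeLength,
        s$markerSpacing)
#> "AxC frame: 32 markers, 249.6 cM, avg chromosome 83 cM, one marker every 7.8 cM"

out$segments
#>             accessions chromosome startCM endCM nBins nMarkers
#> 1 ACC001;ACC002;ACC003         1B    31.3  59.6     6       19
```

Reading the output: the narrow elite panel is dominated by monomorphic
(MHR) markers; the 19 markers the donor block overwrote become polymorphic
codominant (PHR) markers. The first DH population yields a 32-marker
frame over three linkage groups, and the segment caller recovers exactly
the three implanted carriers as one 6-bin block on 1B (positions are on
the consensus-map scale). `runPipeline(cfg, outDir = "...")` writes every
artifact (genotype CSV, QC and assignment TSVs, map TSVs, segments TSV,
run log) to disk; a thin command-line wrapper lives at
`inst/scripts/intromap.R`.

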