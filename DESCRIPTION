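Package: IntroMap
Title: Marker Classification, Linkage and Consensus Mapping, and
    Introgression Detection for High-Density Wheat SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of high-density SNP genotyping arrays in
    hexaploid wheat and its relatives: classification of array markers into
    the six standard performance categories (PHR, NMH, OTV, MHR, CRBT,
    Other), physical chromosome assignment from nullisomic/tetrasomic and
    terminal-deletion aneuploid stocks, doubled-haploid two-point linkage
    map construction (binning, segregation-distortion filtering, LOD/rf
    grouping, seriation with window rippling, Kosambi distances), unweighted
    order-respecting consensus map merging, principal-coordinate ordination
    of genotype similarity, and detection of alien introgression segments as
    rare-haplotype blocks along the genetic map. A seeded synthetic-data
    generator emulates doubled-haploid populations, multi-group accession
    panels, aneuploid stocks and implanted introgressions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
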