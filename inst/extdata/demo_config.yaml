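# Demonstration pipeline configuration: a small three-chromosome panel with
# three doubled-haploid populations and one implanted donor block.
seed: 1
nChromosomes: 3
chromosomeLength: 120
nMarkers: 150
nPositions: 60
populations:
  AxC: 130
  SxR: 64
  SxO: 60
panelGroups:
  elite: 30
  landrace: 20
# a narrow elite panel: mostly monomorphic markers, as in a within-bread-
# wheat screen, so donor haplotype blocks stand out against the background
sim:
  classMix:
    PHR: 0.0
    NMH: 0.0
    OTV: 0.0
    MHR: 0.92
    CRBT: 0.03
    Other: 0.05
introgression:
  accessions: 3
  chromosome: 1B
  span: [40, 70]
  donorCode: BB
minBins: 4
carriersMin: 2
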