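twoMarkerMap <- function(gap, length = 100) {
  TrueMap(data.frame(name = "1A", length = length, centromere = length / 2),
          data.frame(marker = c("M1", "M2"), chromosome = "1A",
                     cM = c(10, 10 + gap)))
}

test_that("DH simulation reproduces the Kosambi recombination fraction", {
  tm <- twoMarkerMap(gap = 10)
  cfg <- simConfig(nLines = 50000, missingRate = 0, distortedFraction = 0,
                   seed = 42)
  pop <- simulateDhPopulation(tm, cfg)$pop
  est <- estimateRf(genotypeCalls(pop)["M1", ], genotypeCalls(pop)["M2", ])
  expected <- 0.5 * tanh(0.2)   # 0.098688
  se <- sqrt(expected * (1 - expected) / 50000)
  expect_lt(abs(est$r - expected), 3 * se)
})

test_that("co-located markers never recombine", {
  tm <- twoMarkerMap(gap = 0)
  cfg <- simConfig(nLines = 5000, missingRate = 0, distortedFraction = 0,
                   seed = 1)
  pop <- simulateDhPopulation(tm, cfg)$pop
  est <- estimateRf(genotypeCalls(pop)["M1", ], genotypeCalls(pop)["M2", ])
  expect_identical(est$R, 0L)
  expect_equal(est$r, 0)
})

test_that("missing calls are injected at the configured rate", {
  tm <- makeTrueMap(stats::setNames(100, "1A"), nMarkers = 20,
                    nPositions = 20, seed = 2)
  cfg <- simConfig(nLines = 10000, missingRate = 0.2, distortedFraction = 0,
                   seed = 2)
  pop <- simulateDhPopulation(tm, cfg)$pop
  missFrac <- rowMeans(is.na(genotypeCalls(pop)))
  expect_lt(abs(mean(missFrac) - 0.2), 0.01)
})

test_that("undistorted markers segregate 1:1 and distortion shifts them", {
  tm <- makeTrueMap(stats::setNames(200, "1A"), nMarkers = 40,
                    nPositions = 40, seed = 3)
  cfg <- simConfig(nLines = 4000, missingRate = 0, distortedFraction = 0.25,
                   distortionAlleleFreq = 0.8, seed = 3)
  out <- simulateDhPopulation(tm, cfg)
  calls <- genotypeCalls(out$pop)
  fA <- rowMeans(calls == "A")
  dist <- rownames(calls) %in% out$truth$distortedMarkers
  expect_equal(length(out$truth$distortedMarkers), 10)
  expect_lt(max(abs(fA[!dist] - 0.5)), 0.05)
  expect_lt(max(abs(fA[dist] - 0.8)), 0.05)
})

test_that("generators are bit-reproducible for a fixed seed", {
  tm <- makeTrueMap(seed = 9)
  cfg <- simConfig(nLines = 50, seed = 9)
  expect_identical(simulateDhPopulation(tm, cfg),
                   simulateDhPopulation(tm, cfg))
  groups <- data.frame(accession = sprintf("A%02d", 1:20),
                       group = rep(c("g1", "g2"), each = 10))
  expect_identical(simulatePanel(tm, groups, cfg),
                   simulatePanel(tm, groups, cfg))
  expect_identical(makeTrueMap(seed = 9)@markers, tm@markers)
})

test_that("panel classes are constructed to their defining rules", {
  tm <- makeTrueMap(stats::setNames(100, "1A"), nMarkers = 60,
                    nPositions = 30, seed = 4)
  groups <- data.frame(accession = sprintf("A%02d", 1:40),
                       group = rep(c("g1", "g2"), each = 20))
  oneClass <- function(cls) {
    mix <- stats::setNames(rep(0, 6),
                           c("PHR", "NMH", "OTV", "MHR", "CRBT", "Other"))
    mix[cls] <- 1
    simulatePanel(tm, groups, simConfig(seed = 4, classMix = mix))$matrix
  }
  # MHR: exactly one called genotype class everywhere
  mhr <- genotypeCalls(oneClass("MHR"))
  nClasses <- apply(mhr, 1, function(r) length(unique(r[r != "NC"])))
  expect_true(all(nClasses == 1))
  # CRBT: every call rate strictly below the threshold
  expect_true(all(callRate(oneClass("CRBT")) < 0.8))
  # PHR: all three clusters, at least two minor homozygotes
  phr <- genotypeCalls(oneClass("PHR"))
  ok <- apply(phr, 1, function(r)
    all(c("AA", "AB", "BB") %in% r) && min(sum(r == "AA"), sum(r == "BB")) >= 2)
  expect_true(all(ok))
  # OTV: null-homozygote cluster plus two ordinary classes
  otv <- genotypeCalls(oneClass("OTV"))
  ok <- apply(otv, 1, function(r)
    sum(r == "NN") > 0 &&
      length(intersect(unique(r), c("AA", "AB", "BB"))) >= 2)
  expect_true(all(ok))
})

test_that("class mix is invalid unless it sums to one", {
  expect_error(simConfig(classMix = c(PHR = 0.5, NMH = 0.4, OTV = 0,
                                      MHR = 0, CRBT = 0, Other = 0)),
               "summing to 1")
})

test_that("aneuploid stocks lose exactly the markers of their lesion", {
  tm <- makeTrueMap(stats::setNames(c(100, 100), c("1A", "2B")),
                    nMarkers = 60, nPositions = 40, seed = 6)
  mk <- trueMarkerPositions(tm)
  panel <- aneuploidPanel(stock = c("N1A", "D2BL"),
                          kind = c("nulli_tetra", "deletion"),
                          chromosome = c("1A", "2B"),
                          arm = c(NA, "L"), retainedFraction = c(NA, 0.5))
  mat <- simulateAneuploids(tm, panel)
  calls <- genotypeCalls(mat)
  on1A <- mk$chromosome == "1A"
  expect_true(all(calls[on1A, "N1A"] == "NC"))
  expect_true(all(calls[!on1A, "N1A"] != "NC"))
  # distal 50% of the 2B long arm: centromere 45, deleted (72.5, 100]
  cen <- 0.45 * 100
  cut <- cen + 0.5 * (100 - cen)
  inDel <- mk$chromosome == "2B" & mk$cM > cut
  expect_true(all(calls[inDel, "D2BL"] == "NC"))
  expect_true(all(calls[!inDel, "D2BL"] != "NC"))
  # empty panel leaves a euploid-only matrix
  empty <- aneuploidPanel(character(0), character(0), character(0))
  mat0 <- simulateAneuploids(tm, empty)
  expect_true(all(genotypeCalls(mat0) == "AA"))
  expect_error(aneuploidPanel("D", "deletion", "2B", "L", 1.2),
               "retained fraction")
})

test_that("introgression injection edits exactly the requested block", {
  tm <- makeTrueMap(stats::setNames(100, "1A"), nMarkers = 30,
                    nPositions = 20, seed = 8)
  groups <- data.frame(accession = sprintf("A%02d", 1:10),
                       group = rep(c("g1", "g2"), each = 5))
  mat <- simulatePanel(tm, groups, simConfig(seed = 8))$matrix
  # whole chromosome
  all <- injectIntrogression(mat, "A01", "1A", c(0, 100), "BB", tm)
  expect_true(all(genotypeCalls(all)[, "A01"] == "BB"))
  # zero-width span: identity
  same <- injectIntrogression(mat, "A01", "1A", c(50, 50), "BB", tm)
  expect_identical(genotypeCalls(same), genotypeCalls(mat))
  # untouched outside the span
  part <- injectIntrogression(mat, "A01", "1A", c(20, 40), "BB", tm)
  mk <- trueMarkerPositions(tm)
  outside <- mk$marker[mk$cM < 20 | mk$cM > 40]
  expect_identical(genotypeCalls(part)[outside, ],
                   genotypeCalls(mat)[outside, ])
  expect_error(injectIntrogression(mat, "NOPE", "1A", c(0, 10), "BB", tm),
               "unknown accession")
})
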