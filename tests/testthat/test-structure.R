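test_that("similarity is the share of identical co-called genotypes", {
  calls <- rbind(
    c("AA", "AA", "BB"),
    c("AB", "AB", "AA"),
    c("BB", "BB", "AA"),
    c("NN", "NN", "AA"),
    c("AA", "NC", "AA"),
    c("AA", "AA", "NC"),
    c("BB", "AA", "AA"),
    c("AA", "BB", "BB"))
  dimnames(calls) <- list(sprintf("M%d", 1:8), c("a", "b", "c"))
  s <- similarityMatrix(CallMatrix(calls))
  expect_equal(s$similarity["a", "a"], 1)
  # a vs b: co-called at M1-M4, M6-M8 (7); identical at M1-M4 and M6 (5)
  expect_equal(s$informative["a", "b"], 7)
  expect_equal(s$similarity["a", "b"], 5 / 7)
  expect_equal(s$similarity, t(s$similarity))
  # marker permutation leaves it unchanged
  s2 <- similarityMatrix(CallMatrix(calls[sample(8), , drop = FALSE]))
  expect_equal(s2$similarity, s$similarity)
  # fully discordant accessions score zero
  disc <- rbind(c("AA", "BB"), c("AB", "AA"))
  dimnames(disc) <- list(c("M1", "M2"), c("x", "y"))
  expect_equal(similarityMatrix(CallMatrix(disc))$similarity["x", "y"], 0)
})

test_that("classical MDS embeds the similarity distances", {
  # points on a line: an exactly Euclidean distance matrix
  p <- c(0, 0.1, 0.35, 0.8)
  d <- abs(outer(p, p, "-"))
  s <- list(similarity = 1 - d, informative = matrix(10, 4, 4))
  dimnames(s$similarity) <- list(letters[1:4], letters[1:4])
  fit <- classicalMds(s, k = 2)
  rec <- as.matrix(dist(fit$points))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # identical accessions collapse to one point
  s2 <- s
  s2$similarity["a", "b"] <- s2$similarity["b", "a"] <- 1
  s2$similarity["a", "c"] <- s2$similarity["c", "a"] <- 1 - 0.25
  s2$similarity["b", "c"] <- s2$similarity["c", "b"] <- 1 - 0.25
  s2$similarity["a", "d"] <- s2$similarity["d", "a"] <- 1 - 0.7
  s2$similarity["b", "d"] <- s2$similarity["d", "b"] <- 1 - 0.7
  fit2 <- classicalMds(s2, k = 2)
  expect_lt(sum((fit2$points["a", ] - fit2$points["b", ])^2), 1e-12)
})

test_that("MDS separates divergent subpopulations on coordinate one", {
  tm <- makeTrueMap(stats::setNames(300, "1A"), nMarkers = 1000,
                    nPositions = 300, seed = 51)
  groups <- data.frame(accession = sprintf("A%03d", 1:50),
                       group = rep(c("g1", "g2"), each = 25))
  cfg <- simConfig(seed = 51,
                   classMix = c(PHR = 1, NMH = 0, OTV = 0, MHR = 0,
                                CRBT = 0, Other = 0),
                   groupShift = 0.45)
  ps <- simulatePanel(tm, groups, cfg)
  fit <- classicalMds(similarityMatrix(ps$matrix))
  c1 <- fit$points[, 1]
  g1 <- c1[groups$group == "g1"]; g2 <- c1[groups$group == "g2"]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
})

test_that("genotype recoding ranks classes by frequency with tie-breaks", {
  calls <- rbind(c("AA", "AA", "AA", "BB", "AB"),
                 c("AA", "AA", "AA", "AA", "AA"),
                 c("AA", "AA", "BB", "BB", "NC"),
                 c("AA", "AA", "AA", "BB", "BB"))
  dimnames(calls) <- list(sprintf("M%d", 1:4), sprintf("S%d", 1:5))
  coded <- recodeGenotypes(CallMatrix(calls))
  # ties AB/BB broken lexicographically: AB takes the higher code
  expect_equal(unname(coded[1, ]), c(3L, 3L, 3L, 1L, 2L))
  expect_equal(unname(coded[2, ]), rep(3L, 5))        # monomorphic
  expect_equal(unname(coded[3, ]), c(3L, 3L, 1L, 1L, NA))
  expect_equal(unname(coded[4, ]), c(3L, 3L, 3L, 1L, 1L))
  # code histogram reproduces the class histogram
  expect_equal(sum(coded[1, ] == 3), 3)
  expect_equal(sum(coded[3, ] == 1, na.rm = TRUE), 2)
})

test_that("UPGMA clustering merges duplicated accessions at height zero", {
  calls <- rbind(c("AA", "AA", "BB", "AB"),
                 c("BB", "BB", "AA", "AA"),
                 c("AA", "AA", "AA", "BB"))
  dimnames(calls) <- list(sprintf("M%d", 1:3), c("dup1", "dup2", "z", "w"))
  cl <- clusterAccessions(recodeGenotypes(CallMatrix(calls)))
  expect_setequal(cl$order, c("dup1", "dup2", "z", "w"))
  first <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first], c("dup1", "dup2"))
  expect_equal(cl$hclust$height[1], 0)
})

segmentFixture <- function(seed, spans = list(c(40, 70)), carriers = 1:3) {
  tm <- makeTrueMap(stats::setNames(c(120, 120), c("1A", "1B")),
                    nMarkers = 120, nPositions = 50, seed = seed)
  groups <- data.frame(accession = sprintf("A%03d", 1:60),
                       group = rep(c("g1", "g2"), each = 30))
  cfg <- simConfig(seed = seed,
                   classMix = c(PHR = 0, NMH = 0, OTV = 0, MHR = 0.9,
                                CRBT = 0, Other = 0.1))
  mat <- simulatePanel(tm, groups, cfg)$matrix
  for (sp in spans)
    mat <- injectIntrogression(mat, sprintf("A%03d", carriers), "1B", sp,
                               "BB", tm)
  list(tm = tm, mat = mat, map = GeneticMap(trueMarkerPositions(tm)))
}

test_that("implanted donor blocks are recovered with exact bin bounds", {
  f <- segmentFixture(seed = 52)
  segs <- detectSegments(recodeGenotypes(f$mat), f$map)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$accessions, "A001;A002;A003")
  expect_equal(segs$chromosome, "1B")
  truth <- trueMarkerPositions(f$tm)
  binPos <- sort(unique(truth$cM[truth$chromosome == "1B"]))
  inSpan <- binPos[binPos >= 40 & binPos <= 70]
  expect_equal(segs$startCM, min(inSpan))
  expect_equal(segs$endCM, max(inSpan))
  expect_equal(segs$nBins, length(inSpan))
})

test_that("clean panels yield no segments and runs respect minBins", {
  f <- segmentFixture(seed = 53, spans = list())
  segs0 <- detectSegments(recodeGenotypes(f$mat), f$map)
  expect_equal(nrow(segs0), 0)
  # widening minBins never increases the segment count
  f2 <- segmentFixture(seed = 53)
  coded <- recodeGenotypes(f2$mat)
  counts <- vapply(c(2, 4, 6, 10, 30), function(mb)
    nrow(detectSegments(coded, f2$map, minBins = mb)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("two disjoint blocks on one chromosome give two segments", {
  f <- segmentFixture(seed = 54, spans = list(c(10, 30), c(80, 110)))
  segs <- detectSegments(recodeGenotypes(f$mat), f$map, minBins = 3)
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$chromosome == "1B"))
  o <- order(segs$startCM)
  expect_lt(segs$endCM[o[1]], segs$startCM[o[2]])
})
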