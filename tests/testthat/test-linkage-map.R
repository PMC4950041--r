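test_that("missing-data filter removes strictly-more-than the threshold", {
  # 100 lines: 21 missing removed, exactly 20 retained
  pop <- dhFromStrings(list(
    M1 = paste(c(rep("-", 21), rep("A", 79)), collapse = ""),
    M2 = paste(c(rep("-", 20), rep("A", 40), rep("B", 40)), collapse = ""),
    M3 = paste(rep(c("A", "B"), 50), collapse = "")))
  kept <- filterMissing(pop, mapConfig())
  expect_identical(kept, c("M2", "M3"))
})

test_that("heterozygous calls count as missing for mapping", {
  pop <- dhFromStrings(list(
    M1 = paste(c(rep("H", 25), rep("A", 75)), collapse = ""),
    M2 = paste(rep(c("A", "B"), 50), collapse = "")))
  expect_identical(filterMissing(pop, mapConfig()), "M2")
})

test_that("binning joins identical and complementary patterns only", {
  base <- paste(rep(c("A", "B"), 10), collapse = "")
  flip <- chartr("AB", "BA", base)
  differ <- sub("^A", "B", base)        # one doubly-called difference
  pop <- dhFromStrings(list(M1 = base, M2 = base, M3 = flip, M4 = differ))
  bn <- binMarkers(pop, mapConfig())
  expect_length(bn$bins, 1)
  expect_setequal(bn$bins[[1]], c("M1", "M2", "M3"))
  expect_identical(bn$singletons, "M4")
  # too little overlap: no bin
  short <- dhFromStrings(list(M1 = "ABABAB", M2 = "ABABAB"))
  bnShort <- binMarkers(short, mapConfig())
  expect_length(bnShort$bins, 0)
})

test_that("binning separates distinct positions at 50+ lines", {
  # 10 true bins, 15 cM apart: co-segregation across bins is vanishingly rare
  pos <- seq(10, 145, by = 15)
  mk <- data.frame(marker = sprintf("AX%03d", 1:40), chromosome = "1A",
                   cM = rep(pos, each = 4))
  tm <- TrueMap(data.frame(name = "1A", length = 160, centromere = 70), mk)
  cfg <- simConfig(nLines = 60, missingRate = 0, distortedFraction = 0,
                   seed = 31)
  pop <- simulateDhPopulation(tm, cfg)$pop
  bn <- binMarkers(pop, mapConfig())
  truth <- trueMarkerPositions(tm)
  # every bin is pure: one true position per bin (zero false merges)
  purity <- vapply(bn$bins, function(b)
    length(unique(truth$cM[match(b, truth$marker)])), numeric(1))
  expect_true(all(purity == 1))
  # duplicated columns always land together
  expect_equal(length(bn$bins) + length(bn$singletons), 10)
})

test_that("representative selection minimizes missing data, seeded ties", {
  pop <- dhFromStrings(list(
    M1 = paste(c(rep("A", 18), "-", "-"), collapse = ""),
    M2 = paste(rep("A", 20), collapse = ""),
    M3 = paste(rep("A", 20), collapse = "")))
  expect_equal(selectRepresentative(c("M1", "M2"), pop), "M2")
  expect_equal(selectRepresentative("M1", pop), "M1")
  pick <- selectRepresentative(c("M2", "M3"), pop, seed = 5)
  expect_identical(pick, selectRepresentative(c("M2", "M3"), pop, seed = 5))
  expect_true(pick %in% c("M2", "M3"))
})

test_that("distortion chi-square matches the closed form", {
  even <- testDistortion(c(50, 50))
  expect_equal(even$statistic, 0)
  expect_equal(even$p.value, 1)
  expect_true(even$keep)
  skew <- testDistortion(c(70, 30))
  expect_equal(skew$statistic, 16)                 # (20^2/50) * 2
  expect_equal(skew$p.value, pchisq(16, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(skew$p.value - 6.3e-5), 1e-5)
  expect_false(skew$keep)
  mild <- testDistortion(c(60, 40))
  expect_equal(mild$statistic, 4)
  expect_equal(round(mild$p.value, 4), 0.0455)
  expect_false(mild$keep)
  expect_error(testDistortion(rep(NA_character_, 5)), "no informative")
})

test_that("distortion test holds its nominal size on simulated DH markers", {
  # 10 000 undistorted markers, 100 lines: rejection rate near alpha
  set.seed(77)
  a <- rbinom(10000, 100, 0.5)
  rej <- vapply(a, function(x) !testDistortion(c(x, 100 - x))$keep,
                logical(1))
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("recombination fraction estimation counts and phases", {
  x <- rep(c("A", "B"), 50)
  expect_equal(estimateRf(x, x)$r, 0)
  expect_equal(estimateRf(x, chartr("AB", "BA", x))$r, 0)  # phase flip
  y <- x; y[1:10] <- chartr("AB", "BA", y[1:10])
  est <- estimateRf(x, y)
  expect_equal(est$r, 0.10)
  expect_equal(est$n, 100L)
  # symmetry
  expect_identical(estimateRf(x, y), estimateRf(y, x))
  expect_true(is.na(estimateRf(x, rep(NA_character_, 100))$r))
  # matrix form agrees with the pairwise form
  pop <- dhFromStrings(list(M1 = paste(x, collapse = ""),
                            M2 = paste(y, collapse = "")))
  rf <- rfMatrix(pop)
  expect_equal(rf$r["M1", "M2"], 0.10)
  expect_equal(rf$r, t(rf$r))
})

test_that("LOD score matches its closed form", {
  expect_equal(lodScore(0.5, 7, 100), 0)
  expect_equal(lodScore(0.1, 10, 100),
               10 * log10(0.1) + 90 * log10(0.9) + 100 * log10(2))
  expect_equal(round(lodScore(0.1, 10, 100), 2), 15.98)
  expect_equal(lodScore(0, 0, 50), 50 * log10(2))   # 15.05, no 0*log(0)
  expect_error(lodScore(0.6, 1, 10), "0, 0.5")
  expect_error(lodScore(0.1, 11, 10), "R <= N")
})

test_that("grouping links by LOD and rf jointly", {
  r <- matrix(c(0, 0.05, 0.45,
                0.05, 0, 0.45,
                0.45, 0.45, 0), 3, 3)
  rf <- rfFromMatrix(r)
  gr <- groupMarkers(rf, mapConfig())
  expect_length(gr$groups, 1)
  expect_setequal(gr$groups[[1]], c("M01", "M02"))
  expect_identical(gr$unlinked, "M03")
  # r below rfMax but too few informative lines to reach LOD 6: unlinked
  rfWeak <- rfFromMatrix(matrix(c(0, 0.25, 0.25, 0), 2, 2))
  rfWeak$n[] <- 10; rfWeak$R <- round(rfWeak$r * 10)
  expect_length(groupMarkers(rfWeak, mapConfig())$groups, 0)
})

test_that("ordering recovers collinear markers and the SARF optimum", {
  # three collinear markers
  rf3 <- rfFromPositions(c(0, 10, 20))
  og <- orderGroup(c("M01", "M02", "M03"), rf3, mapConfig())
  expect_true(identical(og$order, c("M01", "M02", "M03")) ||
                identical(og$order, c("M03", "M02", "M01")))
  # matches the exhaustive SARF optimum for all groups of <= 7 markers
  for (m in 4:7) {
    for (rep in 1:3) {
      rf <- rfFromPositions(sort(runif(m, 0, 60)), noise = 0.02,
                            seed = m * 10 + rep)
      mk <- rownames(rf$r)
      got <- orderGroup(mk, rf, mapConfig())
      best <- exhaustiveOrder(mk, rf)
      expect_equal(got$sarf, best$sarf, tolerance = 1e-10)
    }
  }
})

test_that("positions are cumulative Kosambi distances", {
  # rf derived exactly from true gaps: positions recover them (either
  # orientation), since kosambi(inverseKosambi(d)) = d
  rf <- rfFromPositions(c(0, 10, 30))
  og <- orderGroup(rownames(rf$r), rf, mapConfig())
  expect_true(identical(round(og$cM, 6), c(0, 10, 30)) ||
                identical(round(og$cM, 6), c(0, 20, 30)))
  expect_equal(max(og$cM), 30)
})

test_that("bin reintegration conserves members and positions", {
  frame <- data.frame(marker = c("R1", "R2"), chromosome = "1A",
                      cM = c(0, 12.5))
  bins <- list(c("R1", "X1", "X2"), c("R2", "X3"))
  map <- reintegrateBins(frame, bins, c("R1", "R2"))
  tab <- mapTable(map)
  expect_equal(nrow(tab), 5)                    # sum of surviving bin sizes
  expect_setequal(tab$marker[tab$cM == 0], c("R1", "X1", "X2"))
  expect_setequal(tab$marker[tab$cM == 12.5], c("R2", "X3"))
  # a dropped representative removes its whole bin
  map2 <- reintegrateBins(frame[1, ], bins[1], "R1")
  expect_false(any(c("R2", "X3") %in% markerNames(map2)))
  expect_error(reintegrateBins(frame, bins[1], "R1"), "represent no bin")
})

test_that("map summary arithmetic reproduces printed-style statistics", {
  expect_equal(mapSummaryStats(3663, 21)$avgChromosomeLength, 174)
  expect_equal(mapSummaryStats(7745, 21, 2167),
               list(avgChromosomeLength = 369, markerSpacing = 3.6))
  expect_equal(mapSummaryStats(2819, 21, 655)$markerSpacing, 4.3)
  expect_equal(stageCounts(830, 62)$core, 768)
  expect_equal(stageCounts(2361, 113, 2167), list(core = 2248, unlinked = 81))
})

test_that("full map construction recovers simulated order and length", {
  tm <- makeTrueMap(seed = 41)
  cfg <- simConfig(nLines = 150, seed = 41)
  pop <- simulateDhPopulation(tm, cfg)$pop
  built <- buildMap(pop, mapConfig(seed = 41))
  truth <- trueMarkerPositions(tm)
  tab <- mapTable(built$map)
  # stage counts conserve the input
  cnt <- built$summary$counts
  binned <- sum(lengths(binMarkers(pop, mapConfig(),
                                   filterMissing(pop, mapConfig()))$bins))
  expect_equal(cnt$input,
               cnt$missingFiltered + cnt$uniquePattern + binned)
  # per linkage group, order correlates with truth
  for (lg in unique(tab$chromosome)) {
    s <- tab[tab$chromosome == lg, ]
    tau <- cor(s$cM, truth$cM[match(s$marker, truth$marker)],
               method = "kendall")
    expect_gte(abs(tau), 0.95)
    # one true chromosome per linkage group
    expect_equal(length(unique(truth$chromosome[match(s$marker,
                                                      truth$marker)])), 1)
  }
})

test_that("map positions are invariant under marker relabelling", {
  rf <- rfFromPositions(c(5, 15, 40, 41))
  og1 <- orderGroup(rownames(rf$r), rf, mapConfig())
  rf2 <- rf
  relab <- c(M01 = "Z04", M02 = "Z03", M03 = "Z02", M04 = "Z01")
  dimnames(rf2$r) <- dimnames(rf2$n) <- dimnames(rf2$R) <-
    list(relab, relab)
  og2 <- orderGroup(unname(relab), rf2, mapConfig())
  expect_equal(og1$cM, og2$cM)
  expect_identical(unname(relab[og1$order]), og2$order)
})
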