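## Doubled-haploid two-point linkage mapping: missing-data filter, perfect
## co-segregation binning, representative selection, segregation-distortion
## chi-square filter, rf/LOD grouping. Heterozygous calls are treated as
## missing throughout (a DH line is expected homozygous).

#' Mapping configuration
#'
#' @param maxMissing markers with strictly more missing data are removed
#'   (default 0.20).
#' @param alpha significance level of the segregation-distortion chi-square
#'   test (default 0.05).
#' @param lodMin minimum LOD for linkage (default 6).
#' @param rfMax maximum recombination fraction for linkage (default 0.3).
#' @param rippleWindow window size of the order-rippling refinement
#'   (default 5).
#' @param minBinOverlap minimum pairwise-complete lines for two markers to
#'   be binned together (default 10).
#' @param seed integer seed (representative tie-breaks).
#' @return list of class `mapConfig`.
#' @export
mapConfig <- function(maxMissing = 0.20, alpha = 0.05, lodMin = 6,
                      rfMax = 0.3, rippleWindow = 5L, minBinOverlap = 10L,
                      seed = 1L) {
  if (maxMissing <= 0 || maxMissing >= 1) stop("maxMissing must be in (0,1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (rfMax <= 0 || rfMax >= 1) stop("rfMax must be in (0,1)")
  if (lodMin <= 0 || rippleWindow < 2) stop("thresholds must be positive")
  structure(list(maxMissing = maxMissing, alpha = alpha, lodMin = lodMin,
                 rfMax = rfMax, rippleWindow = as.integer(rippleWindow),
                 minBinOverlap = as.integer(minBinOverlap),
                 seed = as.integer(seed)), class = "mapConfig")
}

## parent calls coded +1/-1, missing (NA or H) = 0
.codeDh <- function(pop) {
  calls <- genotypeCalls(pop)
  x <- matrix(0, nrow = nrow(calls), ncol = ncol(calls),
              dimnames = dimnames(calls))
  x[calls == "A"] <- 1
  x[calls == "B"] <- -1
  x
}

#' Filter markers on missing data
#'
#' @param pop a [DhPopulation-class].
#' @param cfg a [mapConfig()].
#' @return character vector of retained marker ids (missing fraction
#'   `<= maxMissing`; heterozygous calls count as missing).
#' @export
filterMissing <- function(pop, cfg = mapConfig()) {
  calls <- genotypeCalls(pop)
  miss <- rowMeans(is.na(calls) | calls == "H")
  rownames(calls)[miss <= cfg$maxMissing]
}

#' Bin markers by perfect co-segregation
#'
#' Two markers fall in one bin when their calls are identical or exactly
#' complementary on every pairwise-complete line (|correlation| = 1, i.e.
#' zero observed recombination), with at least `minBinOverlap` informative
#' lines. Bins are the connected components of this co-segregation graph.
#' Markers with a unique segregation pattern (singleton bins) are reported
#' separately; the mapping pipeline removes them.
#'
#' @param pop a [DhPopulation-class] (already missing-filtered).
#' @param cfg a [mapConfig()].
#' @param markers optional marker subset.
#' @return list with `bins` (list of marker-id vectors, size >= 2) and
#'   `singletons` (marker ids with a unique pattern).
#' @export
binMarkers <- function(pop, cfg = mapConfig(), markers = NULL) {
  x <- .codeDh(pop)
  if (!is.null(markers)) x <- x[markers, , drop = FALSE]
  m <- nrow(x)
  if (m == 0) return(list(bins = list(), singletons = character(0)))
  S <- x %*% t(x)                    # agreements minus disagreements
  O <- abs(x) %*% t(abs(x))          # pairwise-complete overlap
  coseg <- O >= cfg$minBinOverlap & abs(S) == O
  diag(coseg) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(coseg, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(rownames(x), comp)
  sizes <- lengths(groups)
  list(bins = unname(groups[sizes >= 2]),
       singletons = sort(unname(unlist(groups[sizes == 1]))))
}

#' Choose a bin's representative marker
#'
#' The member with the least missing data; ties are broken by a seeded
#' uniform draw.
#'
#' @param members marker ids of one bin.
#' @param pop the [DhPopulation-class].
#' @param seed integer seed for the tie-break.
#' @return one marker id.
#' @export
selectRepresentative <- function(members, pop, seed = 1L) {
  if (length(members) == 0) stop("empty bin")
  if (length(members) == 1) return(members)
  calls <- genotypeCalls(pop)[members, , drop = FALSE]
  miss <- rowMeans(is.na(calls) | calls == "H")
  best <- members[miss == min(miss)]
  if (length(best) == 1) return(best)
  withSeed(deriveSeed(seed, 41L), sample(best, 1))
}

#' Segregation-distortion chi-square test
#'
#' One-degree-of-freedom chi-square of the observed A:B counts against the
#' 1:1 doubled-haploid expectation, on non-missing calls.
#'
#' @param calls character vector of `"A"`/`"B"`/`"H"`/`NA` calls for one
#'   marker, or a two-element count vector `c(nA, nB)`.
#' @param cfg a [mapConfig()] (significance level).
#' @return list with `statistic`, `p.value`, `keep` (TRUE when
#'   `p >= alpha`), `nA`, `nB`.
#' @export
testDistortion <- function(calls, cfg = mapConfig()) {
  if (is.numeric(calls) && length(calls) == 2) {
    a <- calls[1]; b <- calls[2]
  } else {
    a <- sum(calls == "A", na.rm = TRUE)
    b <- sum(calls == "B", na.rm = TRUE)
  }
  n <- a + b
  if (n == 0) stop("no informative calls")
  e <- n / 2
  stat <- (a - e)^2 / e + (b - e)^2 / e
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p.value = p, keep = p >= cfg$alpha,
       nA = a, nB = b)
}

#' Two-point recombination fraction in a DH population
#'
#' Recombinant lines over informative (pairwise non-missing) lines, with the
#' phase chosen so that `r <= 0.5` (complementary parent coding allowed).
#'
#' @param x,y call vectors (`"A"`/`"B"`/`"H"`/`NA`) of the two markers.
#' @return list with `r`, `n` (informative lines) and `R` (recombinant count
#'   after phasing); `r` is `NA` when no line is informative in both.
#' @export
estimateRf <- function(x, y) {
  ok <- x %in% c("A", "B") & y %in% c("A", "B")
  n <- sum(ok)
  if (n == 0) return(list(r = NA_real_, n = 0L, R = NA_integer_))
  mism <- sum(x[ok] != y[ok])
  R <- min(mism, n - mism)
  list(r = R / n, n = n, R = R)
}

#' Pairwise recombination-fraction matrices
#'
#' @param pop a [DhPopulation-class].
#' @param markers optional marker subset.
#' @return list of matrices `r` (phased rf), `n` (informative lines) and
#'   `R` (recombinant counts); `r` is `NA` where `n` is 0.
#' @export
rfMatrix <- function(pop, markers = NULL) {
  x <- .codeDh(pop)
  if (!is.null(markers)) x <- x[markers, , drop = FALSE]
  S <- x %*% t(x)
  O <- abs(x) %*% t(abs(x))
  mism <- (O - S) / 2
  R <- pmin(mism, O - mism)
  r <- ifelse(O > 0, R / O, NA_real_)
  diag(r) <- 0
  list(r = r, n = O, R = R)
}

#' LOD score of two-point linkage
#'
#' `LOD = R log10(r) + (N - R) log10(1 - r) + N log10(2)`, the log10
#' likelihood ratio of linkage at `r` against free recombination, with
#' `0 * log10(0)` taken as 0.
#'
#' @param r recombination fraction in `[0, 0.5]`.
#' @param R recombinant count.
#' @param N informative count, `0 <= R <= N`.
#' @return the LOD score.
#' @export
lodScore <- function(r, R, N) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) stop("r must lie in [0, 0.5]")
  if (any(R < 0 | R > N)) stop("need 0 <= R <= N")
  t1 <- ifelse(R == 0, 0, R * log10(r))
  t2 <- ifelse(N - R == 0, 0, (N - R) * log10(1 - r))
  t1 + t2 + N * log10(2)
}

#' Sort markers into linkage groups
#'
#' Connected components of the graph with an edge between two markers when
#' their LOD is at least `lodMin` AND their recombination fraction is at
#' most `rfMax`. Singleton components are reported as unlinked.
#'
#' @param rf a [rfMatrix()] result for the grouped markers.
#' @param cfg a [mapConfig()].
#' @return list with `groups` (list of marker-id vectors, size >= 2) and
#'   `unlinked` (marker ids).
#' @export
groupMarkers <- function(rf, cfg = mapConfig()) {
  r <- rf$r; R <- rf$R; N <- rf$n
  lod <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  ok <- !is.na(r) & N > 0
  lod[ok] <- lodScore(pmin(r[ok], 0.5), R[ok], N[ok])
  edge <- ok & r <= cfg$rfMax & lod >= cfg$lodMin
  diag(edge) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(edge, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(rownames(r), comp)
  sizes <- lengths(groups)
  list(groups = unname(groups[sizes >= 2]),
       unlinked = sort(unname(unlist(groups[sizes == 1]))))
}

#' Frame-stage marker accounting
#'
#' Counts derived from the frame-construction stages: the core set left
#' after removing distorted representatives from the bins, and the unlinked
#' count left after grouping.
#'
#' @param nBins number of bins (candidate representatives).
#' @param nDistorted representatives removed by the distortion test.
#' @param nMapped representatives placed in linkage groups (optional).
#' @return list with `core` (= nBins - nDistorted) and, when `nMapped` is
#'   given, `unlinked` (= core - nMapped).
#' @export
#' @examples
#' stageCounts(830, 62)          # core 768
#' stageCounts(2361, 113, 2167)  # core 2248, unlinked 81
stageCounts <- function(nBins, nDistorted, nMapped = NULL) {
  core <- nBins - nDistorted
  out <- list(core = core)
  if (!is.null(nMapped)) out$unlinked <- core - nMapped
  out
}

#' Map summary statistics
#'
#' The two headline per-map statistics at their conventional reporting
#' precisions: average chromosome length (total length over number of
#' linkage groups, rounded to integer cM) and frame-marker spacing (total
#' length over frame-marker count, one decimal).
#'
#' @param totalcM total map length in cM.
#' @param nChromosomes number of chromosomes (linkage groups).
#' @param nFrameMarkers number of mapped frame markers (optional).
#' @return list with `avgChromosomeLength` and, when `nFrameMarkers` is
#'   given, `markerSpacing`.
#' @export
#' @examples
#' mapSummaryStats(3663, 21)        # 174 cM
#' mapSummaryStats(7745, 21, 2167)  # 369 cM, one marker every 3.6 cM
mapSummaryStats <- function(totalcM, nChromosomes, nFrameMarkers = NULL) {
  out <- list(avgChromosomeLength = roundHalfUp(totalcM / nChromosomes))
  if (!is.null(nFrameMarkers))
    out$markerSpacing <- roundHalfUp(totalcM / nFrameMarkers, 1)
  out
}
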