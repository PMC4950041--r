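## Population structure and introgression detection: pairwise genotype
## similarity, principal-coordinate ordination, frequency-rank genotype
## coding, UPGMA accession clustering, and a rare-haplotype segment caller
## along the genetic map.

#' Pairwise genotype similarity matrix
#'
#' `s(a, b)` is the number of markers at which the two accessions carry an
#' identical called genotype divided by the number of markers called in
#' both; no-calls in either accession are excluded. The null-homozygote
#' state is an ordinary genotype here.
#'
#' @param mat a [CallMatrix-class].
#' @return list with `similarity` (accessions x accessions, diagonal 1, NA
#'   where no marker is co-called) and `informative` (per-pair co-called
#'   marker counts).
#' @export
similarityMatrix <- function(mat) {
  calls <- genotypeCalls(mat)
  if (ncol(calls) < 2) stop("need at least two accessions")
  called <- calls != "NC"
  storage.mode(called) <- "numeric"
  co <- t(called) %*% called
  match <- matrix(0, ncol(calls), ncol(calls))
  for (st in c("AA", "AB", "BB", "NN")) {
    ind <- calls == st
    storage.mode(ind) <- "numeric"
    match <- match + t(ind) %*% ind
  }
  s <- ifelse(co > 0, match / co, NA_real_)
  diag(s) <- 1
  dimnames(s) <- dimnames(co) <- list(colnames(calls), colnames(calls))
  list(similarity = s, informative = co)
}

#' Principal-coordinate (classical MDS) ordination
#'
#' Embeds the accessions from the distance matrix `d = 1 - s` by classical
#' multidimensional scaling (double-centred Gram matrix eigendecomposition);
#' coordinates are the top-k eigenvectors scaled by the square root of
#' their eigenvalues. Negative eigenvalues (the similarity is not
#' guaranteed Euclidean) are truncated and reported.
#'
#' @param sim a [similarityMatrix()] result.
#' @param k number of coordinates (default 2).
#' @return list with `points` (accessions x k), `eigenvalues`,
#'   `negativeEigenvalues`.
#' @export
classicalMds <- function(sim, k = 2) {
  s <- sim$similarity
  if (any(is.na(s))) stop("similarity has undefined entries")
  d <- 1 - s
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k)
    warning(sprintf("only %d positive eigenvalue(s); k reduced", ncol(pts)))
  list(points = pts, eigenvalues = fit$eig,
       negativeEigenvalues = fit$eig[fit$eig < 0])
}

#' Frequency-rank genotype coding
#'
#' Per marker, genotype classes are ranked by frequency: the most common
#' class is coded 3, the least common 1, and any class in between 2
#' (monomorphic markers are all 3). Frequency ties are broken
#' lexicographically by the genotype symbol, the smaller symbol taking the
#' higher code. No-calls become `NA`.
#'
#' @param mat a [CallMatrix-class].
#' @return integer matrix (markers x accessions) of codes 1/2/3 with `NA`
#'   for no-calls.
#' @export
recodeGenotypes <- function(mat) {
  calls <- genotypeCalls(mat)
  coded <- matrix(NA_integer_, nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    called <- row[row != "NC"]
    if (!length(called)) next
    tab <- table(called)
    ranked <- names(tab)[order(-tab, names(tab))]
    k <- length(ranked)
    code <- stats::setNames(rep(2L, k), ranked)
    code[1] <- 3L
    if (k >= 2) code[k] <- 1L
    coded[i, row != "NC"] <- code[called]
  }
  coded
}

#' UPGMA clustering of accessions on coded genotypes
#'
#' Distance between two accessions is the mean absolute code difference
#' over loci scored in both; agglomeration is average-linkage (UPGMA).
#'
#' @param coded a [recodeGenotypes()] matrix.
#' @return list with `hclust` (the dendrogram) and `order` (leaf order of
#'   accession ids, the heatmap layout order).
#' @export
clusterAccessions <- function(coded) {
  n <- ncol(coded)
  if (n < 2) stop("need at least two accessions")
  D <- matrix(0, n, n, dimnames = list(colnames(coded), colnames(coded)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ok <- !is.na(coded[, a]) & !is.na(coded[, b])
    D[a, b] <- D[b, a] <-
      if (any(ok)) mean(abs(coded[ok, a] - coded[ok, b])) else 2
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(hclust = hc, order = hc$labels[hc$order])
}

#' Detect introgression segments as rare-haplotype runs
#'
#' Along each chromosome of the map, bins (sets of co-located markers) are
#' scanned for a consistent carrier set: an accession is a carrier in a bin
#' when at least `purity` of its scored loci there carry the rarest code
#' (1); the bin supports a segment when the carrier set has at least
#' `carriersMin` members and the remaining accessions jointly carry the
#' modal code (3) at `purity` of their scored cells. Maximal runs of at
#' least `minBins` consecutive bins with an identical carrier set are
#' reported with their cM span, bin and marker counts.
#'
#' @param coded a [recodeGenotypes()] matrix aligned to the panel.
#' @param map a [GeneticMap-class] covering (a subset of) the coded markers.
#' @param minBins minimum run length in bins (default 4, the smallest
#'   reliably interpretable block).
#' @param carriersMin minimum carrier count (default 2).
#' @param purity rare/modal purity threshold (default 0.9).
#' @return data.frame `accessions` (";"-separated), `chromosome`,
#'   `startCM`, `endCM`, `nBins`, `nMarkers`; zero rows when no run is
#'   found.
#' @export
detectSegments <- function(coded, map, minBins = 4L, carriersMin = 2L,
                           purity = 0.9) {
  tab <- mapTable(map)
  common <- intersect(tab$marker, rownames(coded))
  if (!length(common)) stop("map and coded matrix share no markers")
  tab <- tab[tab$marker %in% common, , drop = FALSE]
  out <- list()
  for (ch in unique(tab$chromosome)) {
    sub <- tab[tab$chromosome == ch, , drop = FALSE]
    binIds <- unique(sub$bin[order(sub$cM)])
    binInfo <- lapply(binIds, function(b) {
      mk <- sub$marker[sub$bin == b]
      list(markers = mk, cM = sub$cM[sub$bin == b][1])
    })
    ## per bin: carrier set, or NULL when the bin cannot support a segment
    carrierSets <- lapply(binInfo, function(b) {
      m <- coded[b$markers, , drop = FALSE]
      f1 <- colMeans(m == 1, na.rm = TRUE)
      scored <- colSums(!is.na(m)) > 0
      carriers <- colnames(coded)[scored & !is.na(f1) & f1 >= purity]
      if (length(carriers) < carriersMin) return(NULL)
      rest <- m[, setdiff(colnames(coded), carriers), drop = FALSE]
      f3 <- mean(rest == 3, na.rm = TRUE)
      if (is.nan(f3) || f3 < purity) return(NULL)
      sort(carriers)
    })
    ## maximal runs of identical carrier sets
    i <- 1L
    while (i <= length(carrierSets)) {
      cs <- carrierSets[[i]]
      if (is.null(cs)) { i <- i + 1L; next }
      j <- i
      while (j < length(carrierSets) &&
               identical(carrierSets[[j + 1L]], cs)) j <- j + 1L
      if (j - i + 1L >= minBins) {
        mks <- unlist(lapply(binInfo[i:j], `[[`, "markers"))
        out[[length(out) + 1L]] <- data.frame(
          accessions = paste(cs, collapse = ";"),
          chromosome = ch,
          startCM = binInfo[[i]]$cM,
          endCM = binInfo[[j]]$cM,
          nBins = j - i + 1L,
          nMarkers = length(mks))
      }
      i <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(accessions = character(0), chromosome = character(0),
                      startCM = numeric(0), endCM = numeric(0),
                      nBins = integer(0), nMarkers = integer(0)))
  do.call(rbind, out)
}
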