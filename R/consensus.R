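## Consensus chromosome assignment and unweighted, order-respecting merging
## of component genetic maps: a union precedence graph over the component
## orders, majority-weight cycle breaking, topological ordering, and an
## order-constrained least-absolute-deviation fit of the positions after
## per-component rescaling to a common span.

#' Assign consensus chromosomes
#'
#' Markers mapped to one chromosome in the majority of component maps take
#' that chromosome. Two-way ties fall back to aneuploid physical evidence,
#' then to survey annotation (either must name one of the candidate
#' chromosomes); markers still undecided get a seeded random pick among the
#' candidates.
#'
#' @param assignments data.frame `marker`, `population`, `chromosome`: the
#'   chromosome each component map placed the marker on.
#' @param physical optional evidence data.frame (`marker`, `chromosome`)
#'   from the aneuploid stocks.
#' @param survey optional survey annotation data.frame (`marker`,
#'   `chromosome`).
#' @param seed integer seed for the random tie-break.
#' @return data.frame `marker`, `chromosome`, `evidence` (majority /
#'   aneuploid / survey / random), `conflict` (did components disagree),
#'   `candidates` (the disagreeing chromosomes, ";"-separated).
#' @export
consensusChromosome <- function(assignments, physical = NULL, survey = NULL,
                                seed = 1L) {
  stopifnot(all(c("marker", "population", "chromosome") %in%
                  names(assignments)))
  lookup <- function(df, mk) {
    if (is.null(df)) return(NA_character_)
    hit <- df$chromosome[match(mk, df$marker)]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  markers <- unique(assignments$marker)
  withSeed(deriveSeed(seed, 53L), {
    rows <- lapply(markers, function(mk) {
      chrs <- assignments$chromosome[assignments$marker == mk]
      tab <- sort(table(chrs), decreasing = TRUE)
      cand <- names(tab)
      conflict <- length(cand) > 1
      if (!conflict || tab[1] > tab[2]) {
        ch <- cand[1]; ev <- "majority"
      } else {
        tied <- cand[tab == tab[1]]
        phys <- lookup(physical, mk)
        srv <- lookup(survey, mk)
        if (!is.na(phys) && phys %in% tied) { ch <- phys; ev <- "aneuploid" }
        else if (!is.na(srv) && srv %in% tied) { ch <- srv; ev <- "survey" }
        else { ch <- sample(tied, 1); ev <- "random" }
      }
      data.frame(marker = mk, chromosome = ch, evidence = ev,
                 conflict = conflict,
                 candidates = paste(cand, collapse = ";"))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

## L1 isotonic regression (pool adjacent violators with weighted medians)
.isotonicL1 <- function(y, w = rep(1, length(y))) {
  wmedian <- function(v, wt) {
    o <- order(v); v <- v[o]; wt <- wt[o]
    cs <- cumsum(wt) / sum(wt)
    v[which(cs >= 0.5)[1]]
  }
  blocks <- lapply(seq_along(y), function(i)
    list(v = y[i], w = w[i], med = y[i]))
  i <- 2L
  while (i <= length(blocks)) {
    if (blocks[[i]]$med < blocks[[i - 1]]$med - 1e-12) {
      merged <- list(v = c(blocks[[i - 1]]$v, blocks[[i]]$v),
                     w = c(blocks[[i - 1]]$w, blocks[[i]]$w))
      merged$med <- wmedian(merged$v, merged$w)
      blocks <- append(blocks[-c(i - 1L, i)], list(merged), after = i - 2L)
      i <- max(2L, i - 1L)
    } else i <- i + 1L
  }
  unlist(lapply(blocks, function(b) rep(b$med, length(b$v))))
}

#' Merge component maps into a consensus map
#'
#' Per consensus chromosome: (1) a precedence edge a->b is collected for
#' every ordered pair in every component map (co-located markers yield no
#' edge), weighted by the number of supporting components; (2) opposing
#' pairs keep the heavier direction (ties keep the direction with the larger
#' cM separation) and any remaining cycles are broken by a minimum-weight
#' feedback arc set; the number of deleted edges is reported and is zero for
#' conflict-free inputs; (3) markers are ordered topologically;
#' (4) consensus positions are a least-absolute-deviation fit to the
#' component positions after rescaling each component chromosome to the mean
#' component span, made monotone along the order by L1 isotonic regression.
#' A marker mapped on several chromosomes keeps only its position on the
#' consensus chromosome.
#'
#' @param maps named list of [GeneticMap-class] component maps.
#' @param consensus a [consensusChromosome()] table; defaults to majority
#'   vote computed from `maps` with `seed`.
#' @param seed integer seed (duplicate resolution without a consensus
#'   chromosome).
#' @return list with `map` (a [GeneticMap-class] with a provenance
#'   attribute), `deletedEdges` (count), `provenance` (data.frame marker,
#'   populations carrying it).
#' @export
mergeMaps <- function(maps, consensus = NULL, seed = 1L) {
  stopifnot(is.list(maps), length(maps) >= 1, !is.null(names(maps)))
  comp <- do.call(rbind, lapply(names(maps), function(nm) {
    tab <- mapTable(maps[[nm]])
    data.frame(population = nm, tab)
  }))
  if (is.null(consensus)) {
    consensus <- consensusChromosome(
      comp[, c("marker", "population", "chromosome")], seed = seed)
  }
  consChr <- stats::setNames(consensus$chromosome, consensus$marker)
  ## retain only positions on the consensus chromosome
  hit <- consChr[comp$marker]
  comp <- comp[!is.na(hit) & comp$chromosome == hit, , drop = FALSE]
  deleted <- 0L
  chromRows <- list()
  for (ch in sort(unique(comp$chromosome))) {
    sub <- comp[comp$chromosome == ch, , drop = FALSE]
    pops <- unique(sub$population)
    spans <- vapply(pops, function(p)
      diff(range(sub$cM[sub$population == p])), numeric(1))
    target <- mean(spans[spans > 0])
    if (!is.finite(target) || target == 0) target <- 1
    ## rescale each component to the mean span
    sub$pos <- sub$cM
    for (p in pops) {
      i <- sub$population == p
      lo <- min(sub$cM[i]); spn <- diff(range(sub$cM[i]))
      sub$pos[i] <- if (spn > 0) (sub$cM[i] - lo) * target / spn else 0
    }
    ## orient components consistently (linkage-group orientation is only
    ## defined up to reversal): flip any component whose shared-marker
    ## positions run against the first component carrying them
    ref <- pops[1]
    for (p in pops[-1]) {
      i <- sub$population == p
      shared <- intersect(sub$marker[i], sub$marker[sub$population == ref])
      if (length(shared) >= 2) {
        a <- sub$pos[i][match(shared, sub$marker[i])]
        b <- sub$pos[sub$population == ref][
          match(shared, sub$marker[sub$population == ref])]
        if (stats::var(a) > 0 && stats::var(b) > 0 &&
              stats::cor(a, b, method = "spearman") < 0) {
          sub$pos[i] <- max(sub$pos[i]) - sub$pos[i]
          sub$cM[i] <- max(sub$cM[i]) - sub$cM[i]
        }
      }
    }
    markers <- unique(sub$marker)
    mi <- stats::setNames(seq_along(markers), markers)
    ## precedence weights and separations over all ordered pairs
    wUp <- matrix(0, length(markers), length(markers))
    sepUp <- matrix(0, length(markers), length(markers))
    for (p in pops) {
      s <- sub[sub$population == p, , drop = FALSE]
      s <- s[order(s$cM), , drop = FALSE]
      n <- nrow(s)
      if (n < 2) next
      for (a in 1:(n - 1)) for (b in (a + 1):n) {
        if (s$cM[b] > s$cM[a]) {
          ia <- mi[s$marker[a]]; ib <- mi[s$marker[b]]
          wUp[ia, ib] <- wUp[ia, ib] + 1
          sepUp[ia, ib] <- sepUp[ia, ib] + (s$pos[b] - s$pos[a])
        }
      }
    }
    ## resolve opposing pairs by weight, then separation
    keepFrom <- integer(0); keepTo <- integer(0); keepW <- numeric(0)
    for (a in seq_along(markers)) for (b in seq_along(markers)) {
      if (a >= b) next
      w1 <- wUp[a, b]; w2 <- wUp[b, a]
      if (w1 == 0 && w2 == 0) next
      if (w1 > 0 && w2 > 0) {
        deleted <- deleted + 1L
        if (w1 > w2 || (w1 == w2 && sepUp[a, b] >= sepUp[b, a])) {
          keepFrom <- c(keepFrom, a); keepTo <- c(keepTo, b)
          keepW <- c(keepW, w1)
        } else {
          keepFrom <- c(keepFrom, b); keepTo <- c(keepTo, a)
          keepW <- c(keepW, w2)
        }
      } else if (w1 > 0) {
        keepFrom <- c(keepFrom, a); keepTo <- c(keepTo, b)
        keepW <- c(keepW, w1)
      } else {
        keepFrom <- c(keepFrom, b); keepTo <- c(keepTo, a)
        keepW <- c(keepW, w2)
      }
    }
    g <- igraph::make_empty_graph(n = length(markers), directed = TRUE)
    if (length(keepFrom)) {
      g <- igraph::add_edges(g, rbind(keepFrom, keepTo))
      igraph::E(g)$weight <- keepW
    }
    ## residual cycles (pairwise majority can be non-transitive)
    if (!igraph::is_dag(g)) {
      fas <- igraph::feedback_arc_set(g, weights = igraph::E(g)$weight)
      deleted <- deleted + length(fas)
      g <- igraph::delete_edges(g, fas)
    }
    topo <- as.integer(igraph::topo_sort(g))
    ord <- markers[topo]
    ## LAD positions: per-marker median of rescaled component positions,
    ## then monotone along the order
    med <- vapply(ord, function(mk)
      stats::median(sub$pos[sub$marker == mk]), numeric(1))
    wt <- vapply(ord, function(mk) sum(sub$marker == mk), numeric(1))
    fit <- .isotonicL1(med, wt)
    fit <- fit - fit[1]
    chromRows[[ch]] <- data.frame(marker = ord, chromosome = ch,
                                  cM = roundHalfUp(fit, 1))
  }
  tab <- do.call(rbind, chromRows)
  prov <- stats::aggregate(population ~ marker, data = comp,
                           FUN = function(x) paste(sort(unique(x)),
                                                   collapse = ";"))
  map <- GeneticMap(tab)
  list(map = map, deletedEdges = deleted, provenance = prov)
}

#' Consensus accounting from per-population-count data
#'
#' Shares of markers mapped in one, two or three component maps (one
#' decimal), the conflict rate among multiply-mapped markers, and the
#' average chromosome length.
#'
#' @param mappedIn named or ordered counts of markers mapped in 1, 2, 3
#'   components.
#' @param nConflict markers mapped to different chromosomes in different
#'   components.
#' @param totalcM optional consensus map length.
#' @param nChromosomes optional chromosome count.
#' @return list with `total`, `shares` (percent), `multiMapped`,
#'   `conflictRate` (percent), and when lengths are given
#'   `avgChromosomeLength`.
#' @export
#' @examples
#' consensusShares(c(47069, 8588, 848), 729, 3739, 21)
consensusShares <- function(mappedIn, nConflict, totalcM = NULL,
                            nChromosomes = NULL) {
  total <- sum(mappedIn)
  multi <- sum(mappedIn[-1])
  out <- list(total = total,
              shares = percentShare(mappedIn, total),
              multiMapped = multi,
              conflictRate = if (multi > 0) percentShare(nConflict, multi)
                             else NA_real_)
  if (!is.null(totalcM) && !is.null(nChromosomes))
    out$avgChromosomeLength <- mapSummaryStats(totalcM, nChromosomes)$
      avgChromosomeLength
  out
}

#' Summary of a merged consensus map
#'
#' @param merged a [mergeMaps()] result.
#' @return list with per-chromosome marker counts, `total`, counts and
#'   shares by number of carrying populations, total length and average
#'   chromosome length.
#' @export
consensusSummary <- function(merged) {
  tab <- mapTable(merged$map)
  nPop <- lengths(strsplit(merged$provenance$population, ";"))
  byCount <- table(factor(nPop, levels = 1:max(nPop)))
  perChrom <- table(tab$chromosome)
  lens <- tapply(tab$cM, tab$chromosome, max)
  c(list(perChromosome = perChrom, totalLength = sum(lens),
         deletedEdges = merged$deletedEdges),
    consensusShares(as.numeric(byCount),
                    nConflict = sum(merged$provenance$conflict %||% 0),
                    totalcM = sum(lens), nChromosomes = length(lens)))
}
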