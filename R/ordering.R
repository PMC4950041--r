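## Marker ordering within a linkage group: greedy seriation minimizing the
## sum of adjacent recombination fractions (SARF), followed by exhaustive
## rippling of a sliding window until no inversion improves the order.

## all permutations of 1..n (n small; cached for the ripple window)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

## SARF of an order given the rf matrix (missing rf counts as 0.5)
.sarf <- function(ord, r) {
  if (length(ord) < 2) return(0)
  adj <- r[cbind(ord[-length(ord)], ord[-1])]
  adj[is.na(adj)] <- 0.5
  sum(adj)
}

## greedy SARF insertion seeded from the most distant pair
.greedyOrder <- function(r) {
  m <- nrow(r)
  rw <- r
  rw[is.na(rw)] <- 0.5
  diag(rw) <- NA
  far <- which(rw == max(rw, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ord <- as.integer(far)
  left <- setdiff(seq_len(m), ord)
  while (length(left)) {
    ## most confidently placed next: smallest rf to any placed marker
    minToPlaced <- vapply(left, function(i) min(rw[i, ord]), numeric(1))
    nxt <- left[which.min(minToPlaced)]
    best <- NULL; bestS <- Inf
    for (pos in 0:length(ord)) {
      cand <- append(ord, nxt, after = pos)
      s <- .sarf(cand, r)
      if (s < bestS - 1e-12) { bestS <- s; best <- cand }
    }
    ord <- best
    left <- setdiff(left, nxt)
  }
  ord
}

## seriation by the first principal coordinate of the Kosambi distances
.pcoOrder <- function(r) {
  d <- r
  d[is.na(d)] <- 0.49
  d <- kosambi(pmin(d, 0.49))
  diag(d) <- 0
  co <- stats::cmdscale(d, k = 1)
  order(co[, 1])
}

## exhaustive window rippling to a fixed point
.ripple <- function(ord, r, w) {
  m <- length(ord)
  w <- min(w, m)
  perms <- .permutations(w)
  repeat {
    improved <- FALSE
    for (s in seq_len(m - w + 1L)) {
      idx <- s:(s + w - 1L)
      base <- .sarf(ord, r)
      bestOrd <- ord; bestS <- base
      for (p in seq_len(nrow(perms))) {
        cand <- ord
        cand[idx] <- ord[idx][perms[p, ]]
        sc <- .sarf(cand, r)
        if (sc < bestS - 1e-12) { bestS <- sc; bestOrd <- cand }
      }
      if (bestS < base - 1e-12) { ord <- bestOrd; improved <- TRUE }
    }
    if (!improved) break
  }
  ord
}

#' Order the markers of one linkage group
#'
#' Builds an initial order by greedy seriation: the pair with the largest
#' recombination fraction seeds the two ends, and each remaining marker (the
#' one most tightly linked to the placed set first) is inserted at the
#' position minimizing the sum of adjacent recombination fractions (SARF).
#' A second initial order comes from principal-coordinate seriation of the
#' Kosambi distance matrix. Each is refined by rippling: every contiguous window of
#' `rippleWindow` markers is exhaustively permuted and the best SARF kept,
#' repeated until a fixed point. Map positions are cumulative Kosambi
#' distances of the adjacent fractions.
#'
#' @param markers marker ids of the group (>= 2).
#' @param rf a [rfMatrix()] result covering them.
#' @param cfg a [mapConfig()].
#' @return list with `order` (marker ids), `cM` (positions starting at 0)
#'   and `sarf`.
#' @export
orderGroup <- function(markers, rf, cfg = mapConfig()) {
  if (length(markers) < 2) stop("group must have at least two markers")
  r <- rf$r[markers, markers, drop = FALSE]
  m <- length(markers)
  if (m == 2) {
    ord <- c(1L, 2L)
  } else {
    ## two seriation seeds, each rippled; the lower SARF wins (greedy
    ## insertion can fold long groups in a way window moves cannot undo)
    cands <- list(.greedyOrder(r), .pcoOrder(r))
    cands <- lapply(cands, .ripple, r = r, w = cfg$rippleWindow)
    ord <- cands[[which.min(vapply(cands, .sarf, numeric(1), r = r))]]
  }
  ordered <- markers[ord]
  adj <- r[cbind(ordered[-length(ordered)], ordered[-1])]
  adj[is.na(adj)] <- 0.49
  adj <- pmin(adj, 0.49)   # guard the Kosambi pole for sparse groups
  list(order = ordered, cM = c(0, cumsum(kosambi(adj))),
       sarf = .sarf(ord, r))
}

#' Exhaustive SARF-optimal order (oracle for small groups)
#'
#' Enumerates all orders (up to reversal) and returns one with minimal SARF.
#' Only feasible for small groups; used to validate [orderGroup()].
#'
#' @param markers marker ids (<= 8).
#' @param rf a [rfMatrix()] result.
#' @return list with `order` and `sarf`.
#' @export
exhaustiveOrder <- function(markers, rf) {
  m <- length(markers)
  stopifnot(m >= 2, m <= 8)
  r <- rf$r[markers, markers, drop = FALSE]
  perms <- .permutations(m)
  perms <- perms[perms[, 1] < perms[, m], , drop = FALSE]  # drop reversals
  s <- apply(perms, 1, .sarf, r = r)
  best <- which.min(s)
  list(order = markers[perms[best, ]], sarf = s[best])
}

#' Assign linkage groups to chromosomes and orient them
#'
#' Each group's chromosome is the majority vote of its members' physical
#' evidence (ties leave the group unassigned). Groups mapped to the same
#' chromosome are merged and re-ordered as one. A group is flipped when its
#' short-arm-annotated markers lie below its long-arm ones, so the short arm
#' reads from the top of the map.
#'
#' @param ordered list of [orderGroup()] results.
#' @param evidence physical evidence data.frame (`marker`, `chromosome`,
#'   optionally `arm`), e.g. from [reconcilePhysical()].
#' @param rf the [rfMatrix()] used for re-ordering merged groups.
#' @param cfg a [mapConfig()].
#' @return list of ordered groups, each with `chromosome` (NA when no or
#'   tied evidence), `order`, `cM`.
#' @export
orientAndAssign <- function(ordered, evidence, rf, cfg = mapConfig()) {
  vote <- function(markers) {
    ev <- evidence$chromosome[match(markers, evidence$marker)]
    ev <- ev[!is.na(ev)]
    if (!length(ev)) return(NA_character_)
    tab <- sort(table(ev), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
    names(tab)[1]
  }
  labs <- vapply(ordered, function(g) vote(g$order), character(1))
  out <- list()
  for (ch in unique(labs)) {
    idx <- which(if (is.na(ch)) is.na(labs) else !is.na(labs) & labs == ch)
    if (is.na(ch)) {
      for (i in idx) out[[length(out) + 1L]] <-
          c(ordered[[i]], list(chromosome = NA_character_))
      next
    }
    grp <- ordered[idx]
    if (length(grp) > 1) {   # fragments of one chromosome: merge, re-order
      members <- unlist(lapply(grp, `[[`, "order"))
      merged <- orderGroup(members, rf, cfg)
    } else merged <- grp[[1]]
    ## orientation: short arm on top
    if (!is.null(evidence$arm)) {
      arm <- evidence$arm[match(merged$order, evidence$marker)]
      sPos <- merged$cM[!is.na(arm) & arm == "S"]
      lPos <- merged$cM[!is.na(arm) & arm == "L"]
      if (length(sPos) && length(lPos) && mean(sPos) > mean(lPos)) {
        merged$order <- rev(merged$order)
        merged$cM <- max(merged$cM) - rev(merged$cM)
      }
    }
    merged$chromosome <- ch
    out[[length(out) + 1L]] <- merged
  }
  out
}

#' Reintegrate bin members into a frame map
#'
#' Every bin member is inserted at the cM position of its representative
#' frame marker; bins whose representative was dropped (distorted or
#' unlinked) are absent from the final map.
#'
#' @param frame data.frame `marker`, `chromosome`, `cM` of the frame
#'   (representatives only).
#' @param bins list of bin member vectors.
#' @param representatives representative marker id per bin (parallel to
#'   `bins`).
#' @return a [GeneticMap-class] with all members of surviving bins.
#' @export
reintegrateBins <- function(frame, bins, representatives) {
  stopifnot(length(bins) == length(representatives))
  keep <- representatives %in% frame$marker
  orphan <- setdiff(frame$marker, representatives)
  if (length(orphan))
    stop("frame markers that represent no bin: ",
         paste(orphan, collapse = ", "))
  rows <- lapply(which(keep), function(i) {
    rep <- representatives[i]
    at <- frame[frame$marker == rep, ]
    data.frame(marker = bins[[i]], chromosome = at$chromosome, cM = at$cM,
               bin = paste0(at$chromosome, "_bin", i))
  })
  GeneticMap(do.call(rbind, rows))
}

#' Build a genetic map for one DH population
#'
#' Runs the full frame-map procedure: missing-data filter, co-segregation
#' binning (unique-pattern markers dropped), representative selection,
#' segregation-distortion filter (removal cascades to the whole bin),
#' rf/LOD grouping, seriation plus rippling within groups, optional
#' chromosome assignment and orientation from physical evidence, Kosambi
#' distances, and reintegration of bin members at their representative's
#' position.
#'
#' @param pop a [DhPopulation-class].
#' @param cfg a [mapConfig()].
#' @param evidence optional physical evidence data.frame for
#'   [orientAndAssign()].
#' @return list with `map` (a [GeneticMap-class]), `summary` (total and
#'   per-chromosome lengths, average chromosome length, marker spacing,
#'   stage counts) and `frame` (the frame-marker table).
#' @export
buildMap <- function(pop, cfg = mapConfig(), evidence = NULL) {
  allMk <- markerNames(pop)
  kept <- filterMissing(pop, cfg)
  bn <- binMarkers(pop, cfg, markers = kept)
  bins <- bn$bins
  reps <- vapply(seq_along(bins), function(i)
    selectRepresentative(bins[[i]], pop, seed = cfg$seed + i), character(1))
  ## distortion filter on representatives; removal cascades to the bin
  callsAll <- genotypeCalls(pop)
  keepRep <- vapply(reps, function(mk)
    testDistortion(callsAll[mk, ], cfg)$keep, logical(1))
  distorted <- reps[!keepRep]
  bins2 <- bins[keepRep]
  reps2 <- reps[keepRep]
  if (length(reps2) < 2) stop("fewer than two representatives survive")
  rf <- rfMatrix(pop, markers = reps2)
  gr <- groupMarkers(rf, cfg)
  ordered <- lapply(gr$groups, orderGroup, rf = rf, cfg = cfg)
  if (!is.null(evidence)) {
    ordered <- orientAndAssign(ordered, evidence, rf, cfg)
  } else {
    for (i in seq_along(ordered)) ordered[[i]]$chromosome <- paste0("LG", i)
  }
  frame <- do.call(rbind, lapply(ordered, function(g)
    data.frame(marker = g$order,
               chromosome = g$chromosome %||% NA_character_,
               cM = roundHalfUp(g$cM, 1))))
  frame <- frame[!is.na(frame$chromosome), , drop = FALSE]
  usable <- reps2 %in% frame$marker
  map <- reintegrateBins(frame, bins2[usable], reps2[usable])
  perChrom <- tapply(mapTable(map)$cM, mapTable(map)$chromosome, max)
  total <- sum(perChrom)
  summary <- c(
    list(totalLength = total, chromosomeLengths = perChrom),
    mapSummaryStats(total, length(perChrom), nrow(frame)),
    list(counts = list(
      input = length(allMk),
      missingFiltered = length(allMk) - length(kept),
      uniquePattern = length(bn$singletons),
      bins = length(bins),
      distorted = length(distorted),
      unlinked = length(gr$unlinked),
      frameMapped = nrow(frame),
      totalMapped = nrow(mapTable(map)))),
    list(distortedMarkers = distorted, unlinkedMarkers = gr$unlinked))
  list(map = map, summary = summary, frame = frame)
}
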