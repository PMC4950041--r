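## Synthetic-data generators. Everything is driven by one integer seed in the
## SimConfig; per-stage sub-streams are derived deterministically so that
## adding a stage never perturbs another stage's draws.

#' Wheat-style chromosome names
#' @param n number of chromosomes (up to 21).
#' @return character vector such as "1A", "1B", "1D", "2A", ...
#' @export
wheatChromosomes <- function(n = 21) {
  stopifnot(n >= 1, n <= 21)
  paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))[seq_len(n)]
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. `classMix` gives the
#' marker performance-category mixture of the simulated panel; the default is
#' the category spectrum typical of a polyploid wheat array screen.
#'
#' @param nLines number of doubled-haploid lines per population.
#' @param missingRate per-call missing probability in the DH populations.
#' @param distortedFraction fraction of markers with segregation distortion.
#' @param distortionAlleleFreq A-allele frequency forced at distorted markers.
#' @param classMix named fractions over PHR/NMH/OTV/MHR/CRBT/Other summing
#'   to 1.
#' @param hetRate residual-heterozygosity rate in DH lines (H calls; treated
#'   as missing by the mapping stages). Defaults to 0.
#' @param groupShift group-level allele-frequency shift controlling
#'   between-group divergence in simulated panels.
#' @param callrateMin the call-rate threshold the CRBT class is forced below.
#' @param seed global integer seed.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(nLines = 100,
                      missingRate = 0.05,
                      distortedFraction = 0.05,
                      distortionAlleleFreq = 0.7,
                      classMix = c(PHR = 53569, NMH = 449941, OTV = 42789,
                                   MHR = 144320, CRBT = 23686,
                                   Other = 105266) / 819571,
                      hetRate = 0,
                      groupShift = 0.3,
                      callrateMin = 0.8,
                      seed = 1L) {
  fr <- c(missingRate, distortedFraction, distortionAlleleFreq, hetRate)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (nLines < 2) stop("nLines must be at least 2")
  need <- c("PHR", "NMH", "OTV", "MHR", "CRBT", "Other")
  if (!all(need %in% names(classMix)) || any(classMix < 0) ||
      abs(sum(classMix) - 1) > 1e-9) {
    stop("classMix must be named fractions over the six categories summing to 1")
  }
  structure(list(nLines = as.integer(nLines), missingRate = missingRate,
                 distortedFraction = distortedFraction,
                 distortionAlleleFreq = distortionAlleleFreq,
                 classMix = classMix[need], hetRate = hetRate,
                 groupShift = groupShift, callrateMin = callrateMin,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Generate a ground-truth genetic map
#'
#' Places markers at a limited number of distinct positions per chromosome so
#' that co-located markers form true bins, as on a saturated array where many
#' probes show identical segregation.
#'
#' @param chromosomeLengths named numeric vector of chromosome lengths (cM);
#'   unnamed vectors get wheat-style names.
#' @param nMarkers total marker count, allocated proportionally to length.
#' @param nPositions total distinct positions (true bins) across chromosomes.
#' @param centromereFraction centromere position as a fraction of length.
#' @param seed integer seed.
#' @return a [TrueMap-class] object.
#' @export
makeTrueMap <- function(chromosomeLengths = stats::setNames(rep(120, 3),
                                                            c("1A", "1B", "1D")),
                        nMarkers = 200, nPositions = 75,
                        centromereFraction = 0.45, seed = 1L) {
  if (length(chromosomeLengths) < 1 || any(chromosomeLengths <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(names(chromosomeLengths)))
    names(chromosomeLengths) <- wheatChromosomes(length(chromosomeLengths))
  nChr <- length(chromosomeLengths)
  if (nPositions < nChr) stop("need at least one position per chromosome")
  if (nMarkers < nPositions) stop("need at least one marker per position")
  withSeed(deriveSeed(seed, 11L), {
    ## spread positions, then markers, proportionally to length
    shares <- chromosomeLengths / sum(chromosomeLengths)
    posPer <- pmax(1L, floor(nPositions * shares))
    i <- 1L
    while (sum(posPer) < nPositions) {
      posPer[i] <- posPer[i] + 1L; i <- i %% nChr + 1L
    }
    while (sum(posPer) > nPositions) {
      j <- which.max(posPer); posPer[j] <- posPer[j] - 1L
    }
    rows <- lapply(seq_len(nChr), function(k) {
      L <- chromosomeLengths[k]
      grid <- seq(roundHalfUp(0.02 * L, 1), roundHalfUp(0.98 * L, 1),
                  by = 0.1)
      if (posPer[k] > length(grid))
        stop("more positions requested than the 0.1-cM grid holds")
      pos <- sort(sample(grid, posPer[k]))
      data.frame(chromosome = names(chromosomeLengths)[k], cM = pos)
    })
    posTab <- do.call(rbind, rows)
    ## every position holds >= 1 marker; extras multinomially
    extra <- stats::rmultinom(1, nMarkers - nrow(posTab),
                              rep(1, nrow(posTab)))[, 1]
    mult <- 1L + extra
    markers <- posTab[rep(seq_len(nrow(posTab)), mult), ]
    markers$marker <- sprintf("AX%05d", seq_len(nrow(markers)))
    chrom <- data.frame(name = names(chromosomeLengths),
                        length = as.numeric(chromosomeLengths),
                        centromere = centromereFraction *
                          as.numeric(chromosomeLengths))
    TrueMap(chrom, markers[, c("marker", "chromosome", "cM")])
  })
}

#' Simulate a doubled-haploid mapping population
#'
#' Gametes are generated marker-to-marker as an interference-free Markov
#' chain: the first marker of a chromosome is `A` or `B` with probability
#' one half, and each interval switches parental phase with probability
#' [inverseKosambi()] of its true cM width, so that estimated maps are
#' Kosambi-consistent with the generating map by construction. Missing calls
#' are injected independently per call; a chosen fraction of markers is
#' distorted by resampling its alleles at a shifted frequency.
#'
#' @param trueMap a [TrueMap-class] object.
#' @param cfg a [simConfig()] list.
#' @return list with `pop` (a [DhPopulation-class]) and `truth` (list with
#'   `distortedMarkers` and the generating `trueMap`).
#' @export
simulateDhPopulation <- function(trueMap, cfg = simConfig()) {
  mk <- trueMarkerPositions(trueMap)
  if (nrow(mk) == 0) stop("true map has no markers")
  n <- cfg$nLines
  withSeed(deriveSeed(cfg$seed, 23L), {
    perChr <- split(mk, mk$chromosome)
    blocks <- lapply(perChr, function(tab) {
      m <- nrow(tab)
      geno <- matrix(0L, nrow = m, ncol = n)
      geno[1, ] <- stats::rbinom(n, 1, 0.5)
      if (m > 1) {
        r <- inverseKosambi(diff(tab$cM))
        sw <- matrix(stats::rbinom((m - 1) * n, 1, rep(r, n)),
                     nrow = m - 1, ncol = n)
        geno[-1, ] <- sw
        geno <- apply(geno, 2, cumsum) %% 2L
        geno <- matrix(geno, nrow = m)
      }
      rownames(geno) <- tab$marker
      geno
    })
    geno <- do.call(rbind, blocks)[mk$marker, , drop = FALSE]
    calls <- matrix(c("A", "B")[geno + 1L], nrow = nrow(geno),
                    dimnames = list(mk$marker,
                                    sprintf("DH%04d", seq_len(n))))
    ## segregation distortion: override selected markers independently
    nDist <- round(cfg$distortedFraction * nrow(calls))
    distorted <- character(0)
    if (nDist > 0) {
      distorted <- sample(rownames(calls), nDist)
      for (mki in distorted) {
        calls[mki, ] <- ifelse(
          stats::rbinom(n, 1, cfg$distortionAlleleFreq) == 1, "A", "B")
      }
    }
    if (cfg$hetRate > 0) {
      het <- matrix(stats::runif(length(calls)) < cfg$hetRate,
                    nrow = nrow(calls))
      calls[het] <- "H"
    }
    if (cfg$missingRate > 0) {
      miss <- matrix(stats::runif(length(calls)) < cfg$missingRate,
                     nrow = nrow(calls))
      calls[miss] <- NA_character_
    }
    list(pop = DhPopulation(calls),
         truth = list(distortedMarkers = sort(distorted), trueMap = trueMap))
  })
}

## -- panel simulation helpers -----------------------------------------------

## inject no-calls without ever pushing the call rate to/below the threshold
.injectNoCalls <- function(calls, nAcc, thr, rate = 0.02) {
  cap <- max(0L, ceiling(nAcc * (1 - thr)) - 1L)
  k <- min(stats::rbinom(1, nAcc, rate), cap)
  if (k > 0) calls[sample(nAcc, k)] <- "NC"
  calls
}

.forceStates <- function(calls, need) {
  ## overwrite random called cells so every state in `need` reaches its quota
  for (st in names(need)) {
    have <- sum(calls == st)
    short <- need[[st]] - have
    if (short > 0) {
      pool <- which(calls != "NC" & calls != st)
      pick <- pool[sample.int(length(pool), short)]
      calls[pick] <- st
    }
  }
  calls
}

#' Simulate a multi-group accession panel
#'
#' Draws each marker from one of the six performance categories of the
#' configured `classMix` and genotypes every accession, with a group-level
#' allele-frequency shift producing between-group divergence. Category rules
#' are enforced by construction, so the generator's truth classes are exact:
#' PHR markers carry all three genotype clusters with at least two minor
#' homozygotes, NMH markers show a major homozygote plus heterozygote only,
#' OTV markers add a null-homozygote cluster, MHR markers are monomorphic,
#' CRBT markers are forced below the call-rate threshold, and Other markers
#' are a homozygote pair with a single minor-homozygote individual.
#'
#' @param trueMap a [TrueMap-class] (marker ids and positions).
#' @param groups data.frame with columns `accession` and `group` (>= 2
#'   groups, each with >= 1 accession).
#' @param cfg a [simConfig()].
#' @return list with `matrix` (a [CallMatrix-class]) and `truth` (data.frame
#'   `marker`, `class`).
#' @export
simulatePanel <- function(trueMap, groups, cfg = simConfig()) {
  stopifnot(is.data.frame(groups), all(c("accession", "group") %in%
                                         names(groups)))
  if (length(unique(groups$group)) < 2) stop("need at least two groups")
  if (anyDuplicated(groups$accession)) stop("duplicate accession ids")
  mk <- trueMarkerPositions(trueMap)$marker
  nAcc <- nrow(groups)
  thr <- cfg$callrateMin
  grpIdx <- as.integer(factor(groups$group))
  nGrp <- max(grpIdx)
  ## alternating group shift signs give divergent allele frequencies
  sgn <- rep(c(1, -1), length.out = nGrp)
  withSeed(deriveSeed(cfg$seed, 37L), {
    cls <- sample(names(cfg$classMix), length(mk), replace = TRUE,
                  prob = cfg$classMix)
    calls <- matrix(NA_character_, nrow = length(mk), ncol = nAcc,
                    dimnames = list(mk, groups$accession))
    for (i in seq_along(mk)) {
      ci <- cls[i]
      if (ci == "PHR") {
        p <- stats::runif(1, 0.25, 0.75)
        pg <- pmin(0.95, pmax(0.05, p + cfg$groupShift * sgn[grpIdx]))
        h <- 0.08
        u <- stats::runif(nAcc)
        row <- ifelse(u < pg * (1 - h), "AA",
                      ifelse(u < (1 - h), "BB", "AB"))
        row <- .injectNoCalls(row, nAcc, thr)
        row <- .forceStates(row, list(AA = 2, BB = 2, AB = 1))
      } else if (ci == "NMH") {
        major <- sample(c("AA", "BB"), 1)
        q <- stats::runif(1, 0.15, 0.45)
        qg <- pmin(0.9, pmax(0.05, q + 0.5 * cfg$groupShift * sgn[grpIdx]))
        row <- ifelse(stats::runif(nAcc) < qg, "AB", major)
        row <- .injectNoCalls(row, nAcc, thr)
        row <- .forceStates(row, stats::setNames(list(1, 1), c(major, "AB")))
      } else if (ci == "OTV") {
        pr <- c(0.45, 0.3, 0.2, 0.05)   # AA, BB, NN, AB
        row <- sample(c("AA", "BB", "NN", "AB"), nAcc, TRUE, pr)
        row <- .injectNoCalls(row, nAcc, thr)
        row <- .forceStates(row, list(NN = 2, AA = 1, BB = 1))
      } else if (ci == "MHR") {
        row <- rep("AA", nAcc)
        row <- .injectNoCalls(row, nAcc, thr)
      } else if (ci == "CRBT") {
        row <- sample(c("AA", "BB"), nAcc, TRUE)
        ncMin <- floor(nAcc * (1 - thr)) + 1L
        k <- min(nAcc, max(ncMin, round(nAcc * stats::runif(1, 1 - thr + 0.05,
                                                            0.5))))
        row[sample(nAcc, k)] <- "NC"
      } else {                           # Other: one minor homozygote only
        row <- rep("AA", nAcc)
        row[sample(nAcc, 1)] <- "BB"
        keep <- which(row == "BB")
        idx <- setdiff(seq_len(nAcc), keep)
        cap <- max(0L, ceiling(nAcc * (1 - thr)) - 1L)
        k <- min(stats::rbinom(1, nAcc, 0.02), cap)
        if (k > 0) row[sample(idx, k)] <- "NC"
      }
      calls[i, ] <- row
    }
    list(matrix = CallMatrix(calls, stats::setNames(groups$group,
                                                    groups$accession)),
         truth = data.frame(marker = mk, class = cls))
  })
}

#' Aneuploid panel descriptor
#'
#' @param stock stock ids.
#' @param kind `"nulli_tetra"` or `"deletion"` per stock.
#' @param chromosome missing chromosome per stock.
#' @param arm for deletions, `"S"` or `"L"`; `NA` for nulli/tetra stocks.
#' @param retainedFraction for deletions, the proximal fraction of the arm
#'   retained, in `[0, 1)`; `NA` for nulli/tetra stocks.
#' @return validated data.frame of class `aneuploidPanel`.
#' @export
aneuploidPanel <- function(stock, kind, chromosome, arm = NA,
                           retainedFraction = NA) {
  n <- length(stock)
  df <- data.frame(stock = as.character(stock),
                   kind = rep_len(as.character(kind), n),
                   chromosome = rep_len(as.character(chromosome), n),
                   arm = rep_len(as.character(arm), n),
                   retainedFraction = rep_len(as.numeric(retainedFraction), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$stock)) stop("duplicate stock ids")
  if (!all(df$kind %in% c("nulli_tetra", "deletion")))
    stop("kind must be nulli_tetra or deletion")
  del <- df$kind == "deletion"
  if (any(del & (is.na(df$arm) | !df$arm %in% c("S", "L"))))
    stop("deletion stocks need arm S or L")
  if (any(del & (is.na(df$retainedFraction) | df$retainedFraction < 0 |
                   df$retainedFraction >= 1)))
    stop("retained fraction must lie in [0, 1)")
  structure(df, class = c("aneuploidPanel", "data.frame"))
}

## deleted cM interval [lo, hi] of a lesion on a chromosome
.deletedInterval <- function(chromRow, arm, retained) {
  cen <- chromRow$centromere; L <- chromRow$length
  if (arm == "S") c(0, (1 - retained) * cen) else
    c(cen + retained * (L - cen), L)
}

#' Simulate an aneuploid stock screen
#'
#' Every stock carries the euploid reference genotype except at markers
#' removed by its lesion, which become no-calls; a nullisomic stock loses a
#' whole chromosome, a deletion stock the distal part of one arm. Euploid
#' reference accessions are appended for the presence quorum of the
#' assignment stage.
#'
#' @param trueMap a [TrueMap-class].
#' @param panel an [aneuploidPanel()].
#' @param nEuploidRefs number of euploid reference accessions to include.
#' @param seed integer seed (reserved; the screen itself is deterministic).
#' @return a [CallMatrix-class] with groups `"aneuploid"` / `"euploid_ref"`.
#' @export
simulateAneuploids <- function(trueMap, panel, nEuploidRefs = 2, seed = 1L) {
  mk <- trueMarkerPositions(trueMap)
  ch <- chromosomeTable(trueMap)
  if (!all(panel$chromosome %in% ch$name))
    stop("panel names a chromosome absent from the map")
  refs <- sprintf("EUPLOID%02d", seq_len(nEuploidRefs))
  cols <- c(panel$stock, refs)
  calls <- matrix("AA", nrow = nrow(mk), ncol = length(cols),
                  dimnames = list(mk$marker, cols))
  for (i in seq_len(nrow(panel))) {
    st <- panel[i, ]
    if (st$kind == "nulli_tetra") {
      gone <- mk$chromosome == st$chromosome
    } else {
      iv <- .deletedInterval(ch[ch$name == st$chromosome, ], st$arm,
                             st$retainedFraction)
      gone <- mk$chromosome == st$chromosome & mk$cM > iv[1] & mk$cM <= iv[2]
      if (st$arm == "S")  # short arm: distal is toward 0
        gone <- mk$chromosome == st$chromosome & mk$cM < iv[2]
    }
    calls[gone, st$stock] <- "NC"
  }
  groups <- stats::setNames(c(rep("aneuploid", nrow(panel)),
                              rep("euploid_ref", nEuploidRefs)), cols)
  CallMatrix(calls, groups)
}

#' Implant a donor introgression block
#'
#' Overwrites the listed accessions with the donor genotype at every marker
#' inside the cM span on the given chromosome (a zero-width span leaves the
#' matrix unchanged). Markers where the donor code equals the panel's only
#' genotype class stay monomorphic and carry no signal.
#'
#' @param mat a [CallMatrix-class].
#' @param accessions accessions carrying the introgression.
#' @param chromosome chromosome name in `trueMap`.
#' @param span numeric `c(start, end)` in cM, within the chromosome.
#' @param donorCode genotype call written inside the span (default `"BB"`).
#' @param trueMap the [TrueMap-class] giving marker positions.
#' @return the modified [CallMatrix-class].
#' @export
injectIntrogression <- function(mat, accessions, chromosome, span,
                                donorCode = "BB", trueMap) {
  stopifnot(is(mat, "CallMatrix"), length(span) == 2, span[1] <= span[2])
  missing <- setdiff(accessions, accessionNames(mat))
  if (length(missing))
    stop(sprintf("unknown accession(s): %s", paste(missing, collapse = ", ")))
  ch <- chromosomeTable(trueMap)
  if (!chromosome %in% ch$name) stop("unknown chromosome")
  if (span[1] < 0 || span[2] > ch$length[ch$name == chromosome])
    stop("span must lie within the chromosome")
  if (span[1] == span[2]) return(mat)
  mk <- trueMarkerPositions(trueMap)
  hit <- mk$marker[mk$chromosome == chromosome &
                     mk$cM >= span[1] & mk$cM <= span[2]]
  hit <- intersect(hit, markerNames(mat))
  calls <- genotypeCalls(mat)
  calls[hit, accessions] <- donorCode
  CallMatrix(calls, accessionGroups(mat))
}
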