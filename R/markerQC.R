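## Marker performance classification on genotype calls. The array software
## defines these categories on intensity clusters; at the call level the
## same six classes are re-expressed on genotype class counts and call rate.

#' QC configuration
#'
#' @param callrateMin minimum call rate below which a marker is CRBT
#'   (default 0.80, the threshold used for wide-cross material in place of
#'   the usual 0.97).
#' @param minMinorHom minimum minor-homozygote count for a PHR call
#'   (default 2).
#' @return list of class `qcConfig`.
#' @export
qcConfig <- function(callrateMin = 0.80, minMinorHom = 2L) {
  if (callrateMin <= 0 || callrateMin > 1)
    stop("callrateMin must lie in (0, 1]")
  structure(list(callrateMin = callrateMin,
                 minMinorHom = as.integer(minMinorHom)), class = "qcConfig")
}

#' Marker call rate
#'
#' Fraction of accessions with a call other than no-call; the
#' null-homozygote state counts as a call.
#'
#' @param x a [CallMatrix-class] or a character vector of calls.
#' @return named numeric vector of per-marker call rates.
#' @export
callRate <- function(x) {
  calls <- if (is(x, "CallMatrix")) genotypeCalls(x) else
    matrix(x, nrow = 1, dimnames = list("marker", NULL))
  if (ncol(calls) == 0) stop("no accessions")
  rowMeans(calls != "NC")
}

.classCounts <- function(row) {
  counts <- vapply(CALL_STATES, function(s) sum(row == s), integer(1))
  counts
}

.classifyRow <- function(row, cfg) {
  bad <- setdiff(unique(row), CALL_STATES)
  if (length(bad))
    stop(sprintf("unknown call symbol(s): %s", paste(bad, collapse = ", ")))
  counts <- .classCounts(row)
  cr <- 1 - counts[["NC"]] / length(row)
  called <- counts[c("AA", "AB", "BB", "NN")]
  present <- names(called)[called > 0]
  nonNull <- intersect(present, c("AA", "AB", "BB"))
  minorHom <- min(counts[["AA"]], counts[["BB"]])
  category <-
    if (cr < cfg$callrateMin) "CRBT"
    else if (counts[["NN"]] > 0 && length(nonNull) >= 2) "OTV"
    else if (length(present) == 1) "MHR"
    else if (all(c("AA", "AB", "BB") %in% present) &&
               minorHom >= cfg$minMinorHom) "PHR"
    else if ((length(present) == 2 && "AB" %in% present) ||
               all(c("AA", "AB", "BB") %in% present)) "NMH"
    else if (setequal(present, c("AA", "BB")) &&
               minorHom >= cfg$minMinorHom) "PHR"  # codominant, no het class
    else "Other"
  list(category = category, callRate = cr, counts = counts,
       minorHom = minorHom)
}

#' Classify a single marker
#'
#' Applies the six-category decision rule in order: call rate below threshold
#' (CRBT); null-homozygote cluster plus two or more ordinary genotype classes
#' (OTV); a single called class (MHR); all three ordinary classes with at
#' least `minMinorHom` minor homozygotes (PHR); two classes one of which is
#' the heterozygote, or all three classes short of the minor-homozygote
#' quorum (NMH); a codominant AA/BB pair meeting the quorum (PHR); anything
#' else (Other). Minor-allele ties are broken lexicographically (AA before
#' BB).
#'
#' @param row character vector of calls for one marker.
#' @param cfg a [qcConfig()].
#' @return list with `category`, `callRate`, `counts`, `minorHom`.
#' @export
classifyMarker <- function(row, cfg = qcConfig()) .classifyRow(row, cfg)

#' Classify every marker of a panel
#'
#' @param mat a [CallMatrix-class].
#' @param cfg a [qcConfig()].
#' @return data.frame with one row per marker: `marker`, `category`,
#'   `callRate`, per-state counts and `minorHom`.
#' @export
classifyMarkers <- function(mat, cfg = qcConfig()) {
  calls <- genotypeCalls(mat)
  res <- lapply(seq_len(nrow(calls)), function(i)
    .classifyRow(calls[i, ], cfg))
  counts <- t(vapply(res, function(r) r$counts, numeric(5)))
  colnames(counts) <- paste0("n", CALL_STATES)
  data.frame(marker = rownames(calls),
             category = vapply(res, function(r) r$category, character(1)),
             callRate = vapply(res, function(r) r$callRate, numeric(1)),
             counts,
             minorHom = vapply(res, function(r) r$minorHom, numeric(1)),
             row.names = NULL)
}

#' Count polymorphic markers between or within groups
#'
#' Restricted to useful markers (PHR, NMH, OTV), counts markers showing more
#' than one distinct called genotype among the pooled accessions of the
#' group(s); a single individual with a distinct genotype already counts as
#' a polymorphism. No-calls are ignored.
#'
#' @param mat a [CallMatrix-class].
#' @param groupA character vector of accession ids.
#' @param groupB optional second accession set, disjoint from `groupA`.
#' @param classes optional precomputed [classifyMarkers()] table for the full
#'   panel; computed if missing.
#' @param cfg a [qcConfig()] used when `classes` is computed here.
#' @return integer count of polymorphic useful markers.
#' @export
countPolymorphic <- function(mat, groupA, groupB = NULL, classes = NULL,
                             cfg = qcConfig()) {
  if (length(groupA) == 0 || (!is.null(groupB) && length(groupB) == 0))
    stop("groups must be non-empty")
  if (!is.null(groupB) && length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  acc <- c(groupA, groupB)
  missing <- setdiff(acc, accessionNames(mat))
  if (length(missing))
    stop(sprintf("unknown accession(s): %s", paste(missing, collapse = ", ")))
  if (is.null(classes)) classes <- classifyMarkers(mat, cfg)
  useful <- classes$marker[classes$category %in% c("PHR", "NMH", "OTV")]
  sub <- genotypeCalls(mat)[useful, acc, drop = FALSE]
  poly <- apply(sub, 1, function(row) {
    g <- unique(row[row != "NC"])
    length(g) > 1
  })
  sum(poly)
}

#' Dominance class of a polymorphic marker
#'
#' Within a stated accession group: codominant when the called classes are
#' AA and BB only (both present); dominant when they are exactly one
#' homozygote plus the heterozygote; partially codominant when both
#' homozygotes are present together with a heterozygote subset.
#' Null-homozygote calls are excluded from the decision.
#'
#' @param row character vector of calls for one marker restricted to the
#'   group.
#' @return one of `"codominant"`, `"dominant"`, `"partially_codominant"`.
#' @export
classifyDominance <- function(row) {
  g <- unique(row[row %in% c("AA", "AB", "BB")])
  if (length(g) < 2) stop("marker is monomorphic within the group")
  if (setequal(g, c("AA", "BB"))) "codominant"
  else if (setequal(g, c("AA", "AB")) || setequal(g, c("BB", "AB"))) "dominant"
  else "partially_codominant"
}

#' Total of useful markers from category counts
#'
#' Useful markers are those in the PHR, NMH or OTV categories.
#'
#' @param counts named numeric vector of per-category counts.
#' @return sum of the PHR, NMH and OTV counts.
#' @export
#' @examples
#' usefulTotal(c(PHR = 53569, NMH = 449941, OTV = 42789, MHR = 144320))
usefulTotal <- function(counts) {
  stopifnot(all(c("PHR", "NMH", "OTV") %in% names(counts)))
  sum(counts[c("PHR", "NMH", "OTV")])
}

#' Category summary of a panel
#'
#' @param mat a [CallMatrix-class].
#' @param cfg a [qcConfig()].
#' @param classes optional precomputed [classifyMarkers()] table.
#' @return list: `categoryCounts` (all six categories, summing to the marker
#'   count), `usefulCount`, `usefulShare` (percent, 1 decimal),
#'   `sampleCallRates` (per accession), and the `classes` table.
#' @export
summarizeCategories <- function(mat, cfg = qcConfig(), classes = NULL) {
  if (is.null(classes)) classes <- classifyMarkers(mat, cfg)
  lev <- c("PHR", "NMH", "OTV", "MHR", "CRBT", "Other")
  counts <- table(factor(classes$category, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  calls <- genotypeCalls(mat)
  list(categoryCounts = counts,
       usefulCount = usefulTotal(counts),
       usefulShare = percentShare(usefulTotal(counts), sum(counts)),
       sampleCallRates = colMeans(calls != "NC"),
       classes = classes)
}
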