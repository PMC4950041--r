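## Physical chromosome assignment from aneuploid stocks. A marker whose
## probe site is removed by a lesion fails to call (or calls as a
## hemizygous null) in that stock only; absence confined to exactly one
## lesion localizes the marker.

.absentIn <- function(calls) calls %in% c("NC", "NN")

.euploidPresent <- function(calls, refs, quorum) {
  sub <- calls[, refs, drop = FALSE]
  m <- !.absentIn(sub)
  dim(m) <- dim(sub)
  rowMeans(m) >= quorum
}

#' Assign markers to chromosomes from nullisomic/tetrasomic stocks
#'
#' A marker is assigned to chromosome C when it is called in at least
#' `quorum` of the euploid references, absent (no-call or null-homozygote)
#' in every nullisomic-C stock, and called in every stock nullisomic for
#' another chromosome. Markers absent in stocks of zero or two or more
#' chromosomes stay unassigned.
#'
#' @param mat a [CallMatrix-class] containing the stock and reference
#'   columns.
#' @param panel an [aneuploidPanel()]; only `nulli_tetra` rows are used.
#' @param euploidRefs accession ids of euploid references.
#' @param quorum minimum fraction of references calling the marker
#'   (default 0.9).
#' @return data.frame `marker`, `chromosome` (NA when unassigned), `armLow`,
#'   `armHigh`, `arm` (NA here), `source = "nulli_tetra"`.
#' @export
assignByNulliTetra <- function(mat, panel, euploidRefs, quorum = 0.9) {
  stocks <- panel[panel$kind == "nulli_tetra", , drop = FALSE]
  if (nrow(stocks) == 0) stop("panel has no nulli_tetra stocks")
  calls <- genotypeCalls(mat)
  unknown <- setdiff(c(stocks$stock, euploidRefs), colnames(calls))
  if (length(unknown))
    stop(sprintf("unknown accession(s): %s", paste(unknown, collapse = ", ")))
  present <- .euploidPresent(calls, euploidRefs, quorum)
  absent <- .absentIn(calls[, stocks$stock, drop = FALSE])
  dim(absent) <- c(nrow(calls), nrow(stocks))
  chrs <- unique(stocks$chromosome)
  ## per chromosome: absent in all / any of its stocks
  absAll <- vapply(chrs, function(ch) {
    idx <- which(stocks$chromosome == ch)
    rowSums(absent[, idx, drop = FALSE]) == length(idx)
  }, logical(nrow(calls)))
  absAny <- vapply(chrs, function(ch) {
    idx <- which(stocks$chromosome == ch)
    rowSums(absent[, idx, drop = FALSE]) > 0
  }, logical(nrow(calls)))
  dim(absAll) <- dim(absAny) <- c(nrow(calls), length(chrs))
  nHit <- rowSums(absAny)
  assigned <- rep(NA_character_, nrow(calls))
  one <- which(present & nHit == 1)
  if (length(one)) {
    hitIdx <- apply(absAny[one, , drop = FALSE], 1, which)
    complete <- absAll[cbind(one, hitIdx)]
    assigned[one[complete]] <- chrs[hitIdx[complete]]
  }
  data.frame(marker = rownames(calls), chromosome = assigned,
             armLow = NA_real_, armHigh = NA_real_, arm = NA_character_,
             source = "nulli_tetra", row.names = NULL)
}

#' Assign markers from terminal-deletion stocks
#'
#' A marker is assigned to the chromosome arm whose deletion stocks are the
#' only ones in which it is absent. Nested deletions on one arm refine the
#' localization: absence in a stock retaining the proximal fraction rho
#' places the marker distal to rho, presence places it proximal, so the
#' interval is `[max rho(absent), min rho(present) above that]` in
#' retained-fraction coordinates (0 = centromere, 1 = telomere).
#' Inconsistent absence patterns leave the marker unassigned.
#'
#' @inheritParams assignByNulliTetra
#' @return data.frame as in [assignByNulliTetra()] with `arm` and the
#'   `armLow`/`armHigh` interval filled in, `source = "deletion"`.
#' @export
assignByDeletion <- function(mat, panel, euploidRefs, quorum = 0.9) {
  stocks <- panel[panel$kind == "deletion", , drop = FALSE]
  if (nrow(stocks) == 0) stop("panel has no deletion stocks")
  calls <- genotypeCalls(mat)
  unknown <- setdiff(c(stocks$stock, euploidRefs), colnames(calls))
  if (length(unknown))
    stop(sprintf("unknown accession(s): %s", paste(unknown, collapse = ", ")))
  present <- .euploidPresent(calls, euploidRefs, quorum)
  absent <- .absentIn(calls[, stocks$stock, drop = FALSE])
  dim(absent) <- c(nrow(calls), nrow(stocks))
  out <- data.frame(marker = rownames(calls), chromosome = NA_character_,
                    armLow = NA_real_, armHigh = NA_real_,
                    arm = NA_character_, source = "deletion",
                    row.names = NULL)
  for (i in seq_len(nrow(calls))) {
    if (!present[i]) next
    hit <- which(absent[i, ])
    if (length(hit) == 0) next
    chrArm <- unique(stocks[hit, c("chromosome", "arm")])
    if (nrow(chrArm) != 1) next      # absences span several lesions
    ch <- chrArm$chromosome; arm <- chrArm$arm
    same <- which(stocks$chromosome == ch & stocks$arm == arm)
    lo <- max(stocks$retainedFraction[intersect(same, hit)])
    presentSame <- setdiff(same, hit)
    hi <- 1
    if (length(presentSame)) {
      rhos <- stocks$retainedFraction[presentSame]
      if (any(rhos <= lo)) next      # contradiction: present but deleted
      hi <- min(rhos)
    }
    out$chromosome[i] <- ch
    out$arm[i] <- arm
    out$armLow[i] <- lo
    out$armHigh[i] <- hi
  }
  out
}

#' Reconcile physical evidence from several sources
#'
#' Sources agreeing on a chromosome (or a single source speaking) give the
#' assignment; conflicting sources leave the marker unassigned and the
#' conflict is recorded. When several sources agree, the reported source is
#' the highest-priority one: nulli/tetra, then deletion, then survey.
#'
#' @param evidenceList list of evidence data.frames (as produced by
#'   [assignByNulliTetra()], [assignByDeletion()], or survey annotations
#'   with columns `marker`, `chromosome`, `source = "survey"`).
#' @return list with `evidence` (one row per marker) and `conflicts`
#'   (markers whose sources disagree, with the conflicting chromosomes).
#' @export
reconcilePhysical <- function(evidenceList) {
  if (length(evidenceList) == 0) stop("need at least one evidence source")
  priority <- c(nulli_tetra = 1, deletion = 2, survey = 3)
  all <- do.call(rbind, lapply(evidenceList, function(df) {
    need <- setdiff(c("marker", "chromosome", "source"), names(df))
    if (length(need)) stop("evidence lacks columns: ",
                           paste(need, collapse = ", "))
    if (is.null(df$arm)) df$arm <- NA_character_
    if (is.null(df$armLow)) df$armLow <- NA_real_
    if (is.null(df$armHigh)) df$armHigh <- NA_real_
    df[, c("marker", "chromosome", "armLow", "armHigh", "arm", "source")]
  }))
  all <- all[!is.na(all$chromosome), , drop = FALSE]
  markers <- unique(unlist(lapply(evidenceList, function(df) df$marker)))
  rows <- lapply(markers, function(mk) {
    sub <- all[all$marker == mk, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(marker = mk, chromosome = NA_character_,
                        armLow = NA_real_, armHigh = NA_real_,
                        arm = NA_character_, source = NA_character_,
                        conflict = FALSE))
    chrs <- unique(sub$chromosome)
    if (length(chrs) > 1)
      return(data.frame(marker = mk, chromosome = NA_character_,
                        armLow = NA_real_, armHigh = NA_real_,
                        arm = NA_character_, source = NA_character_,
                        conflict = TRUE))
    best <- sub[order(priority[sub$source]), , drop = FALSE][1, ]
    ## keep the deletion arm interval if any source provides one
    armRow <- sub[!is.na(sub$arm), , drop = FALSE]
    if (nrow(armRow)) {
      best$arm <- armRow$arm[1]
      best$armLow <- armRow$armLow[1]
      best$armHigh <- armRow$armHigh[1]
    }
    best$conflict <- FALSE
    best
  })
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  conflicts <- ev$marker[ev$conflict]
  conflictTab <- all[all$marker %in% conflicts, , drop = FALSE]
  list(evidence = ev[, setdiff(names(ev), "conflict")],
       conflicts = conflictTab)
}
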