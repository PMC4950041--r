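## Readers and writers for the plain-text artifact formats. Readers reject
## malformed input (unknown symbols, ragged rows, duplicate ids) with the
## offending line number rather than repairing it; writers emit
## deterministic, sorted output.

.readDelimStrict <- function(path, sep) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("file has no data rows: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  width <- length(fields[[1]])
  bad <- which(lengths(fields) != width)
  if (length(bad))
    stop(sprintf("ragged row at line %d of %s", bad[1], path))
  fields
}

#' Read a genotype CSV into a CallMatrix
#'
#' Expected layout: a header of accession ids (first cell a label for the
#' marker column), then one row per marker with calls in
#' `AA`/`AB`/`BB`/`NN`/`NC`.
#'
#' @param path CSV file path.
#' @param groups optional named character vector of group labels per
#'   accession.
#' @return a [CallMatrix-class].
#' @export
readGenotypeCsv <- function(path, groups = NULL) {
  fields <- .readDelimStrict(path, ",")
  acc <- fields[[1]][-1]
  if (anyDuplicated(acc)) stop("duplicate accession ids in header")
  rows <- fields[-1]
  mk <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(mk))
    stop(sprintf("duplicate marker id at line %d",
                 which(duplicated(mk))[1] + 1L))
  calls <- do.call(rbind, lapply(rows, function(f) f[-1]))
  dimnames(calls) <- list(mk, acc)
  okSym <- calls %in% CALL_STATES
  dim(okSym) <- dim(calls)
  bad <- which(!okSym, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unknown call symbol '%s' at line %d",
                 calls[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L))
  CallMatrix(calls, groups)
}

#' Write a CallMatrix to genotype CSV
#' @param mat a [CallMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeCsv <- function(mat, path) {
  calls <- genotypeCalls(mat)
  header <- paste(c("marker", colnames(calls)), collapse = ",")
  body <- paste(rownames(calls),
                apply(calls, 1, paste, collapse = ","), sep = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a parent-coded population CSV
#'
#' Layout as [readGenotypeCsv()] but with calls `A`/`B`/`H`/`-` (missing).
#'
#' @param path CSV file path.
#' @return a [DhPopulation-class].
#' @export
readPopulationCsv <- function(path) {
  fields <- .readDelimStrict(path, ",")
  acc <- fields[[1]][-1]
  if (anyDuplicated(acc)) stop("duplicate line ids in header")
  rows <- fields[-1]
  mk <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(mk))
    stop(sprintf("duplicate marker id at line %d",
                 which(duplicated(mk))[1] + 1L))
  calls <- do.call(rbind, lapply(rows, function(f) f[-1]))
  dimnames(calls) <- list(mk, acc)
  okSym <- calls %in% c("A", "B", "H", "-")
  dim(okSym) <- dim(calls)
  bad <- which(!okSym, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unknown call symbol '%s' at line %d",
                 calls[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L))
  calls[calls == "-"] <- NA_character_
  DhPopulation(calls)
}

#' Write a DhPopulation to CSV
#' @param pop a [DhPopulation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePopulationCsv <- function(pop, path) {
  calls <- genotypeCalls(pop)
  calls[is.na(calls)] <- "-"
  header <- paste(c("marker", colnames(calls)), collapse = ",")
  body <- paste(rownames(calls),
                apply(calls, 1, paste, collapse = ","), sep = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genetic map TSV
#'
#' Columns `marker`, `chromosome`, `cM`, `bin`; output is sorted by
#' chromosome and position, cM at 0.1 precision.
#'
#' @param path TSV file path.
#' @return a [GeneticMap-class].
#' @export
readMapTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("marker", "chromosome", "cM", "bin"), names(tab))
  if (length(need))
    stop("map file lacks column(s): ", paste(need, collapse = ", "))
  if (any(is.na(tab$cM)) || any(tab$cM < 0))
    stop("cM must be non-negative")
  tab$cM <- roundHalfUp(tab$cM, 1)
  GeneticMap(tab)
}

#' Write a genetic map TSV
#' @param map a [GeneticMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMapTsv <- function(map, path) {
  tab <- mapTable(map)
  tab$cM <- sprintf("%.1f", tab$cM)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an aneuploid panel TSV
#'
#' Columns `stock`, `kind`, `chromosome`, `arm`, `retained_fraction`.
#'
#' @param path TSV file path.
#' @return an [aneuploidPanel()].
#' @export
readPanelTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- setdiff(c("stock", "kind", "chromosome"), names(tab))
  if (length(need))
    stop("panel file lacks column(s): ", paste(need, collapse = ", "))
  aneuploidPanel(tab$stock, tab$kind, tab$chromosome,
                 arm = tab$arm %||% NA,
                 retainedFraction = tab$retained_fraction %||% NA)
}
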