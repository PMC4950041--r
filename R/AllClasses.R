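## Central S4 containers. The call vocabulary is fixed: the five-state call
## alphabet includes an explicit null-homozygote state (NN) so off-target
## variants can be represented, and NC marks a failed call.

#' Five-state genotype call alphabet
#'
#' `AA`/`AB`/`BB` are the usual diploid-style cluster calls, `NN` is the
#' null-homozygote (off-target variant) cluster and `NC` is a no-call.
#' @export
CALL_STATES <- c("AA", "AB", "BB", "NN", "NC")

## Parent-coded calls for a doubled-haploid population; H marks residual
## heterozygosity (treated as missing by the mapping stages), NA is missing.
DH_STATES <- c("A", "B", "H")

#' CallMatrix: genotype calls for a marker-by-accession panel
#'
#' An S4 container for a markers x accessions matrix of five-state genotype
#' calls (see [CALL_STATES]) together with a group label per accession
#' (e.g. elite hexaploid, Watkins landrace, tetraploid, wild relative,
#' aneuploid stock, mapping line).
#'
#' @slot calls character matrix, markers in rows, accessions in columns,
#'   entries drawn from [CALL_STATES].
#' @slot groups named character vector of group labels, one per accession,
#'   names matching `colnames(calls)`.
#' @export
setClass("CallMatrix", representation(calls = "matrix", groups = "character"))

setValidity("CallMatrix", function(object) {
  m <- object@calls
  if (!is.character(m)) return("calls must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("calls must carry marker rownames and accession colnames")
  if (anyDuplicated(rownames(m))) return("duplicate marker ids")
  if (anyDuplicated(colnames(m))) return("duplicate accession ids")
  bad <- setdiff(unique(as.vector(m)), CALL_STATES)
  if (length(bad))
    return(sprintf("unknown call symbol(s): %s", paste(bad, collapse = ", ")))
  if (!identical(sort(names(object@groups)), sort(colnames(m))))
    return("groups must be named by the accession ids")
  TRUE
})

#' Construct a CallMatrix
#'
#' @param calls character matrix of calls (markers x accessions) with
#'   dimnames; entries in [CALL_STATES].
#' @param groups character vector of group labels, either named by accession
#'   or in column order; defaults to a single `"panel"` group.
#' @return a [CallMatrix-class] object.
#' @export
CallMatrix <- function(calls, groups = NULL) {
  if (is.null(groups)) groups <- rep("panel", ncol(calls))
  if (is.null(names(groups))) {
    stopifnot(length(groups) == ncol(calls))
    names(groups) <- colnames(calls)
  }
  new("CallMatrix", calls = calls, groups = groups[colnames(calls)])
}

#' DhPopulation: parent-coded doubled-haploid genotypes
#'
#' Markers x lines matrix of parent-coded calls: `"A"`, `"B"`, `"H"`
#' (residual heterozygosity) or `NA` (missing).
#'
#' @slot calls character matrix markers x lines.
#' @export
setClass("DhPopulation", representation(calls = "matrix"))

setValidity("DhPopulation", function(object) {
  m <- object@calls
  if (!is.character(m)) return("calls must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("calls must carry marker rownames and line colnames")
  if (anyDuplicated(rownames(m))) return("duplicate marker ids")
  bad <- setdiff(unique(as.vector(m)), c(DH_STATES, NA))
  if (length(bad))
    return(sprintf("unknown call symbol(s): %s", paste(bad, collapse = ", ")))
  if (all(is.na(m))) return("population has no informative calls")
  TRUE
})

#' Construct a DhPopulation
#' @param calls character matrix of `"A"`/`"B"`/`"H"`/`NA` calls
#'   (markers x lines).
#' @return a [DhPopulation-class] object.
#' @export
DhPopulation <- function(calls) new("DhPopulation", calls = calls)

#' GeneticMap: ordered marker positions on linkage groups
#'
#' Records `(marker, chromosome, cM, bin)`, ordered by chromosome and
#' non-decreasing cM. All members of a bin share the cM position of their
#' representative frame marker.
#'
#' @slot table data.frame with columns `marker`, `chromosome`, `cM`, `bin`.
#' @export
setClass("GeneticMap", representation(table = "data.frame"))

setValidity("GeneticMap", function(object) {
  tab <- object@table
  need <- c("marker", "chromosome", "cM", "bin")
  if (!all(need %in% names(tab)))
    return(sprintf("map table needs columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$marker)) return("duplicate marker ids in map")
  if (any(is.na(tab$cM)) || any(tab$cM < 0)) return("cM must be non-negative")
  ok <- vapply(split(tab$cM, tab$chromosome),
               function(x) !is.unsorted(x), logical(1))
  if (!all(ok)) return("cM must be non-decreasing within each chromosome")
  TRUE
})

#' Construct a GeneticMap
#' @param table data.frame with columns `marker`, `chromosome`, `cM` and
#'   optionally `bin` (defaults to one bin per distinct position). Rows are
#'   sorted by chromosome and position.
#' @return a [GeneticMap-class] object.
#' @export
GeneticMap <- function(table) {
  if (is.null(table$bin)) {
    table$bin <- paste0(table$chromosome, "_",
                        as.integer(factor(table$cM)))
  }
  table <- table[order(table$chromosome, table$cM, table$marker), , drop = FALSE]
  rownames(table) <- NULL
  new("GeneticMap", table = table[, c("marker", "chromosome", "cM", "bin")])
}

#' TrueMap: simulation ground truth
#'
#' The generating map of the synthetic-data module: chromosome lengths with
#' centromere positions, and true marker positions (several markers may share
#' one position, forming a true bin).
#'
#' @slot chromosomes data.frame `name`, `length` (cM), `centromere` (cM).
#' @slot markers data.frame `marker`, `chromosome`, `cM`, ordered within
#'   chromosome.
#' @export
setClass("TrueMap",
         representation(chromosomes = "data.frame", markers = "data.frame"))

setValidity("TrueMap", function(object) {
  ch <- object@chromosomes; mk <- object@markers
  if (!all(c("name", "length", "centromere") %in% names(ch)))
    return("chromosomes needs name/length/centromere")
  if (!all(c("marker", "chromosome", "cM") %in% names(mk)))
    return("markers needs marker/chromosome/cM")
  if (anyDuplicated(mk$marker)) return("duplicate marker ids")
  if (!all(mk$chromosome %in% ch$name)) return("marker on unknown chromosome")
  len <- stats::setNames(ch$length, ch$name)
  if (any(mk$cM < 0) || any(mk$cM > len[mk$chromosome]))
    return("marker positions must lie within [0, chromosome length]")
  ok <- vapply(split(mk$cM, mk$chromosome),
               function(x) !is.unsorted(x), logical(1))
  if (!all(ok)) return("marker positions must be non-decreasing")
  if (any(ch$centromere <= 0) || any(ch$centromere >= ch$length))
    return("centromere must lie strictly inside the chromosome")
  TRUE
})

#' Construct a TrueMap
#' @param chromosomes data.frame `name`, `length`, `centromere` (cM).
#' @param markers data.frame `marker`, `chromosome`, `cM`; sorted on
#'   construction.
#' @return a [TrueMap-class] object.
#' @export
TrueMap <- function(chromosomes, markers) {
  markers <- markers[order(markers$chromosome, markers$cM, markers$marker), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  new("TrueMap", chromosomes = chromosomes, markers = markers)
}
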