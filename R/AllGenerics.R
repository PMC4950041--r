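#' @import methods
NULL

#' Marker identifiers of a container
#' @param x a [CallMatrix-class], [DhPopulation-class], [GeneticMap-class] or
#'   [TrueMap-class] object.
#' @return character vector of marker ids.
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' Accession (or line) identifiers of a container
#' @param x a [CallMatrix-class] or [DhPopulation-class] object.
#' @return character vector of accession ids.
#' @export
setGeneric("accessionNames", function(x) standardGeneric("accessionNames"))

#' Group label per accession
#' @param x a [CallMatrix-class] object.
#' @return named character vector of group labels.
#' @export
setGeneric("accessionGroups", function(x) standardGeneric("accessionGroups"))

#' Genotype call matrix
#' @param x a [CallMatrix-class] or [DhPopulation-class] object.
#' @return the underlying character matrix (markers x accessions).
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' Map table of a GeneticMap
#' @param x a [GeneticMap-class] object.
#' @return data.frame with columns marker, chromosome, cM, bin.
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname markerNames
#' @export
setMethod("markerNames", "CallMatrix", function(x) rownames(x@calls))
#' @rdname markerNames
#' @export
setMethod("markerNames", "DhPopulation", function(x) rownames(x@calls))
#' @rdname markerNames
#' @export
setMethod("markerNames", "GeneticMap", function(x) x@table$marker)
#' @rdname markerNames
#' @export
setMethod("markerNames", "TrueMap", function(x) x@markers$marker)

#' @rdname accessionNames
#' @export
setMethod("accessionNames", "CallMatrix", function(x) colnames(x@calls))
#' @rdname accessionNames
#' @export
setMethod("accessionNames", "DhPopulation", function(x) colnames(x@calls))

#' @rdname accessionGroups
#' @export
setMethod("accessionGroups", "CallMatrix", function(x) x@groups)

#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "CallMatrix", function(x) x@calls)
#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "DhPopulation", function(x) x@calls)

#' @rdname mapTable
#' @export
setMethod("mapTable", "GeneticMap", function(x) x@table)

#' Chromosome table of a TrueMap
#' @param x a [TrueMap-class] object.
#' @return data.frame with columns name, length, centromere.
#' @export
setGeneric("chromosomeTable", function(x) standardGeneric("chromosomeTable"))
#' @rdname chromosomeTable
#' @export
setMethod("chromosomeTable", "TrueMap", function(x) x@chromosomes)

#' True marker positions of a TrueMap
#' @param x a [TrueMap-class] object.
#' @return data.frame with columns marker, chromosome, cM.
#' @export
setGeneric("trueMarkerPositions",
           function(x) standardGeneric("trueMarkerPositions"))
#' @rdname trueMarkerPositions
#' @export
setMethod("trueMarkerPositions", "TrueMap", function(x) x@markers)

setMethod("show", "CallMatrix", function(object) {
  cat(sprintf("CallMatrix: %d markers x %d accessions\n",
              nrow(object@calls), ncol(object@calls)))
  tab <- table(object@groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "DhPopulation", function(object) {
  cat(sprintf("DhPopulation: %d markers x %d lines, %.1f%% missing\n",
              nrow(object@calls), ncol(object@calls),
              100 * mean(is.na(object@calls))))
})

setMethod("show", "GeneticMap", function(object) {
  tab <- object@table
  cat(sprintf("GeneticMap: %d markers on %d chromosome(s), %.1f cM total\n",
              nrow(tab), length(unique(tab$chromosome)),
              sum(tapply(tab$cM, tab$chromosome, max))))
})

setMethod("show", "TrueMap", function(object) {
  cat(sprintf("TrueMap: %d chromosomes, %d markers at %d distinct positions\n",
              nrow(object@chromosomes), nrow(object@markers),
              nrow(unique(object@markers[c("chromosome", "cM")]))))
})
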