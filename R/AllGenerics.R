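#' @include AllClasses.R
NULL

#' @rdname filterLowExpression
#' @export
setGeneric("filterLowExpression", function(x, samples, minLog2 = 6,
                                           minSamples = 5L)
    standardGeneric("filterLowExpression"))

#' @rdname quantileNormalize
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname collapseProbes
#' @export
setGeneric("collapseProbes", function(x, map,
                                      method = c("max_mean_probe", "gene_mean"))
    standardGeneric("collapseProbes"))

#' @rdname groupMeans
#' @export
setGeneric("groupMeans", function(x, samples) standardGeneric("groupMeans"))

#' @rdname scoreSamples
#' @export
setGeneric("scoreSamples", function(x, panels) standardGeneric("scoreSamples"))

#' Accessors for ContrastResult objects
#'
#' `resultTable()` returns the per-gene result `data.frame`; `priorDf()` and
#' `priorVar()` return the empirical-Bayes hyperparameters (d0, s0^2);
#' `candidateGenes()` applies the fold-change / FDR candidate rule.
#'
#' @param object A [ContrastResult-class] object.
#' @name ContrastResult-accessors
NULL

#' @rdname ContrastResult-accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname ContrastResult-accessors
#' @export
setGeneric("priorDf", function(object) standardGeneric("priorDf"))

#' @rdname ContrastResult-accessors
#' @export
setGeneric("priorVar", function(object) standardGeneric("priorVar"))

#' @rdname selectCandidates
#' @export
setGeneric("candidateGenes", function(object, fcThreshold = 2,
                                      qThreshold = 0.05)
    standardGeneric("candidateGenes"))

#' Accessors for SignaturePartition objects
#'
#' @param object A [SignaturePartition-class] object.
#' @param region A region name from [vennRegionNames()].
#' @name SignaturePartition-accessors
NULL

#' @rdname SignaturePartition-accessors
#' @export
setGeneric("regionGenes", function(object, region) standardGeneric("regionGenes"))

#' @rdname SignaturePartition-accessors
#' @export
setGeneric("regionSizes", function(object) standardGeneric("regionSizes"))

#' Accessors for CellTypeScores objects
#'
#' `scoreMatrix()` returns the panels x samples score matrix; `panelCoverage()`
#' the fraction of each panel's marker genes found in the expression matrix.
#'
#' @param object A [CellTypeScores-class] object.
#' @name CellTypeScores-accessors
NULL

#' @rdname CellTypeScores-accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))

#' @rdname CellTypeScores-accessors
#' @export
setGeneric("panelCoverage", function(object) standardGeneric("panelCoverage"))
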