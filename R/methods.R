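#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ContrastResult-accessors
#' @export
setMethod("resultTable", "ContrastResult", function(object) object@table)

#' @rdname ContrastResult-accessors
#' @export
setMethod("priorDf", "ContrastResult", function(object) object@d0)

#' @rdname ContrastResult-accessors
#' @export
setMethod("priorVar", "ContrastResult", function(object) object@s0sq)

#' @describeIn selectCandidates Method for [ContrastResult-class]; returns the
#'   candidate gene IDs only.
#' @export
setMethod("candidateGenes", "ContrastResult",
    function(object, fcThreshold = 2, qThreshold = 0.05) {
        selectCandidates(object, fcThreshold, qThreshold)$gene
    })

setMethod("show", "ContrastResult", function(object) {
    tb <- object@table
    cat("ContrastResult \"", object@contrast, "\": ",
        object@conditionA, " vs ", object@conditionB,
        " (paired, ", length(object@subjects), " subjects)\n", sep = "")
    cat("  genes tested: ", nrow(tb),
        "; prior df d0 = ", format(object@d0, digits = 4),
        ", prior variance s0^2 = ", format(object@s0sq, digits = 4), "\n",
        sep = "")
    cat("  candidates at |FC|>2, q<0.05: ",
        nrow(selectCandidates(object)), "\n", sep = "")
})

#' @rdname SignaturePartition-accessors
#' @export
setMethod("regionGenes", "SignaturePartition", function(object, region) {
    region <- match.arg(region, vennRegionNames())
    object@regions[[region]]
})

#' @rdname SignaturePartition-accessors
#' @export
setMethod("regionSizes", "SignaturePartition", function(object) {
    vapply(object@regions[vennRegionNames()], length, integer(1))
})

setMethod("show", "SignaturePartition", function(object) {
    sz <- regionSizes(object)
    cat("SignaturePartition over contrasts: ",
        paste(object@contrasts, collapse = ", "), "\n", sep = "")
    for (r in vennRegionNames())
        cat(sprintf("  %-22s %d\n", r, sz[[r]]))
    cat("  union: ", sum(sz), " genes\n", sep = "")
})

#' @rdname CellTypeScores-accessors
#' @export
setMethod("scoreMatrix", "CellTypeScores", function(object) object@scores)

#' @rdname CellTypeScores-accessors
#' @export
setMethod("panelCoverage", "CellTypeScores", function(object) object@coverage)

setMethod("show", "CellTypeScores", function(object) {
    cat("CellTypeScores: ", nrow(object@scores), " panels x ",
        ncol(object@scores), " samples\n", sep = "")
    lo <- names(which(object@coverage < 1))
    if (length(lo))
        cat("  panels with partial marker coverage: ",
            paste(lo, collapse = ", "), "\n", sep = "")
})
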