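#' @import methods
NULL

#' Biopsy condition labels
#'
#' The four biopsy conditions of the paired study design: non-involved skin
#' (`L_NI`), acne papule at baseline (`L1`), papule after vehicle treatment,
#' i.e. spontaneous resolution (`L3`), and papule after trifarotene treatment
#' (`R3`).
#'
#' @return Character vector of the four condition labels.
#' @export
#' @examples
#' acneConditions()
acneConditions <- function() c("L_NI", "L1", "L3", "R3")

#' Names of the seven Venn regions of three contrast signatures
#'
#' Three candidate gene sets (papule, vehicle, trifarotene signatures)
#' partition their union into seven disjoint regions; these are their fixed
#' names, used by [vennPartition()] and the synthetic-study generator.
#'
#' @return Character vector of length 7.
#' @export
vennRegionNames <- function() {
    c("papule_only", "vehicle_only", "trifarotene_only",
      "papule_vehicle", "papule_trifarotene", "vehicle_trifarotene",
      "all_three")
}

#' ContrastResult: per-gene paired differential expression for one contrast
#'
#' Holds the per-gene moderated-t results of one paired two-condition
#' contrast, together with the empirical-Bayes hyperparameters shared by all
#' genes of the contrast.
#'
#' @slot contrast Name of the contrast (e.g. `"papule"`).
#' @slot conditionA,conditionB The two condition labels compared
#'   (differences are A minus B on the log2 scale).
#' @slot subjects Subject IDs contributing complete pairs.
#' @slot table `data.frame` with one row per gene: `gene`, `log2fc` (mean
#'   paired difference), `fc` (signed linear fold change), `s2` (residual
#'   variance), `df` (residual degrees of freedom), `t` (moderated t),
#'   `dfTotal` (prior + residual df), `p` (two-sided raw p), `q` (BH FDR).
#' @slot d0 Prior degrees of freedom (may be `Inf` for total shrinkage).
#' @slot s0sq Prior variance.
#'
#' @aliases ContrastResult
#' @exportClass ContrastResult
setClass("ContrastResult",
    slots = c(
        contrast = "character",
        conditionA = "character",
        conditionB = "character",
        subjects = "character",
        table = "data.frame",
        d0 = "numeric",
        s0sq = "numeric"
    )
)

setValidity("ContrastResult", function(object) {
    tb <- object@table
    need <- c("gene", "log2fc", "fc", "s2", "df", "t", "dfTotal", "p", "q")
    if (!all(need %in% names(tb)))
        return(paste("table must contain columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(tb$gene))
        return("duplicate gene IDs in result table")
    if (length(object@d0) != 1L || object@d0 < 0)
        return("d0 must be a single nonnegative number (possibly Inf)")
    if (length(object@s0sq) != 1L || !is.finite(object@s0sq) || object@s0sq < 0)
        return("s0sq must be a single nonnegative finite number")
    ok <- !is.na(tb$p) & !is.na(tb$q)
    if (any(tb$q[ok] + 1e-12 < tb$p[ok]))
        return("BH-adjusted q must be >= raw p genewise")
    TRUE
})

#' SignaturePartition: the seven-region Venn over three candidate gene sets
#'
#' @slot regions Named list of 7 character vectors (see [vennRegionNames()]),
#'   pairwise disjoint; their union is the union of the three input sets.
#' @slot contrasts Names of the three contrasts the partition was built from.
#' @slot thresholds List echoing the fold-change / FDR thresholds used.
#'
#' @aliases SignaturePartition
#' @exportClass SignaturePartition
setClass("SignaturePartition",
    slots = c(
        regions = "list",
        contrasts = "character",
        thresholds = "list"
    )
)

setValidity("SignaturePartition", function(object) {
    if (!identical(sort(names(object@regions)), sort(vennRegionNames())))
        return("regions must be named by the 7 canonical Venn region names")
    all_genes <- unlist(object@regions, use.names = FALSE)
    if (anyDuplicated(all_genes))
        return("Venn regions must be pairwise disjoint")
    TRUE
})

#' CellTypeScores: marker-panel scores per sample
#'
#' @slot scores Numeric matrix, panels x samples; each entry is the mean log2
#'   expression of the panel's marker genes found in the expression matrix.
#' @slot coverage Named numeric vector, fraction of each panel's genes found.
#'
#' @aliases CellTypeScores
#' @exportClass CellTypeScores
setClass("CellTypeScores",
    slots = c(scores = "matrix", coverage = "numeric")
)

setValidity("CellTypeScores", function(object) {
    if (!identical(rownames(object@scores), names(object@coverage)))
        return("coverage must be named by the score-matrix panel rows")
    if (any(object@coverage <= 0 | object@coverage > 1))
        return("coverage must lie in (0, 1]")
    if (!all(is.finite(object@scores)))
        return("scores must be finite")
    TRUE
})
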