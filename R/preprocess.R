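#' @include AllGenerics.R study.R
NULL

# resolve (matrix, samples) for matrix-signature methods
check_annotated <- function(x, samples) {
    samples <- validate_sample_table(samples)
    missing <- setdiff(colnames(x), samples$sample_id)
    if (length(missing))
        stop("sample(s) not annotated in the sample table: ",
             paste(missing, collapse = ", "))
    samples[match(colnames(x), samples$sample_id), ]
}

#' Filter low-expression features
#'
#' Keeps a feature iff there is at least one condition group in which at
#' least `minSamples` of that group's samples have log2 expression `>=`
#' `minLog2` (inclusive threshold: an intensity of exactly 2^6 counts).
#' Feature order is preserved. Condition groups are the four biopsy classes.
#'
#' @param x Log2 expression matrix or a `SummarizedExperiment` from
#'   [acneStudy()].
#' @param samples Sample table (`data.frame`); ignored for the
#'   `SummarizedExperiment` method.
#' @param minLog2 Log2 expression threshold (default 6, i.e. 2^6 on the
#'   linear scale).
#' @param minSamples Minimum number of samples at or above the threshold in
#'   some single condition (default 5).
#' @return Object of the same class as `x`, with failing features removed.
#' @export
#' @rdname filterLowExpression
setMethod("filterLowExpression", signature(x = "matrix"),
    function(x, samples, minLog2 = 6, minSamples = 5L) {
        samples <- check_annotated(x, samples)
        keep <- rep(FALSE, nrow(x))
        for (cond in unique(samples$condition)) {
            cols <- samples$sample_id[samples$condition == cond]
            keep <- keep |
                rowSums(x[, cols, drop = FALSE] >= minLog2) >= minSamples
        }
        if (!any(keep))
            warning("no feature passes the expression filter")
        x[keep, , drop = FALSE]
    })

#' @rdname filterLowExpression
#' @export
setMethod("filterLowExpression", signature(x = "SummarizedExperiment"),
    function(x, samples, minLog2 = 6, minSamples = 5L) {
        p <- study_parts(x)
        kept <- filterLowExpression(p$exprs, p$samples, minLog2, minSamples)
        x[rownames(kept), ]
    })

#' Quantile-normalize an expression matrix
#'
#' Forces every column to the same empirical distribution: after
#' normalization each column's sorted values equal the row-wise mean of the
#' column-sorted input, with ties within a column receiving the mean of the
#' reference values they span. A cross-sample normalization utility for
#' matrices not already normalized upstream. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x Log2 expression matrix or `SummarizedExperiment`.
#' @return Same class as `x`; a single-column input is returned unchanged
#'   with a warning.
#' @export
#' @rdname quantileNormalize
setMethod("quantileNormalize", signature(x = "matrix"), function(x) {
    if (ncol(x) < 2L) {
        warning("quantile normalization needs >= 2 samples; returning input")
        return(x)
    }
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", signature(x = "SummarizedExperiment"),
    function(x) {
        SummarizedExperiment::assay(x, "log2") <-
            quantileNormalize(SummarizedExperiment::assay(x, "log2"))
        x
    })

#' Collapse probe-level rows to unique genes
#'
#' `max_mean_probe` keeps, per gene, the probe with the highest mean log2
#' expression (ties broken by lexicographic probe ID); `gene_mean` averages
#' all of a gene's probes. Features absent from the map are dropped with a
#' message; genes appear in order of first occurrence among the mapped
#' features.
#'
#' @param x Probe-level log2 matrix or `SummarizedExperiment`.
#' @param map `data.frame` with columns `probe_id`, `gene_symbol` (see
#'   [readProbeGeneMap()]).
#' @param method `"max_mean_probe"` or `"gene_mean"`.
#' @return Same class as `x`, one row per gene.
#' @export
#' @rdname collapseProbes
setMethod("collapseProbes", signature(x = "matrix"),
    function(x, map, method = c("max_mean_probe", "gene_mean")) {
        method <- match.arg(method)
        if (anyDuplicated(map$probe_id))
            stop("probe IDs in the map must be unique")
        idx <- match(rownames(x), map$probe_id)
        n_drop <- sum(is.na(idx))
        if (n_drop == nrow(x))
            stop("no feature of the matrix is present in the probe map")
        if (n_drop > 0)
            message(n_drop, " unmapped feature(s) dropped")
        x <- x[!is.na(idx), , drop = FALSE]
        gene <- map$gene_symbol[idx[!is.na(idx)]]
        genes <- unique(gene)
        if (method == "gene_mean") {
            out <- rowsum(x, gene, reorder = FALSE) /
                as.vector(table(gene)[unique(gene)])
            out <- out[genes, , drop = FALSE]
        } else {
            rm_ <- rowMeans(x)
            pick <- vapply(genes, function(g) {
                rows <- which(gene == g)
                best <- rows[rm_[rows] == max(rm_[rows])]
                best[order(rownames(x)[best])][1L]
            }, integer(1))
            out <- x[pick, , drop = FALSE]
        }
        rownames(out) <- genes
        out
    })

#' @rdname collapseProbes
#' @export
setMethod("collapseProbes", signature(x = "SummarizedExperiment"),
    function(x, map, method = c("max_mean_probe", "gene_mean")) {
        p <- study_parts(x)
        acneStudy(collapseProbes(p$exprs, map, method), p$samples)
    })

#' Per-condition group means
#'
#' Arithmetic mean of the log2 values per gene and condition -- equivalently
#' the log2 of the geometric mean of the linear-scale intensities, the
#' convention used for reporting group expression levels.
#'
#' @param x Log2 expression matrix or `SummarizedExperiment`.
#' @param samples Sample table; ignored for the `SummarizedExperiment`
#'   method.
#' @return Numeric matrix, genes x conditions (conditions present in the
#'   sample table, in [acneConditions()] order).
#' @export
#' @rdname groupMeans
setMethod("groupMeans", signature(x = "matrix"), function(x, samples) {
    samples <- check_annotated(x, samples)
    conds <- intersect(acneConditions(), unique(samples$condition))
    if (!length(conds)) stop("no condition groups present")
    out <- vapply(conds, function(cond) {
        cols <- samples$sample_id[samples$condition == cond]
        if (!length(cols)) stop("empty condition group: ", cond)
        rowMeans(x[, cols, drop = FALSE])
    }, numeric(nrow(x)))
    if (nrow(x) == 1L)
        out <- matrix(out, nrow = 1L, dimnames = list(rownames(x), conds))
    out
})

#' @rdname groupMeans
#' @export
setMethod("groupMeans", signature(x = "SummarizedExperiment"),
    function(x, samples) {
        p <- study_parts(x)
        groupMeans(p$exprs, p$samples)
    })

#' Signed linear fold change from a log2 difference
#'
#' Maps a log2 fold change to the signed linear convention used in reported
#' tables: `2^delta` for `delta >= 0` and `-2^(-delta)` otherwise, so a
#' halving is reported as -2 rather than 0.5.
#'
#' @param delta Numeric vector of log2 fold changes.
#' @return Numeric vector of signed linear fold changes.
#' @export
#' @examples
#' signedFoldChange(c(0, 1, -1, -log2(23.5)))
signedFoldChange <- function(delta) {
    ifelse(delta >= 0, 2^delta, -2^(-delta))
}
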