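#' @include AllClasses.R
NULL

# validate an expression matrix: unique finite dimnames + finite values
validate_exprs <- function(m) {
    if (!is.matrix(m) || !is.numeric(m))
        stop("expression values must be a numeric matrix")
    if ((nrow(m) > 0L && is.null(rownames(m))) ||
        (ncol(m) > 0L && is.null(colnames(m))))
        stop("expression matrix must have feature and sample IDs as dimnames")
    dup <- rownames(m)[duplicated(rownames(m))]
    if (length(dup))
        stop("duplicate feature ID(s): ", paste(unique(dup), collapse = ", "))
    dup <- colnames(m)[duplicated(colnames(m))]
    if (length(dup))
        stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
    if (!all(is.finite(m))) {
        bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
        stop("non-finite expression value at feature '",
             rownames(m)[bad[1L]], "', sample '", colnames(m)[bad[2L]], "'")
    }
    invisible(m)
}

# validate a sample table: sample_id/subject_id/condition, enum + pairing rules
validate_sample_table <- function(samples) {
    need <- c("sample_id", "subject_id", "condition")
    if (!all(need %in% names(samples)))
        stop("sample table must have columns: ", paste(need, collapse = ", "))
    samples$condition <- as.character(samples$condition)
    bad <- setdiff(unique(samples$condition), acneConditions())
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "),
             "; allowed: ", paste(acneConditions(), collapse = ", "))
    dup <- samples$sample_id[duplicated(samples$sample_id)]
    if (length(dup))
        stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
    key <- paste(samples$subject_id, samples$condition)
    if (anyDuplicated(key)) {
        k <- key[duplicated(key)][1L]
        stop("subject has more than one sample for one condition: ", k)
    }
    invisible(samples)
}

#' Assemble an expression study as a SummarizedExperiment
#'
#' Combines a log2-scale expression matrix (features x samples) with its
#' sample table (subject and biopsy condition per sample) into a
#' `SummarizedExperiment` with assay `"log2"` and colData columns `subject`
#' and `condition`. All downstream functions accept this container.
#'
#' Matrices are exchanged on log2 scale throughout; linear-scale input must be
#' log2-transformed by the caller. Missing values are not supported: any
#' non-finite cell is an error.
#'
#' @param exprs Numeric matrix of log2 intensities with feature IDs as
#'   rownames and sample IDs as colnames.
#' @param samples `data.frame` with columns `sample_id`, `subject_id`,
#'   `condition`; every matrix column must appear exactly once, and a subject
#'   may contribute at most one sample per condition (see [acneConditions()]).
#' @return A [SummarizedExperiment::SummarizedExperiment] object.
#' @export
#' @examples
#' m <- matrix(rnorm(8, 8), 2, 4,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' samp <- data.frame(sample_id = paste0("s", 1:4), subject_id = "p1",
#'                    condition = acneConditions())
#' acneStudy(m, samp)
acneStudy <- function(exprs, samples) {
    validate_exprs(exprs)
    samples <- validate_sample_table(as.data.frame(samples))
    if (!setequal(colnames(exprs), samples$sample_id))
        stop("sample IDs of the matrix and the sample table must coincide; ",
             "missing from table: ",
             paste(setdiff(colnames(exprs), samples$sample_id), collapse = ", "))
    samples <- samples[match(colnames(exprs), samples$sample_id), ]
    cd <- S4Vectors::DataFrame(
        subject = samples$subject_id,
        condition = factor(samples$condition, levels = acneConditions()),
        row.names = samples$sample_id)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = exprs), colData = cd)
}

# internal: pull (matrix, samples data.frame) out of an SE
study_parts <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    list(
        exprs = SummarizedExperiment::assay(se, "log2"),
        samples = data.frame(
            sample_id = rownames(cd),
            subject_id = as.character(cd$subject),
            condition = as.character(cd$condition),
            stringsAsFactors = FALSE))
}

#' Sample conditions and subjects of a study
#'
#' Convenience accessors for the colData of a study built by [acneStudy()]
#' or [simulateStudy()].
#'
#' @param se A `SummarizedExperiment` from [acneStudy()].
#' @return Named character vector (names are sample IDs).
#' @export
sampleConditions <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    stats::setNames(as.character(cd$condition), rownames(cd))
}

#' @rdname sampleConditions
#' @export
sampleSubjects <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    stats::setNames(as.character(cd$subject), rownames(cd))
}
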