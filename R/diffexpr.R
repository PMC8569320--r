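#' @include AllClasses.R study.R preprocess.R
NULL

#' Within-subject paired differences for a two-condition contrast
#'
#' For each subject possessing both conditions, returns the per-gene log2
#' difference `conditionA - conditionB`. Subjects missing either biopsy are
#' dropped with a message; fewer than two complete subjects is an error.
#'
#' @param x Log2 expression matrix or `SummarizedExperiment`.
#' @param samples Sample table (`data.frame`); omit for a
#'   `SummarizedExperiment`.
#' @param conditionA,conditionB Condition labels (see [acneConditions()]).
#' @return Numeric matrix, genes x complete subjects (subject IDs as
#'   colnames).
#' @export
pairedDifferences <- function(x, samples = NULL, conditionA, conditionB) {
    if (methods::is(x, "SummarizedExperiment")) {
        p <- study_parts(x)
        x <- p$exprs
        samples <- p$samples
    }
    samples <- check_annotated(x, samples)
    if (conditionA == conditionB)
        stop("contrast conditions must differ")
    bad <- setdiff(c(conditionA, conditionB), acneConditions())
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "))
    sa <- samples[samples$condition == conditionA, ]
    sb <- samples[samples$condition == conditionB, ]
    complete <- intersect(sa$subject_id, sb$subject_id)
    dropped <- setdiff(union(sa$subject_id, sb$subject_id), complete)
    if (length(dropped))
        message("subject(s) lacking one condition dropped: ",
                paste(sort(dropped), collapse = ", "))
    if (length(complete) < 2L)
        stop("fewer than 2 subjects have both '", conditionA, "' and '",
             conditionB, "'")
    complete <- sort(complete)
    ca <- sa$sample_id[match(complete, sa$subject_id)]
    cb <- sb$sample_id[match(complete, sb$subject_id)]
    d <- x[, ca, drop = FALSE] - x[, cb, drop = FALSE]
    colnames(d) <- complete
    d
}

#' Method-of-moments empirical-Bayes variance prior
#'
#' Estimates the scaled-inverse-chi-square prior (`d0`, `s0^2`) of per-gene
#' residual variances from the moments of `e = log(s2)`: `d0` solves
#' `trigamma(d0/2) = var(e) - trigamma(df/2)` (bisection on \[0.1, 500\]) and
#' `log(s0^2) = mean(e) - digamma(df/2) + log(df/2) + digamma(d0/2) -
#' log(d0/2)`. When the observed dispersion of log-variances does not exceed
#' the sampling dispersion (`var(e) <= trigamma(df/2)`), `d0 = Inf`: total
#' shrinkage to the common variance; in the degenerate case of exactly
#' constant observed variances the common value itself is returned as
#' `s0^2` (no sampling-dispersion correction), so the moderated t then
#' coincides with the classic t.
#'
#' @param s2 Per-gene sample variances (non-positive values are excluded
#'   from the moments with a message).
#' @param df Residual degrees of freedom of each `s2`.
#' @return List with elements `d0` and `s0sq`.
#' @export
estimatePrior <- function(s2, df) {
    pos <- s2 > 0 & is.finite(s2)
    if (sum(!pos) > 0)
        message(sum(!pos), " non-positive variance(s) excluded from the prior fit")
    s2 <- s2[pos]
    if (length(s2) < 10L)
        stop("fewer than 10 positive variances; cannot fit the variance ",
             "prior -- if the data are noise-free, add measurement noise")
    e <- log(s2)
    ev <- stats::var(e)
    if (ev <= 1e-12) {
        # constant observed variances: no sampling dispersion at all, so
        # the common value itself is the prior variance
        return(list(d0 = Inf, s0sq = exp(mean(e))))
    }
    target <- ev - trigamma(df / 2)
    corrected_mean <- mean(e) - digamma(df / 2) + log(df / 2)
    if (target <= trigamma(500 / 2)) {
        return(list(d0 = Inf, s0sq = exp(corrected_mean)))
    }
    lo <- 0.1; hi <- 500
    if (target >= trigamma(lo / 2)) {
        d0 <- lo
    } else {
        for (i in 1:200) {                     # trigamma is decreasing in d0
            mid <- (lo + hi) / 2
            if (trigamma(mid / 2) > target) lo <- mid else hi <- mid
            if (hi - lo < 1e-10) break
        }
        d0 <- (lo + hi) / 2
    }
    s0sq <- exp(corrected_mean + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated paired t-test
#'
#' One-sample moderated t on a matrix of within-subject differences (from
#' [pairedDifferences()]): per gene, `beta` is the mean difference, `s2` the
#' sample variance with `df = n - 1`, the posterior variance is the
#' df-weighted blend `(d0*s0^2 + df*s2) / (d0 + df)`, and
#' `t = beta / sqrt(s2_post / n)` is referred to a t distribution with
#' `d0 + df` degrees of freedom (two-sided). Hyperparameters default to
#' [estimatePrior()] on the observed variances. Genes with `s2 = 0` obtain a
#' finite posterior variance through shrinkage whenever `d0 > 0`; if `d0 = 0`
#' and `s2 = 0` the p-value is `NaN` and excluded from BH adjustment.
#'
#' @param diffs Genes x subjects matrix of paired log2 differences.
#' @param contrast Name for the contrast (metadata only).
#' @param conditionA,conditionB Condition labels (metadata only).
#' @param d0,s0sq Optional fixed prior; `d0 = 0` gives the classic
#'   (shrinkage-free) one-sample t.
#' @return A [ContrastResult-class] object.
#' @export
fitModeratedT <- function(diffs, contrast = "contrast",
                          conditionA = NA_character_,
                          conditionB = NA_character_,
                          d0 = NULL, s0sq = NULL) {
    n <- ncol(diffs)
    if (n < 2L) stop("need >= 2 paired differences per gene")
    if (is.null(rownames(diffs)))
        rownames(diffs) <- sprintf("g%05d", seq_len(nrow(diffs)))
    if (is.null(colnames(diffs)))
        colnames(diffs) <- sprintf("subj%02d", seq_len(n))
    beta <- rowMeans(diffs)
    df <- n - 1
    s2 <- rowSums((diffs - beta)^2) / df
    if (is.null(d0) || is.null(s0sq)) {
        if (all(s2 <= 0))
            stop("all genes have zero variance across differences; the ",
                 "moderated t is undefined -- inject measurement noise")
        prior <- estimatePrior(s2, df)
        d0 <- prior$d0
        s0sq <- prior$s0sq
    }
    s2post <- if (is.infinite(d0)) rep(s0sq, length(s2))
        else (d0 * s0sq + df * s2) / (d0 + df)
    tmod <- beta / sqrt(s2post / n)
    df_total <- d0 + df
    p <- 2 * stats::pt(-abs(tmod), df = df_total)
    bad <- !is.finite(tmod)                     # s2post == 0 (d0 = 0, s2 = 0)
    if (any(bad)) {
        message(sum(bad), " zero-variance gene(s) with no shrinkage; ",
                "p set to NaN and excluded from BH")
        p[bad] <- NaN
    }
    q <- rep(NaN, length(p))
    q[!bad] <- bhAdjust(p[!bad])
    tb <- data.frame(
        gene = rownames(diffs), log2fc = beta, fc = signedFoldChange(beta),
        s2 = s2, df = df, t = tmod, dfTotal = df_total, p = p, q = q,
        row.names = NULL, stringsAsFactors = FALSE)
    methods::new("ContrastResult", contrast = contrast,
        conditionA = as.character(conditionA),
        conditionB = as.character(conditionB),
        subjects = colnames(diffs), table = tb, d0 = d0, s0sq = s0sq)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The step-up procedure: with `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1; values are returned in
#' the input order. Implemented directly so it can be validated against an
#' independent implementation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted q-values.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.04, 0.03, 0.05))
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must be finite and within [0, 1]")
    m <- length(p)
    if (m == 0L) return(numeric(0))
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(m / (m:1) * p[o]))
    q[order(o)]
}

#' Candidate differentially expressed genes
#'
#' A gene is a candidate iff `|signed fold change| > fcThreshold` and
#' `q < qThreshold`, both strict; its direction is the sign of the log2 fold
#' change. The defaults are the reporting convention absolute fold change
#' > 2 and FDR < 0.05.
#'
#' @param result A [ContrastResult-class] object.
#' @param fcThreshold Linear fold-change threshold (strict).
#' @param qThreshold BH FDR threshold (strict).
#' @return `data.frame` with columns `gene`, `direction` (+1/-1).
#' @export
#' @rdname selectCandidates
selectCandidates <- function(result, fcThreshold = 2, qThreshold = 0.05) {
    tb <- resultTable(result)
    sel <- !is.na(tb$q) & abs(tb$fc) > fcThreshold & tb$q < qThreshold
    data.frame(gene = tb$gene[sel],
               direction = as.integer(sign(tb$log2fc[sel])),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Run one paired contrast end to end
#'
#' Convenience wrapper: [pairedDifferences()] then [fitModeratedT()].
#'
#' @inheritParams pairedDifferences
#' @param name Contrast name recorded in the result.
#' @return A [ContrastResult-class] object.
#' @export
runContrast <- function(x, samples = NULL, conditionA, conditionB,
                        name = paste0(conditionA, "_vs_", conditionB)) {
    d <- pairedDifferences(x, samples, conditionA, conditionB)
    fitModeratedT(d, contrast = name, conditionA = conditionA,
                  conditionB = conditionB)
}
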