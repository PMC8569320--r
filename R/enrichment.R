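#' @include diffexpr.R
NULL

#' Rank genes by a differential expression metric
#'
#' Produces the descending ranked list consumed by preranked gene-set
#' enrichment. Ties are broken by gene ID ascending, so the ranking is
#' deterministic.
#'
#' @param result A [ContrastResult-class] object, or a named numeric vector
#'   of metric values.
#' @param metric `"t"` (moderated t, default) or `"log2fc"`.
#' @return Named numeric vector sorted in decreasing metric order (a ranked
#'   list).
#' @export
rankGenes <- function(result, metric = c("t", "log2fc")) {
    if (methods::is(result, "ContrastResult")) {
        metric <- match.arg(metric)
        tb <- resultTable(result)
        v <- stats::setNames(tb[[metric]], tb$gene)
    } else {
        v <- result
    }
    if (is.null(names(v)) || anyDuplicated(names(v)))
        stop("metric values must be named by unique gene IDs")
    if (any(!is.finite(v)))
        stop("metric contains non-finite values; drop those genes first")
    v[order(-v, names(v))]
}

# core running-sum walk over the full ranked list
es_walk <- function(hits, absw, N) {
    nh <- sum(hits)
    wsum <- sum(absw[hits])
    steps <- numeric(N)
    if (wsum > 0) steps[hits] <- absw[hits] / wsum
    else steps[hits] <- 1 / nh        # all-zero weights: unweighted fallback
    steps[!hits] <- -1 / (N - nh)
    cumsum(steps)
}

#' Enrichment score of a gene set on a ranked list
#'
#' The classic weighted Kolmogorov-Smirnov running sum: walking down the
#' ranked list, a hit increments the sum by `|metric|^weight` normalized
#' over hits and a miss decrements it by `1/(N - n_hits)`. The enrichment
#' score is the running-sum value of maximal absolute deviation from zero
#' (signed; an exact positive/negative tie resolves positive). The leading
#' edge contains the hits at or before the extremum for a positive score,
#' and at or after it for a negative one. With `weight = 0` the score
#' reduces to the classical KS statistic on ranks.
#'
#' @param ranked Named numeric vector from [rankGenes()] (descending).
#' @param geneSet Character vector; members absent from the ranked list are
#'   dropped and `sizeUsed` records how many remain (zero overlap is an
#'   error).
#' @param weight Exponent on `|metric|` for hit increments (0 or 1).
#' @return List: `es`, `runningSum` (length `N`), `leadingEdge`,
#'   `sizeUsed`.
#' @export
enrichmentScore <- function(ranked, geneSet, weight = 1) {
    N <- length(ranked)
    hits <- names(ranked) %in% geneSet
    nh <- sum(hits)
    if (nh == 0L) stop("gene set has no overlap with the ranked list")
    if (nh == N) stop("gene set covers the whole ranked list")
    rs <- es_walk(hits, abs(ranked)^weight, N)
    mx <- max(rs); mn <- min(rs)
    if (mx >= -mn) {
        es <- mx
        i <- which(rs == mx)[1L]
        le <- names(ranked)[seq_len(i)][hits[seq_len(i)]]
    } else {
        es <- mn
        i <- which(rs == mn)[1L]
        idx <- if (i < N) seq.int(i + 1L, N) else integer(0)
        le <- names(ranked)[idx][hits[idx]]  # extremum sits just before a hit
    }
    list(es = es, runningSum = rs, leadingEdge = le, sizeUsed = nh)
}

# ES from sorted hit positions only (O(k)); used for the permutation null
es_from_positions <- function(pos, absw, N) {
    k <- length(pos)
    w <- absw[pos]
    wsum <- sum(w)
    cw <- if (wsum > 0) cumsum(w) / wsum else seq_len(k) / k
    gaps <- (pos - seq_len(k)) / (N - k)
    top <- cw - gaps
    bottom <- c(0, cw[-k]) - gaps
    mx <- max(top)
    mn <- min(bottom, 0)
    if (mx >= -mn) mx else mn
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' For each gene set of adequate size, computes the enrichment score on the
#' ranked list and compares it to a null distribution of scores of random
#' same-size gene sets (gene-label permutation -- appropriate when the
#' sample size is far too small for sample-label permutation). The p-value
#' uses the add-one estimator over null scores of the same sign,
#' `p = (1 + #{|ES_null| >= |ES|}) / (1 + n_same_sign)`, and NES normalizes
#' by the mean absolute same-sign null score. BH adjustment is applied
#' across the reported sets. Deterministic under a fixed seed.
#'
#' @param ranked Named numeric vector from [rankGenes()].
#' @param collection Named list of gene sets (e.g. from [readGmt()]).
#' @param nPerm Number of permutations (values below 100 warn: unstable p).
#' @param weight ES weight exponent, see [enrichmentScore()].
#' @param seed Integer seed for the permutation stream.
#' @param minSize,maxSize Sets whose overlap with the ranked list is outside
#'   this range are skipped (recorded in the `skipped` attribute).
#' @return `data.frame` with one row per scored set: `set`, `sizeUsed`,
#'   `es`, `nes`, `p`, `q`, `leadingEdge` (comma-joined).
#' @export
gseaPreranked <- function(ranked, collection, nPerm = 1000L, weight = 1,
                          seed = 1L, minSize = 5L, maxSize = 500L) {
    if (nPerm < 100L)
        warning("nPerm < 100 gives unstable permutation p-values")
    N <- length(ranked)
    absw <- abs(ranked)^weight
    overlap <- lapply(collection, function(g) which(names(ranked) %in% g))
    sizes <- lengths(overlap)
    keep <- sizes >= minSize & sizes <= maxSize & sizes < N
    skipped <- names(collection)[!keep]
    if (length(skipped))
        message(length(skipped), " set(s) skipped (overlap outside [",
                minSize, ", ", maxSize, "])")
    if (!any(keep)) {
        out <- data.frame(set = character(0), sizeUsed = integer(0),
                          es = numeric(0), nes = numeric(0), p = numeric(0),
                          q = numeric(0), leadingEdge = character(0))
        attr(out, "skipped") <- skipped
        return(out)
    }
    used <- names(collection)[keep]
    obs <- lapply(collection[used], function(g)
        enrichmentScore(ranked, g, weight))
    null_by_size <- with_local_seed(seed, {
        env <- new.env()
        for (k in sort(unique(sizes[keep]))) {
            assign(as.character(k), vapply(seq_len(nPerm), function(i)
                es_from_positions(sort(sample.int(N, k)), absw, N),
                numeric(1)), envir = env)
        }
        env
    })
    rows <- lapply(used, function(nm) {
        o <- obs[[nm]]
        nulls <- get(as.character(o$sizeUsed), envir = null_by_size)
        same <- if (o$es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
        p <- (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same))
        nes <- if (length(same) && mean(abs(same)) > 0)
            o$es / mean(abs(same)) else NA_real_
        data.frame(set = nm, sizeUsed = o$sizeUsed, es = o$es, nes = nes,
                   p = p, leadingEdge = paste(o$leadingEdge, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    out <- out[c("set", "sizeUsed", "es", "nes", "p", "q", "leadingEdge")]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}
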