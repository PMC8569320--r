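# independent brute-force oracles and small fixture builders

rand_exprs <- function(nr, nc, seed = 1, lo = 4, hi = 12) {
    set.seed(seed)
    matrix(runif(nr * nc, lo, hi), nr, nc,
           dimnames = list(sprintf("f%03d", seq_len(nr)),
                           sprintf("s%02d", seq_len(nc))))
}

# a 9-subject x 4-condition sample table over given sample ids
full_design <- function(nSubjects = 9) {
    conds <- acneConditions()
    subj <- sprintf("P%02d", seq_len(nSubjects))
    data.frame(
        sample_id = as.vector(outer(subj, conds, paste, sep = "_")),
        subject_id = rep(subj, times = length(conds)),
        condition = rep(conds, each = nSubjects),
        stringsAsFactors = FALSE)
}

rand_study_matrix <- function(nr, nSubjects = 9, seed = 1) {
    samp <- full_design(nSubjects)
    m <- rand_exprs(nr, nrow(samp), seed)
    colnames(m) <- samp$sample_id
    list(m = m, samples = samp)
}

# two-loop implementation of the expression filter rule
oracle_filter <- function(m, samples, minLog2, minSamples) {
    keep <- logical(nrow(m))
    for (i in seq_len(nrow(m))) {
        for (cond in unique(samples$condition)) {
            ids <- samples$sample_id[samples$condition == cond]
            n_ok <- 0
            for (s in ids) if (m[i, s] >= minLog2) n_ok <- n_ok + 1
            if (n_ok >= minSamples) keep[i] <- TRUE
        }
    }
    rownames(m)[keep]
}

# direct step-by-step running-sum walk for the enrichment score
oracle_es <- function(ranked, geneSet, weight) {
    hit <- names(ranked) %in% geneSet
    N <- length(ranked); nh <- sum(hit)
    w <- abs(ranked)^weight
    run <- 0; best <- 0
    maxv <- -Inf; minv <- Inf
    for (i in seq_len(N)) {
        run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / (N - nh)
        if (run > maxv) maxv <- run
        if (run < minv) minv <- run
    }
    unname(if (maxv >= -minv) maxv else minv)
}

# recompute-everything UPGMA: at each step rebuild the full matrix of
# average pairwise 1-Pearson distances between current clusters
oracle_upgma <- function(d0, labels) {
    clusters <- as.list(labels)
    merges <- list()
    dmat <- as.matrix(d0)
    while (length(clusters) > 1) {
        k <- length(clusters)
        best <- c(NA, NA); bestd <- Inf
        for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
            dd <- mean(dmat[clusters[[i]], clusters[[j]]])
            if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
        }
        merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        merges[[length(merges) + 1]] <- list(members = merged, height = bestd)
        clusters <- c(clusters[-best], list(merged))
    }
    merges
}

# canonical representation of an hclust merge tree for comparison
hclust_merges <- function(hc, labels) {
    members <- list()
    out <- list()
    for (i in seq_len(nrow(hc$merge))) {
        get_m <- function(v) if (v < 0) labels[-v] else members[[v]]
        mem <- sort(c(get_m(hc$merge[i, 1]), get_m(hc$merge[i, 2])))
        members[[i]] <- mem
        out[[i]] <- list(members = mem, height = hc$height[i])
    }
    out
}

# per-gene membership-bitmask partition of three sets
oracle_venn <- function(A, B, C) {
    u <- sort(unique(c(A, B, C)))
    code <- paste0(as.integer(u %in% A), as.integer(u %in% B),
                   as.integer(u %in% C))
    split(u, factor(code, levels = c("100", "010", "001", "110",
                                     "101", "011", "111")))
}
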