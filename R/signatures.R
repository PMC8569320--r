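#' @include diffexpr.R
NULL

#' Derive the papule, vehicle and trifarotene contrast signatures
#'
#' Runs the three paired contrasts of the study design with shared
#' thresholds: papule = L1 vs L_NI (lesion vs non-involved skin), vehicle =
#' L3 vs L1 (spontaneous resolution vs baseline papule), trifarotene = R3 vs
#' L1 (treated vs baseline papule), and selects candidate genes per contrast.
#'
#' @param x Log2 expression matrix or `SummarizedExperiment`.
#' @param samples Sample table; omit for a `SummarizedExperiment`.
#' @param fcThreshold,qThreshold Candidate thresholds, see
#'   [selectCandidates()].
#' @return List with elements `results` (named list of three
#'   [ContrastResult-class] objects), `candidates` (named list of three
#'   character vectors) and `partition` (the [SignaturePartition-class] of
#'   the candidate sets).
#' @export
deriveSignatures <- function(x, samples = NULL, fcThreshold = 2,
                             qThreshold = 0.05) {
    defs <- list(papule = c("L1", "L_NI"),
                 vehicle = c("L3", "L1"),
                 trifarotene = c("R3", "L1"))
    results <- lapply(names(defs), function(nm)
        runContrast(x, samples, defs[[nm]][1], defs[[nm]][2], name = nm))
    names(results) <- names(defs)
    candidates <- lapply(results, candidateGenes,
                         fcThreshold = fcThreshold, qThreshold = qThreshold)
    partition <- vennPartition(candidates$papule, candidates$vehicle,
                               candidates$trifarotene,
                               thresholds = list(fc = fcThreshold,
                                                 fdr = qThreshold))
    list(results = results, candidates = candidates, partition = partition)
}

#' Partition three gene sets into the seven Venn regions
#'
#' Exact set algebra over the papule (`A`), vehicle (`B`) and trifarotene
#' (`C`) candidate sets; the regions are named as in [vennRegionNames()],
#' are pairwise disjoint, and their union equals `A | B | C`.
#'
#' @param A,B,C Character vectors of gene IDs (papule, vehicle, trifarotene
#'   signatures).
#' @param thresholds Optional provenance list stored in the object.
#' @return A [SignaturePartition-class] object.
#' @export
#' @examples
#' vennPartition(c("g1", "g2", "g3"), c("g2", "g3"), c("g3", "g4"))
vennPartition <- function(A, B, C, thresholds = list()) {
    A <- unique(as.character(A)); B <- unique(as.character(B))
    C <- unique(as.character(C))
    u <- sort(unique(c(A, B, C)))
    inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
    regions <- list(
        papule_only = u[inA & !inB & !inC],
        vehicle_only = u[!inA & inB & !inC],
        trifarotene_only = u[!inA & !inB & inC],
        papule_vehicle = u[inA & inB & !inC],
        papule_trifarotene = u[inA & !inB & inC],
        vehicle_trifarotene = u[!inA & inB & inC],
        all_three = u[inA & inB & inC])
    methods::new("SignaturePartition", regions = regions,
                 contrasts = c("papule", "vehicle", "trifarotene"),
                 thresholds = thresholds)
}

#' Classify treatment-reversal patterns
#'
#' For each gene, the pattern is determined solely by the signs of the
#' papule and trifarotene log2 fold changes:
#' `up_in_papule_down_after_treatment` iff papule > 0 and trifarotene < 0,
#' the mirrored pattern for the opposite signs, `other` otherwise. The
#' typical input is the trifarotene-specific Venn region, probing whether
#' genes raised in the lesion are pushed back down by treatment alone.
#'
#' @param genes Character vector of gene IDs, or a
#'   [SignaturePartition-class] (its `trifarotene_only` region is used).
#' @param papuleResult,trifaroteneResult [ContrastResult-class] objects for
#'   the papule and trifarotene contrasts.
#' @return `data.frame` with columns `gene`, `pattern`.
#' @export
classifyReversal <- function(genes, papuleResult, trifaroteneResult) {
    if (methods::is(genes, "SignaturePartition"))
        genes <- regionGenes(genes, "trifarotene_only")
    pt <- resultTable(papuleResult)
    tt <- resultTable(trifaroteneResult)
    missing <- setdiff(genes, intersect(pt$gene, tt$gene))
    if (length(missing))
        stop("gene(s) missing from a contrast result: ",
             paste(missing, collapse = ", "))
    dp <- pt$log2fc[match(genes, pt$gene)]
    dt <- tt$log2fc[match(genes, tt$gene)]
    pattern <- ifelse(dp > 0 & dt < 0, "up_in_papule_down_after_treatment",
               ifelse(dp < 0 & dt > 0, "down_in_papule_up_after_treatment",
                      "other"))
    data.frame(gene = genes, pattern = pattern,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster genes by correlation distance with average linkage
#'
#' Restricts each gene's row to the samples of the chosen conditions,
#' z-scores it (mean 0, sd 1), and clusters genes with UPGMA (average
#' linkage) on the distance `1 - Pearson correlation` between scaled rows --
#' the heatmap ordering convention. Samples are not clustered. Genes are
#' sorted lexicographically before clustering so the result is invariant to
#' input order; a zero-variance gene row has its correlations set to 0
#' (distance 1 to everything) with a message.
#'
#' @param x Log2 expression matrix or `SummarizedExperiment`.
#' @param samples Sample table; omit for a `SummarizedExperiment`.
#' @param genes Character vector of >= 2 gene IDs present in `x`.
#' @param conditions Conditions defining the sample subset (default
#'   `L_NI`, `L1`, `R3`: the non-involved / baseline papule / treated
#'   heatmap).
#' @return List with elements `order` (gene IDs in dendrogram leaf order),
#'   `hclust` (the merge tree), `scaled` (the z-scored submatrix, rows in
#'   leaf order) and `zeroVariance` (gene IDs with flat profiles).
#' @export
clusterGenes <- function(x, samples = NULL, genes,
                         conditions = c("L_NI", "L1", "R3")) {
    if (methods::is(x, "SummarizedExperiment")) {
        p <- study_parts(x)
        x <- p$exprs
        samples <- p$samples
    }
    samples <- check_annotated(x, samples)
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
        stop("gene(s) not in the matrix: ", paste(missing, collapse = ", "))
    genes <- sort(unique(genes))
    if (length(genes) < 2L) stop("need >= 2 genes to cluster")
    cols <- samples$sample_id[samples$condition %in% conditions]
    if (length(cols) < 2L) stop("need >= 2 samples in the chosen conditions")
    sub <- x[genes, cols, drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    flat <- sds == 0
    if (any(flat))
        message(sum(flat), " zero-variance gene row(s); correlation set to 0")
    z <- (sub - rowMeans(sub)) / ifelse(flat, 1, sds)
    cc <- suppressWarnings(stats::cor(t(z)))
    cc[flat, ] <- 0; cc[, flat] <- 0
    diag(cc) <- 1
    d <- stats::as.dist(1 - cc)
    hc <- stats::hclust(d, method = "average")
    list(order = genes[hc$order], hclust = hc,
         scaled = z[hc$order, , drop = FALSE],
         zeroVariance = genes[flat])
}
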