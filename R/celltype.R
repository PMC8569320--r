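#' @include AllGenerics.R study.R
NULL

#' Built-in cell-type marker panels
#'
#' The marker panels used for in silico cell-type scoring of bulk skin
#' biopsies: 11 major cell types derived from single-cell RNA-seq of healthy
#' and acne skin, plus 4 macrophage subclasses (M0/M1/M2 from bulk
#' deconvolution reference profiles, SPP1+ macrophages -- the
#' osteopontin-expressing, fibrosis-associated subset -- from lung fibrosis
#' single-cell work).
#'
#' @param source `"all"` (default), `"major"` or `"macrophage"`.
#' @return Named list of character gene vectors with attributes
#'   `"description"` and `"source"` (per-panel `major`/`macrophage` labels).
#' @export
#' @examples
#' names(builtinMarkerPanels())
#' builtinMarkerPanels("macrophage")[["SPP1 macrophage"]]
builtinMarkerPanels <- function(source = c("all", "major", "macrophage")) {
    source <- match.arg(source)
    major <- list(
        "B cells" = c("MS4A1", "CD79A"),
        "Fibroblasts" = c("DCN", "COL6A2", "APOD", "CFD", "IGFBP5",
                          "COL1A2", "COL1A1", "COL3A1"),
        "Keratinocytes" = c("KRT5", "KRT1", "KRT14", "KRT15", "S100A2",
                            "KRT6A", "HOPX", "KRT10", "DSP"),
        "Langerhans cells" = "CD207",
        "Mast cells" = c("CPA3", "IL1RL1", "CTSG", "TPSAB1", "GATA2"),
        "Melanocytes" = c("MLANA", "MITF", "PMEL", "DCT"),
        "Myeloid cells" = c("CD68", "CTSS"),
        "Schwann cells" = "SCN7A",
        "T cells" = c("CD3D", "TRBC2", "IL7R", "PTPRC", "CXCR4"),
        "Venular cells" = c("SELE", "CD93", "TM4SF1", "A2M", "RCAN1"),
        "VSMC" = c("TAGLN", "RGS5", "MYH11", "ACTA2", "MYL9"))
    macrophage <- list(
        "M0 macrophage" = c("ACP5", "BHLHE41", "C5AR1", "CCDC102B", "CCL22",
            "CCL7", "COL8A2", "CSF1", "CXCL3", "CXCL5", "CYP27A1", "DCSTAMP",
            "GPC4", "HK3", "IGSF6", "MARCO", "MMP9", "NCF2", "PLA2G7",
            "PPBP", "QPCT", "SLAMF8", "SLC12A8", "TNFSF14", "VNN1"),
        "M1 macrophage" = c("ACHE", "APOBEC3A", "APOL3", "APOL6", "ARRB1",
            "CCL19", "CCL5", "CCR7", "CD38", "CD40", "CHI3L1", "CXCL10",
            "CXCL11", "CXCL13", "CXCL9", "CYP27B1", "DHX58", "HESX1", "IDO1",
            "IFI44L", "IL2RA", "KIAA0754", "KYNU", "LAG3", "LAMP3", "LILRA3",
            "LILRB2", "NOD2", "PLA1A", "PTGIR", "RASSF4", "RSAD2", "SLAMF1",
            "SLC2A6", "SOCS1", "TLR7", "TNFAIP6", "TNIP3", "TRPM4"),
        "M2 macrophage" = c("AIF1", "ALOX15", "CCL13", "CCL14", "CCL23",
            "CD209", "CD4", "CFP", "CLEC10A", "CLEC4A", "CRYBB1", "FES",
            "FRMD4A", "FZD2", "GSTT1", "HRH1", "HTR2B", "MS4A6A", "NME8",
            "NPL", "P2RY13", "PDCD1LG2", "RENBP", "WNT5B"),
        "SPP1 macrophage" = c("MERTK", "CD14", "SPP1", "CD68", "LYZ"))
    panels <- switch(source, all = c(major, macrophage), major = major,
                     macrophage = macrophage)
    src <- rep(c("major", "macrophage"),
               c(length(major), length(macrophage)))
    names(src) <- c(names(major), names(macrophage))
    attr(panels, "source") <- src[names(panels)]
    attr(panels, "description") <- stats::setNames(
        paste(src[names(panels)], "cell-type marker panel"), names(panels))
    panels
}

#' Score samples by marker-panel mean expression
#'
#' The per-sample cell-type score is the arithmetic mean of the log2
#' expression values of the panel's marker genes found in the matrix --
#' a lightweight in silico deconvolution proxy for cell-type abundance.
#' Missing panel genes are dropped, never imputed; the fraction found is
#' reported as coverage, and a panel with zero overlap is skipped with a
#' message.
#'
#' @param x Log2 expression matrix or `SummarizedExperiment`.
#' @param panels Named list of marker-gene vectors (e.g.
#'   [builtinMarkerPanels()]).
#' @return A [CellTypeScores-class] object (panels x samples).
#' @export
#' @rdname scoreSamples
setMethod("scoreSamples", signature(x = "matrix"), function(x, panels) {
    if (nrow(x) == 0L || ncol(x) == 0L) stop("empty expression matrix")
    if (is.null(names(panels))) stop("panels must be named")
    present <- lapply(panels, intersect, x = rownames(x))
    skip <- lengths(present) == 0L
    if (any(skip))
        message("panel(s) with no genes in the matrix skipped: ",
                paste(names(panels)[skip], collapse = ", "))
    if (all(skip)) stop("no panel overlaps the expression matrix")
    present <- present[!skip]
    scores <- t(vapply(present, function(g)
        colMeans(x[g, , drop = FALSE]), numeric(ncol(x))))
    coverage <- lengths(present) / lengths(panels[!skip])
    methods::new("CellTypeScores", scores = scores,
                 coverage = stats::setNames(coverage, rownames(scores)))
})

#' @rdname scoreSamples
#' @export
setMethod("scoreSamples", signature(x = "SummarizedExperiment"),
    function(x, panels)
        scoreSamples(SummarizedExperiment::assay(x, "log2"), panels))

#' Wilcoxon rank-sum test (exact or normal approximation)
#'
#' Rank-sum statistic on pooled mid-ranks. The two-sided p-value is exact --
#' by full enumeration of all `choose(nx+ny, nx)` rank assignments -- when
#' `nx + ny <= 12` and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used. If all pooled values are
#' identical, p = 1 with a warning.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List: `statistic` (rank sum of `x`), `p` (two-sided), `exact`
#'   (logical).
#' @export
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))  # exact p = 1/3
wilcoxonRankSum <- function(x, y) {
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    nx <- length(x); ny <- length(y); n <- nx + ny
    pooled <- c(x, y)
    r <- rank(pooled)
    W <- sum(r[seq_len(nx)])
    mu <- nx * (n + 1) / 2
    ties <- anyDuplicated(pooled) > 0L
    if (length(unique(pooled)) == 1L) {
        warning("all values identical across both groups; p = 1")
        return(list(statistic = W, p = 1, exact = FALSE))
    }
    if (n <= 12L && !ties) {
        sums <- utils::combn(n, nx, sum)
        p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
        return(list(statistic = W, p = p, exact = TRUE))
    }
    tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
        warning("degenerate rank variance; p = 1")
        return(list(statistic = W, p = 1, exact = FALSE))
    }
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
    list(statistic = W, p = p, exact = FALSE)
}

#' Compare cell-type scores between condition groups
#'
#' One Wilcoxon rank-sum comparison per (panel, condition pair), with
#' significance stars. No multiplicity adjustment is applied across panels
#' or pairs (stars annotate each comparison on its own).
#'
#' The default star thresholds follow the boxplot-annotation convention
#' `* p < 0.05`, `** p < 0.01`, `*** p < 0.0001`; `scheme = "conventional"`
#' uses `*** p < 0.001` instead.
#'
#' @param scores A [CellTypeScores-class] from [scoreSamples()].
#' @param samples Sample table (`data.frame`) or `SummarizedExperiment`
#'   carrying the colData of the scored samples.
#' @param pairs List of length-2 character vectors of condition labels;
#'   default: all pairwise combinations present.
#' @param scheme Star threshold scheme, `"caption"` (default) or
#'   `"conventional"`.
#' @return `data.frame`: `panel`, `groupA`, `groupB`, `nA`, `nB`,
#'   `statistic`, `p`, `stars`.
#' @export
compareGroups <- function(scores, samples, pairs = NULL,
                          scheme = c("caption", "conventional")) {
    scheme <- match.arg(scheme)
    stopifnot(methods::is(scores, "CellTypeScores"))
    if (methods::is(samples, "SummarizedExperiment"))
        samples <- study_parts(samples)$samples
    samples <- validate_sample_table(samples)
    sm <- scoreMatrix(scores)
    missing <- setdiff(colnames(sm), samples$sample_id)
    if (length(missing))
        stop("scored sample(s) not annotated: ", paste(missing, collapse = ", "))
    cond <- samples$condition[match(colnames(sm), samples$sample_id)]
    present <- intersect(acneConditions(), unique(cond))
    if (is.null(pairs)) {
        pairs <- utils::combn(present, 2L, simplify = FALSE)
    } else {
        bad <- setdiff(unique(unlist(pairs)), acneConditions())
        if (length(bad))
            stop("unknown condition label(s): ", paste(bad, collapse = ", "))
    }
    star_cut <- if (scheme == "caption") c(1e-4, 0.01, 0.05)
                else c(1e-3, 0.01, 0.05)
    star_of <- function(p)
        if (p < star_cut[1]) "***" else if (p < star_cut[2]) "**"
        else if (p < star_cut[3]) "*" else "ns"
    rows <- list()
    for (panel in rownames(sm)) {
        for (pr in pairs) {
            a <- sm[panel, cond == pr[1]]
            b <- sm[panel, cond == pr[2]]
            if (!length(a) || !length(b))
                stop("empty group for pair ", pr[1], " vs ", pr[2])
            w <- wilcoxonRankSum(a, b)
            rows[[length(rows) + 1L]] <- data.frame(
                panel = panel, groupA = pr[1], groupB = pr[2],
                nA = length(a), nB = length(b),
                statistic = w$statistic, p = w$p, stars = star_of(w$p),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
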