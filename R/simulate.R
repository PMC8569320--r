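#' @include study.R
NULL

# evaluate code under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Configuration of a synthetic paired acne biopsy study
#'
#' Describes a paired multi-condition expression study to be generated by
#' [simulateStudy()]: each of `nSubjects` subjects contributes one sample per
#' biopsy condition (`L_NI`, `L1`, `L3`, `R3`). Genes are planted as
#' differentially expressed in the contrasts implied by their Venn region
#' (papule: L1 vs L_NI; vehicle: L3 vs L1; trifarotene: R3 vs L1) with
#' controlled overlap structure, and marker panels can be shifted per
#' condition to emulate cell-type composition changes.
#'
#' Per-gene noise variances are drawn from a scaled-inverse-chi-square prior
#' with `varPriorDf` degrees of freedom and scale `noiseSd^2`, so the
#' empirical-Bayes moderated t of [fitModeratedT()] has a recoverable target;
#' set `varPriorDf = Inf` for homoscedastic noise.
#'
#' @param nSubjects Number of subjects (default 9, the paired study design).
#' @param nGenes Number of genes.
#' @param baselineRange Range (log2 scale) of per-gene baseline means.
#' @param subjectSd SD of the per-subject random effect (log2 scale).
#' @param noiseSd Residual noise scale (log2); the prior scale s0 of the
#'   per-gene variances.
#' @param vennRegionSizes Named integer vector over [vennRegionNames()]:
#'   number of genes planted in each region.
#' @param effectLog2fc Absolute planted log2 fold change per affected
#'   contrast.
#' @param directionUpFraction Fraction of planted genes whose lesion
#'   direction is up (up in papule; treatment contrasts are mirrored, i.e.
#'   down after vehicle/trifarotene resolution, matching the reversal
#'   pattern).
#' @param varPriorDf Prior degrees of freedom of the per-gene variance
#'   distribution (`Inf` = constant variance `noiseSd^2`).
#' @param celltypePanels Optional named list of marker-gene panels (e.g.
#'   [builtinMarkerPanels()]); panel genes become row names of the simulated
#'   matrix and are excluded from the Venn regions.
#' @param celltypeShift Optional named list: panel name -> named numeric of
#'   additive log2 shifts per condition, applied to all genes of that panel.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A list of class `"study_design_config"`.
#' @export
studyDesignConfig <- function(nSubjects = 9L,
                              nGenes = 2000L,
                              baselineRange = c(4, 12),
                              subjectSd = 0.3,
                              noiseSd = 0.4,
                              vennRegionSizes = c(
                                  papule_only = 20L, vehicle_only = 10L,
                                  trifarotene_only = 10L, papule_vehicle = 10L,
                                  papule_trifarotene = 10L,
                                  vehicle_trifarotene = 5L, all_three = 40L),
                              effectLog2fc = 2,
                              directionUpFraction = 0.8,
                              varPriorDf = 4,
                              celltypePanels = NULL,
                              celltypeShift = NULL,
                              seed = 1L) {
    stopifnot(nSubjects >= 1, nGenes >= 1,
              length(baselineRange) == 2L, baselineRange[1] <= baselineRange[2],
              subjectSd >= 0, noiseSd >= 0, effectLog2fc > 0,
              directionUpFraction >= 0, directionUpFraction <= 1,
              varPriorDf > 0)
    sz <- rep(0L, 7L)
    names(sz) <- vennRegionNames()
    if (length(vennRegionSizes)) {
        bad <- setdiff(names(vennRegionSizes), vennRegionNames())
        if (length(bad))
            stop("unknown Venn region name(s): ", paste(bad, collapse = ", "))
        sz[names(vennRegionSizes)] <- as.integer(vennRegionSizes)
    }
    if (any(sz < 0)) stop("Venn region sizes must be nonnegative")
    n_marker <- if (is.null(celltypePanels)) 0L else
        length(unique(unlist(celltypePanels, use.names = FALSE)))
    if (sum(sz) + n_marker > nGenes)
        stop("sum of Venn region sizes (", sum(sz), ") plus marker genes (",
             n_marker, ") exceeds nGenes (", nGenes, ")")
    if (!is.null(celltypeShift)) {
        if (is.null(celltypePanels))
            stop("celltypeShift requires celltypePanels")
        bad <- setdiff(names(celltypeShift), names(celltypePanels))
        if (length(bad))
            stop("celltypeShift names not among panels: ",
                 paste(bad, collapse = ", "))
        for (s in celltypeShift) {
            bad <- setdiff(names(s), acneConditions())
            if (length(bad))
                stop("celltypeShift condition(s) unknown: ",
                     paste(bad, collapse = ", "))
        }
    }
    structure(list(
        nSubjects = as.integer(nSubjects), nGenes = as.integer(nGenes),
        baselineRange = as.numeric(baselineRange),
        subjectSd = subjectSd, noiseSd = noiseSd, vennRegionSizes = sz,
        effectLog2fc = effectLog2fc,
        directionUpFraction = directionUpFraction, varPriorDf = varPriorDf,
        celltypePanels = celltypePanels, celltypeShift = celltypeShift,
        seed = as.integer(seed)),
        class = "study_design_config")
}

#' Simulate a paired acne biopsy expression study with known ground truth
#'
#' Generates log2 expression values under the additive model
#' `y = mu_g + b_s + delta_{g,c} + m_{g,c} + eps` with subject random effects
#' `b_s ~ N(0, subjectSd^2)` and gene-specific Gaussian noise. The planted
#' condition effects `delta` are built so that a gene is differentially
#' expressed with `|log2FC| = effectLog2fc` exactly in the contrasts implied
#' by its Venn region and has a zero effect elsewhere; `m` adds the
#' configured cell-type shifts to marker-panel genes.
#'
#' @param config A [studyDesignConfig()].
#' @return A list with elements:
#'   \describe{
#'     \item{study}{`SummarizedExperiment` (assay `"log2"`, colData
#'       `subject`/`condition`) as from [acneStudy()].}
#'     \item{truth}{`data.frame` with per-gene `region` (one of
#'       [vennRegionNames()] or `"none"`) and planted direction per contrast
#'       (`dir_papule`, `dir_vehicle`, `dir_trifarotene` in -1/0/+1); the
#'       cell-type shift map is attached as attribute `"celltype_shift"`.}
#'   }
#' @export
#' @examples
#' sim <- simulateStudy(studyDesignConfig(nGenes = 100, seed = 42))
#' table(sim$truth$region)
simulateStudy <- function(config) {
    stopifnot(inherits(config, "study_design_config"))
    with_local_seed(config$seed, {
        n_g <- config$nGenes
        n_s <- config$nSubjects
        conds <- acneConditions()
        markers <- if (is.null(config$celltypePanels)) character(0) else
            sort(unique(unlist(config$celltypePanels, use.names = FALSE)))
        n_syn <- n_g - length(markers)
        genes <- c(markers, sprintf("g%05d", seq_len(n_syn)))
        subjects <- sprintf("P%02d", seq_len(n_s))
        samp <- expand.grid(subject_id = subjects, condition = conds,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        samp <- samp[order(samp$subject_id, match(samp$condition, conds)), ]
        samp$sample_id <- paste(samp$subject_id, samp$condition, sep = "_")
        rownames(samp) <- NULL

        mu <- stats::runif(n_g, config$baselineRange[1], config$baselineRange[2])
        dir <- ifelse(stats::runif(n_g) < config$directionUpFraction, 1L, -1L)
        region <- rep("none", n_g)
        sz <- config$vennRegionSizes
        eligible <- which(!(genes %in% markers))
        planted <- sample(eligible, sum(sz))
        region[planted] <- rep(names(sz), times = sz)

        in_papule <- region %in% c("papule_only", "papule_vehicle",
                                   "papule_trifarotene", "all_three")
        in_vehicle <- region %in% c("vehicle_only", "papule_vehicle",
                                    "vehicle_trifarotene", "all_three")
        in_trif <- region %in% c("trifarotene_only", "papule_trifarotene",
                                 "vehicle_trifarotene", "all_three")
        E <- config$effectLog2fc
        e_p <- ifelse(in_papule, dir * E, 0)
        e_v <- ifelse(in_vehicle, -dir * E, 0)   # mirrored: resolution reverses
        e_t <- ifelse(in_trif, -dir * E, 0)
        delta <- cbind(L_NI = 0, L1 = e_p, L3 = e_p + e_v, R3 = e_p + e_t)

        sigma2 <- if (config$noiseSd == 0) rep(0, n_g)
            else if (is.infinite(config$varPriorDf)) rep(config$noiseSd^2, n_g)
            else config$noiseSd^2 * config$varPriorDf /
                 stats::rchisq(n_g, config$varPriorDf)
        b <- stats::rnorm(n_s, 0, config$subjectSd)
        names(b) <- subjects

        shift <- matrix(0, n_g, length(conds),
                        dimnames = list(genes, conds))
        if (!is.null(config$celltypeShift)) {
            for (panel in names(config$celltypeShift)) {
                pg <- intersect(config$celltypePanels[[panel]], genes)
                s <- config$celltypeShift[[panel]]
                for (cond in names(s))
                    shift[pg, cond] <- shift[pg, cond] + s[[cond]]
            }
        }

        m <- matrix(0, n_g, nrow(samp), dimnames = list(genes, samp$sample_id))
        for (j in seq_len(nrow(samp))) {
            cond <- samp$condition[j]
            m[, j] <- mu + b[[samp$subject_id[j]]] + delta[, cond] +
                shift[, cond] + stats::rnorm(n_g, 0, sqrt(sigma2))
        }

        truth <- data.frame(
            gene = genes, region = region,
            dir_papule = as.integer(sign(e_p)),
            dir_vehicle = as.integer(sign(e_v)),
            dir_trifarotene = as.integer(sign(e_t)),
            stringsAsFactors = FALSE)
        attr(truth, "celltype_shift") <- config$celltypeShift

        list(study = acneStudy(m, samp[c("sample_id", "subject_id", "condition")]),
             truth = truth)
    })
}

#' Simulate a pure-null paired study
#'
#' [simulateStudy()] with no planted regions and no cell-type shifts; the
#' harness for type-I-error and FDR calibration of the differential
#' expression stage.
#'
#' @param nSubjects,nGenes,seed As in [studyDesignConfig()].
#' @param noiseSd,subjectSd,varPriorDf Noise settings, defaulting to the
#'   standard study conditions.
#' @return A `SummarizedExperiment`, as the `study` element of
#'   [simulateStudy()].
#' @export
simulateNullStudy <- function(nSubjects = 9L, nGenes = 2000L, seed = 1L,
                              noiseSd = 0.4, subjectSd = 0.3, varPriorDf = 4) {
    cfg <- studyDesignConfig(
        nSubjects = nSubjects, nGenes = nGenes,
        vennRegionSizes = integer(0), noiseSd = noiseSd,
        subjectSd = subjectSd, varPriorDf = varPriorDf, seed = seed)
    simulateStudy(cfg)$study
}

#' Read a study-design configuration from YAML
#'
#' Keys mirror the arguments of [studyDesignConfig()] in snake_case
#' (`n_subjects`, `n_genes`, `baseline_mean_range`, `subject_sd`, `noise_sd`,
#' `venn_region_sizes`, `effect_log2fc`, `direction_up_fraction`,
#' `var_prior_df`, `celltype_shift`, `seed`); unknown keys are an error.
#' `celltype_panels: builtin` selects [builtinMarkerPanels()].
#'
#' @param x Path to a YAML file, or an already-parsed list.
#' @return A validated [studyDesignConfig()].
#' @export
readStudyDesignConfig <- function(x) {
    cfg <- if (is.character(x)) yaml::read_yaml(x) else x
    key_map <- c(n_subjects = "nSubjects", n_genes = "nGenes",
                 baseline_mean_range = "baselineRange",
                 subject_sd = "subjectSd", noise_sd = "noiseSd",
                 venn_region_sizes = "vennRegionSizes",
                 effect_log2fc = "effectLog2fc",
                 direction_up_fraction = "directionUpFraction",
                 var_prior_df = "varPriorDf",
                 celltype_panels = "celltypePanels",
                 celltype_shift = "celltypeShift", seed = "seed")
    bad <- setdiff(names(cfg), names(key_map))
    if (length(bad))
        stop("unknown study-design key(s): ", paste(bad, collapse = ", "))
    args <- stats::setNames(cfg, key_map[names(cfg)])
    if (!is.null(args$vennRegionSizes))
        args$vennRegionSizes <- unlist(args$vennRegionSizes)
    if (identical(args$celltypePanels, "builtin"))
        args$celltypePanels <- builtinMarkerPanels()
    if (!is.null(args$celltypeShift))
        args$celltypeShift <- lapply(args$celltypeShift, unlist)
    do.call(studyDesignConfig, args)
}

#' Write ground truth as TSV
#'
#' @param truth The `truth` element of [simulateStudy()].
#' @param path Output file.
#' @export
writeGroundTruth <- function(truth, path) {
    lines <- c(paste(names(truth), collapse = "\t"),
               do.call(paste, c(truth, sep = "\t")))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
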