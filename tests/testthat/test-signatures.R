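test_that("Venn partition performs exact three-set algebra", {
    p <- vennPartition(c("g1", "g2", "g3"), c("g2", "g3"), c("g3", "g4"))
    expect_identical(regionGenes(p, "papule_only"), "g1")
    expect_identical(regionGenes(p, "papule_vehicle"), "g2")
    expect_identical(regionGenes(p, "all_three"), "g3")
    expect_identical(regionGenes(p, "trifarotene_only"), "g4")
    expect_identical(regionGenes(p, "vehicle_only"), character(0))
    expect_identical(regionGenes(p, "vehicle_trifarotene"), character(0))

    g <- paste0("g", 1:7)
    p <- vennPartition(g, g, g)
    expect_identical(sort(regionGenes(p, "all_three")), sort(g))
    expect_equal(sum(regionSizes(p)), 7)
})

test_that("Venn partition equals the membership-bitmask oracle", {
    set.seed(7)
    for (i in 1:25) {
        pool <- sprintf("g%02d", 1:30)
        A <- sample(pool, sample(0:20, 1))
        B <- sample(pool, sample(0:20, 1))
        C <- sample(pool, sample(0:20, 1))
        p <- vennPartition(A, B, C)
        oracle <- oracle_venn(A, B, C)
        names(oracle) <- vennRegionNames()
        for (r in vennRegionNames())
            expect_identical(regionGenes(p, r), unname(oracle[[r]]))
        # conservation: region sizes sum to the union
        expect_equal(sum(regionSizes(p)), length(unique(c(A, B, C))))
    }
})

test_that("reversal classification follows the sign rule exactly", {
    mk <- function(genes, lfc) {
        tb <- data.frame(gene = genes, log2fc = lfc,
                         fc = signedFoldChange(lfc), s2 = 1, df = 8,
                         t = lfc, dfTotal = 12, p = 0.001, q = 0.01)
        methods::new("ContrastResult", contrast = "x", conditionA = "a",
                     conditionB = "b", subjects = "s", table = tb,
                     d0 = 4, s0sq = 1)
    }
    pr <- mk(c("g1", "g2", "g3"), c(3, 3, -2))
    tr <- mk(c("g1", "g2", "g3"), c(-3, 1, 2))
    cls <- classifyReversal(c("g1", "g2", "g3"), pr, tr)
    expect_identical(cls$pattern,
                     c("up_in_papule_down_after_treatment", "other",
                       "down_in_papule_up_after_treatment"))
    expect_error(classifyReversal("missing", pr, tr), "missing")
})

test_that("zero-noise planted genes land in exactly their contrast sets", {
    cfg <- studyDesignConfig(
        nGenes = 60, noiseSd = 0.001, subjectSd = 0, effectLog2fc = 3,
        vennRegionSizes = c(papule_only = 1, trifarotene_only = 3), seed = 5)
    sim <- simulateStudy(cfg)
    sig <- deriveSignatures(sim$study)
    tr <- sim$truth
    expect_setequal(sig$candidates$papule,
                    tr$gene[tr$region == "papule_only"])
    expect_setequal(sig$candidates$trifarotene,
                    tr$gene[tr$region == "trifarotene_only"])
    expect_length(sig$candidates$vehicle, 0)

    # reversal-planted genes (papule up, reversed under treatment) classify
    # as reversal; trifarotene-only genes have no papule effect, so their
    # truth pattern is 'other' apart from sign noise
    cfg2 <- studyDesignConfig(
        nGenes = 60, noiseSd = 0.001, subjectSd = 0, effectLog2fc = 3,
        directionUpFraction = 1, vennRegionSizes = c(papule_trifarotene = 8),
        seed = 6)
    sim2 <- simulateStudy(cfg2)
    sig2 <- deriveSignatures(sim2$study)
    genes <- sim2$truth$gene[sim2$truth$region == "papule_trifarotene"]
    cls <- classifyReversal(genes, sig2$results$papule,
                            sig2$results$trifarotene)
    expect_true(all(cls$pattern == "up_in_papule_down_after_treatment"))
})

test_that("planted Venn structure is recovered with high Jaccard", {
    jaccard <- function(a, b)
        if (!length(a) && !length(b)) 1 else
            length(intersect(a, b)) / length(union(a, b))
    per_seed <- vapply(1:5, function(s) {
        cfg <- studyDesignConfig(
            nGenes = 800, effectLog2fc = 3, noiseSd = 0.3,
            vennRegionSizes = c(papule_only = 10, vehicle_only = 10,
                trifarotene_only = 10, papule_vehicle = 5,
                papule_trifarotene = 5, vehicle_trifarotene = 5,
                all_three = 5), seed = s)
        sim <- simulateStudy(cfg)
        sig <- deriveSignatures(sim$study)
        min(vapply(vennRegionNames(), function(r) jaccard(
            regionGenes(sig$partition, r),
            sim$truth$gene[sim$truth$region == r]), numeric(1)))
    }, numeric(1))
    expect_gte(median(per_seed), 0.8)
})

test_that("gene clustering merges identical profiles first, negations last", {
    samp <- full_design(3)
    base <- sin(seq_len(nrow(samp)))
    m <- rbind(gA = base, gB = base * 2 + 1,       # perfectly correlated
               gC = -base,                          # anticorrelated
               gD = cos(3 * seq_len(nrow(samp))))   # unrelated
    colnames(m) <- samp$sample_id
    cl <- clusterGenes(m, samp, c("gA", "gB", "gC"),
                       conditions = acneConditions())
    hc <- cl$hclust
    first <- sort(hc$labels[-hc$merge[1, ]])
    expect_identical(first, c("gA", "gB"))          # distance 0 merged first
    expect_equal(hc$height[1], 0, tolerance = 1e-12)
    expect_equal(max(hc$height), 2, tolerance = 1e-12)  # 1 - (-1)
})

test_that("UPGMA with correlation distance matches the brute-force oracle", {
    for (seed in 1:6) {
        rs <- rand_study_matrix(8, 4, seed + 100)
        genes <- rownames(rs$m)
        cl <- clusterGenes(rs$m, rs$samples, genes,
                           conditions = acneConditions())
        z <- t(scale(t(rs$m)))
        d <- as.dist(1 - cor(t(z)))
        oracle <- oracle_upgma(d, genes)
        mine <- hclust_merges(cl$hclust, cl$hclust$labels)
        expect_equal(length(mine), length(oracle))
        for (i in seq_along(oracle)) {
            expect_identical(mine[[i]]$members, oracle[[i]]$members)
            expect_equal(mine[[i]]$height, oracle[[i]]$height,
                         tolerance = 1e-9)
        }
    }
})

test_that("clustering is invariant to gene input order", {
    rs <- rand_study_matrix(10, 4, seed = 55)
    genes <- rownames(rs$m)
    a <- clusterGenes(rs$m, rs$samples, genes)
    for (i in 1:3) {
        set.seed(i)
        b <- clusterGenes(rs$m, rs$samples, sample(genes))
        expect_identical(b$order, a$order)
        expect_equal(b$hclust$height, a$hclust$height)
    }
})

test_that("zero-variance gene rows cluster at unit distance", {
    samp <- full_design(2)
    m <- rbind(flat = rep(5, nrow(samp)),
               gA = seq_len(nrow(samp)),
               gB = seq_len(nrow(samp)) * 2)
    colnames(m) <- samp$sample_id
    expect_message(cl <- clusterGenes(m, samp, rownames(m),
                                      conditions = acneConditions()),
                   "zero-variance")
    expect_identical(cl$zeroVariance, "flat")
    # the flat gene joins last, at distance 1 from the gA/gB cluster
    expect_equal(max(cl$hclust$height), 1, tolerance = 1e-12)
})
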