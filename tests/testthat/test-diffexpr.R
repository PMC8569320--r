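test_that("paired differences are per-subject a-minus-b and antisymmetric", {
    samp <- full_design(3)
    m <- rand_exprs(5, nrow(samp), seed = 1)
    colnames(m) <- samp$sample_id
    m["f001", "P01_L1"] <- 7; m["f001", "P01_L_NI"] <- 5
    d <- pairedDifferences(m, samp, "L1", "L_NI")
    expect_equal(d["f001", "P01"], 2)
    expect_equal(ncol(d), 3)

    # reversing the contrast negates every difference
    d2 <- pairedDifferences(m, samp, "L_NI", "L1")
    expect_equal(d2, -d[, colnames(d2)])

    # subject lacking one condition is dropped with a message
    samp2 <- samp[!(samp$subject_id == "P02" & samp$condition == "L_NI"), ]
    m2 <- m[, samp2$sample_id]
    expect_message(d3 <- pairedDifferences(m2, samp2, "L1", "L_NI"), "P02")
    expect_identical(colnames(d3), c("P01", "P03"))

    samp3 <- samp[samp$subject_id %in% "P01" | samp$condition != "L_NI", ]
    expect_error(pairedDifferences(m[, samp3$sample_id], samp3, "L1", "L_NI"),
                 "fewer than 2 subjects")
})

test_that("moderated t reduces to the classic t without shrinkage", {
    set.seed(21)
    d <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("p%d", 1:6)))
    res <- fitModeratedT(d, d0 = 0, s0sq = 1)
    tb <- resultTable(res)
    classic <- apply(d, 1, function(x) unname(t.test(x)$statistic))
    expect_equal(tb$t, classic, tolerance = 1e-12, ignore_attr = TRUE)
    classic_p <- apply(d, 1, function(x) t.test(x)$p.value)
    expect_equal(tb$p, classic_p, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("homogeneous variances give total shrinkage without changing t", {
    set.seed(22)
    base <- rnorm(8)
    # every gene has the same residual variance pattern, different means
    d <- t(vapply(1:50, function(i) base - mean(base) + i / 10, numeric(8)))
    rownames(d) <- sprintf("g%02d", 1:50)
    res <- fitModeratedT(d)
    expect_identical(priorDf(res), Inf)
    s2 <- resultTable(res)$s2
    expect_equal(priorVar(res), s2[1], tolerance = 1e-9)
    classic <- apply(d, 1, function(x) unname(t.test(x)$statistic))
    expect_equal(resultTable(res)$t, classic, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("variance prior recovery matches the generating hyperparameters", {
    # variances drawn from the scaled-inverse-chi-square model the
    # estimator assumes: s2 = sigma2 * chisq_df / df, sigma2 ~ s0^2*d0/chisq_d0
    recover <- function(seed, n, d0_true, s0sq_true, df) {
        set.seed(seed)
        sigma2 <- s0sq_true * d0_true / rchisq(n, d0_true)
        s2 <- sigma2 * rchisq(n, df) / df
        estimatePrior(s2, df)
    }
    fits <- lapply(1:20, recover, n = 5000, d0_true = 4, s0sq_true = 0.25,
                   df = 8)
    d0s <- vapply(fits, `[[`, numeric(1), "d0")
    s0s <- vapply(fits, `[[`, numeric(1), "s0sq")
    expect_lt(abs(median(d0s) - 4) / 4, 0.30)
    expect_lt(abs(median(s0s) - 0.25) / 0.25, 0.10)
})

test_that("prior estimation agrees with the limma reference fit", {
    set.seed(31)
    df <- 8
    sigma2 <- 0.25 * 10 / rchisq(3000, 10)
    s2 <- sigma2 * rchisq(3000, df) / df
    mine <- estimatePrior(s2, df)
    ref <- limma::fitFDist(s2, df1 = df)
    expect_equal(mine$d0, ref$df2, tolerance = 1e-3)
    expect_equal(mine$s0sq, ref$scale, tolerance = 1e-3)
})

test_that("equal variances give d0 = Inf; mixtures give partial shrinkage", {
    expect_identical(estimatePrior(rep(0.5, 100), 8)$d0, Inf)
    expect_equal(estimatePrior(rep(0.5, 100), 8)$s0sq, 0.5, tolerance = 1e-12)

    set.seed(41)
    s2 <- c(0.1 * rchisq(500, 8) / 8, 2 * rchisq(500, 8) / 8)
    fit <- estimatePrior(s2, 8)
    expect_true(is.finite(fit$d0))
    # posterior variance lies strictly between s2 and s0sq genewise
    post <- (fit$d0 * fit$s0sq + 8 * s2) / (fit$d0 + 8)
    away <- abs(s2 - fit$s0sq) > 1e-9
    expect_true(all((post[away] > pmin(s2, fit$s0sq)[away]) &
                    (post[away] < pmax(s2, fit$s0sq)[away])))
})

test_that("moderated and limma pipelines agree end to end", {
    st <- simulateNullStudy(nGenes = 800, seed = 13)
    d <- pairedDifferences(st, conditionA = "L1", conditionB = "L_NI")
    mine <- resultTable(fitModeratedT(d))
    fit <- limma::eBayes(limma::lmFit(d, matrix(1, ncol(d), 1)))
    expect_equal(mine$t, fit$t[, 1], tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(mine$p, fit$p.value[, 1], tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("BH adjustment equals the hand-run step-up and p.adjust", {
    expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.05)),
                 c(0.04, 0.05, 0.05, 0.05))
    expect_equal(bhAdjust(1), 1)
    expect_error(bhAdjust(c(0.5, 1.2)), "within")
    expect_error(bhAdjust(c(0.5, NA)), "finite")

    set.seed(51)
    for (i in 1:100) {
        p <- runif(sample(1:40, 1))
        q <- bhAdjust(p)
        expect_equal(q, p.adjust(p, "BH"))
        # sorted q is monotone nondecreasing in sorted p
        expect_true(!is.unsorted(q[order(p)]))
    }
})

test_that("candidate selection is strict on both thresholds", {
    tb <- data.frame(
        gene = c("boundary", "spp1_like", "weak_q", "up"),
        log2fc = c(1, -log2(28.2), 3, 2),
        fc = c(2, -28.2, 8, 4),
        s2 = 1, df = 8, t = c(5, -9, 5, 6), dfTotal = 12,
        p = c(1e-4, 1e-5, 1e-3, 1e-6),
        q = c(0.01, 0.0022, 0.06, 0.001))
    res <- methods::new("ContrastResult", contrast = "x", conditionA = "a",
                        conditionB = "b", subjects = letters[1:9],
                        table = tb, d0 = 4, s0sq = 1)
    sel <- selectCandidates(res)
    expect_identical(sel$gene, c("spp1_like", "up"))
    expect_identical(sel$direction, c(-1L, 1L))

    # brute-force filter loop on random results
    set.seed(61)
    for (i in 1:20) {
        n <- 50
        tb <- data.frame(gene = sprintf("g%02d", 1:n),
                         log2fc = rnorm(n, 0, 2), s2 = 1, df = 8,
                         t = rnorm(n), dfTotal = 12,
                         p = runif(n), q = runif(n))
        tb$fc <- signedFoldChange(tb$log2fc)
        tb$q <- pmax(tb$q, tb$p)
        res <- methods::new("ContrastResult", contrast = "x",
                            conditionA = "a", conditionB = "b",
                            subjects = "s", table = tb, d0 = 4, s0sq = 1)
        want <- character(0)
        for (j in 1:n)
            if (abs(tb$fc[j]) > 2 && tb$q[j] < 0.05)
                want <- c(want, tb$gene[j])
        expect_identical(selectCandidates(res)$gene, want)
    }
})

test_that("swapping the contrast negates effects but keeps p and q", {
    rs <- rand_study_matrix(40, 9, seed = 71)
    a <- resultTable(runContrast(rs$m, rs$samples, "L1", "L_NI"))
    b <- resultTable(runContrast(rs$m, rs$samples, "L_NI", "L1"))
    expect_equal(a$log2fc, -b$log2fc)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
    expect_equal(a$q, b$q)
})

test_that("moderated t shrinks outlier statistics on heteroscedastic data", {
    set.seed(81)
    n <- 400
    sigma2 <- 0.05 * 10 / rchisq(n, 3)
    d <- t(vapply(sigma2, function(s) rnorm(6, 0, sqrt(s)), numeric(6)))
    rownames(d) <- sprintf("g%03d", 1:n)
    res <- resultTable(fitModeratedT(d))
    classic_t <- rowMeans(d) / sqrt(res$s2 / 6)
    expect_lt(var(res$t), var(classic_t))
})
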