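test_that("minor allele frequency counts copies over gene copies", {
    ## three single-copy carriers among 192 lines: 3/768
    d <- c(rep(1, 3), rep(0, 189))
    f <- minorAlleleFrequency(d, biallelic = FALSE)
    expect_equal(f, 3 / 768)
    expect_equal(round(f, 3), 0.004)
    expect_equal(minorAlleleFrequency(rep(2, 10)), 0.5)
    ## a column and its complement are two sides of one frequency
    set.seed(51)
    d <- sample(0:4, 50, TRUE)
    expect_equal(minorAlleleFrequency(d, biallelic = FALSE) +
                 minorAlleleFrequency(4 - d, biallelic = FALSE), 1)
    ## missing dosages reduce the denominator
    expect_equal(minorAlleleFrequency(c(2, NA, 2), biallelic = FALSE),
                 0.5)
    expect_error(minorAlleleFrequency(c(NA, NA)), "missing")
})

test_that("genotype factor encoding spans the observed dosage classes", {
    enc <- encodeGenotypeFactor(c(0, 1, 2, 3, 4, 2, 2))
    expect_equal(ncol(enc$factorX), 4L)      # 5 classes -> 4 df
    expect_equal(enc$reference, 2)
    expect_null(encodeGenotypeFactor(rep(3, 10)))
})

test_that("with identity kinship the Q+K model is exactly ANCOVA", {
    set.seed(52)
    n <- 60
    y <- setNames(rnorm(n), paste0("L", 1:n))
    d <- setNames(sample(0:4, n, TRUE), names(y))
    null <- qkNull(y)
    fit <- fitQKModel(null, d)
    a <- anova(lm(y ~ factor(d)))
    expect_lt(abs(fit$p - a$`Pr(>F)`[1]), 1e-8)
    expect_lt(abs(fit$effect - coef(lm(y ~ as.numeric(d)))[2]), 1e-8)
    ## two observed classes: factor test and additive test coincide
    d2 <- setNames(rbinom(n, 1, 0.4), names(y))
    f2 <- fitQKModel(null, d2)
    a2 <- anova(lm(y ~ d2))
    expect_lt(abs(f2$p - a2$`Pr(>F)`[1]), 1e-10)
    expect_equal(f2$df1, 1L)
})

test_that("rotated-space p-values equal a dense GLS evaluation", {
    ## same variance components, two computational routes
    set.seed(53)
    cfg <- separatedConfig(seed = 53, nLines = 40L, nSsrs = 10L)
    p <- simulateAdmixedPopulation(cfg)
    dp <- asDosagePanel(p)
    kin <- loiselleKinship(dp)
    y <- setNames(rnorm(40), p@lineIds)
    null <- qkNull(y, kin = kin)
    dm <- dosageMatrix(dp, role = "candidate")
    set.seed(54)
    cols <- sample(ncol(dm), min(20, ncol(dm)))
    for (j in cols) {
        d <- dm[names(y), j]
        fit <- fitQKModel(null, d)
        if (is.null(fit)) next
        ## dense route: V = (K + delta I), whitened ANCOVA
        V <- kin@.Data[names(y), names(y)] + null$delta * diag(40)
        cV <- chol(V)
        enc <- encodeGenotypeFactor(d)
        X1 <- cbind(1, enc$factorX)
        yw <- forwardsolve(t(cV), y)
        X1w <- forwardsolve(t(cV), X1)
        X0w <- forwardsolve(t(cV), matrix(1, 40))
        r1 <- sum(lm.fit(X1w, yw)$residuals^2)
        r0 <- sum(lm.fit(X0w, yw)$residuals^2)
        q <- ncol(enc$factorX); df2 <- 40 - ncol(X1)
        Fd <- ((r0 - r1) / q) / (r1 / df2)
        pd <- pf(Fd, q, df2, lower.tail = FALSE)
        expect_lt(abs(fit$p - pd), 1e-10)
    }
})

test_that("power rises with the simulated per-copy effect", {
    set.seed(55)
    n <- 120; nMark <- 60
    rej <- vapply(c(0, 0.5, 1, 2), function(beta) {
        hits <- 0L
        for (m in seq_len(nMark)) {
            d <- setNames(rbinom(n, 4, 0.3), paste0("L", 1:n))
            y <- beta * d + rnorm(n, 0, 2)
            fit <- fitQKModel(qkNull(y), d)
            hits <- hits + (fit$p < 0.05)
        }
        hits / nMark
    }, numeric(1))
    expect_true(all(diff(rej) >= 0))
    expect_lt(rej[1], 0.2)
    expect_gt(rej[4], 0.9)
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is one", {
    p <- c(0.01, 0.02, 0.03, 0.04)
    q <- storeyQvalues(p, pi0 = 1)$qvalues
    expect_equal(q, rep(0.04, 4))
    set.seed(56)
    p <- runif(200)^1.5
    expect_equal(storeyQvalues(p, pi0 = 1)$qvalues,
                 p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("q-values are monotone, bounded by pi0, order-invariant", {
    set.seed(57)
    p <- c(runif(300), runif(100, 0, 0.01))
    res <- storeyQvalues(p, seed = 9)
    expect_gt(res$pi0, 0); expect_lte(res$pi0, 1)
    o <- order(p)
    expect_true(all(diff(res$qvalues[o]) >= -1e-15))
    expect_lte(max(res$qvalues), res$pi0)
    perm <- sample(length(p))
    res2 <- storeyQvalues(p[perm], seed = 9)
    expect_equal(res2$qvalues, res$qvalues[perm], tolerance = 1e-12)
    expect_warning(storeyQvalues(runif(10), seed = 1), "unstable")
})

test_that("thirteen discoveries at q = 0.02 imply 0.26 false ones", {
    expect_equal(expectedFalseDiscoveries(0.02, 13), 0.26)
})

test_that("the scan emits one record per testable allele and dataset", {
    cfg <- smallConfig(seed = 58)
    s <- simulateStudy(cfg, layout = smallLayout())
    dp <- asDosagePanel(s$panel)
    fits <- list(fitSpatialReml(s$trial, "C6", "2011", nStarts = 1),
                 fitSpatialReml(s$trial, "C3", "2011", nStarts = 1))
    means <- adjustedLineMeans(fits)
    kin <- loiselleKinship(dp)
    qf <- estimateAdmixture(dp, 3, seed = 1, nRestarts = 1)
    rec <- associationScan(means, dp, Q = qf, kin = kin)
    skipped <- attr(rec, "skipped")
    nCols <- sum(as.data.frame(SummarizedExperiment::rowData(dp))$role
                 == "candidate")
    expect_equal(nrow(rec) + ifelse(is.null(skipped), 0, nrow(skipped)),
                 nCols * 2)
    expect_false("CONTROL" %in% "" )  # control excluded by design
    expect_true(all(rec$n == 48))
    ## p sorted within trait-year
    for (sp in split(rec, paste(rec$trait, rec$year)))
        expect_true(all(diff(sp$p) >= 0))
    ## consistent permutation of line order changes nothing
    perm <- sample(ncol(dp))
    dp2 <- dp[, perm]
    rec2 <- associationScan(means, new("DosagePanel", dp2),
                            Q = qf, kin = kin)
    ## identical up to the numerical noise of re-eigendecomposition
    expect_equal(rec$p, rec2$p, tolerance = 1e-6)
    expect_equal(rec$effect, rec2$effect, tolerance = 1e-6)
})

test_that("misaligned line ids are reported, not silently dropped", {
    cfg <- smallConfig(seed = 59)
    s <- simulateStudy(cfg, layout = smallLayout())
    dp <- asDosagePanel(s$panel)
    means <- data.frame(line_id = c("GHOST1", "GHOST2"),
                        trait = "C6", year = "2011", mean = c(1, 2))
    expect_error(associationScan(means, dp), "GHOST")
})

test_that("significance summary counts agree with a direct recount", {
    set.seed(60)
    rec <- data.frame(
        marker_id = paste0("m", 1:50), allele = "a", type = "SNP",
        gene = sample(c("g1", "g2", NA), 50, TRUE),
        trait = "C6", year = "2011", n = 100, maf = 0.2,
        p = runif(50)^3, effect = rnorm(50), df1 = 1,
        sigma2_g = 1, sigma2_e = 1, class_means = "")
    rec$q <- storeyQvalues(rec$p, seed = 2)$qvalues
    sm <- significanceSummary(rec)
    for (i in seq_len(nrow(sm$thresholds)))
        expect_equal(sm$thresholds$n[i],
                     sum(rec$p < sm$thresholds$threshold[i]))
    expect_equal(sum(sm$byGene$n_records), nrow(rec))
})
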