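test_that("K = 1 admixture equals the pooled multinomial likelihood", {
    D1 <- makeLocus(rbind(c(2, 2, 0), c(1, 0, 3), c(4, 0, 0)))
    D2 <- makeLocus(rbind(c(0, 4), c(2, 2), c(1, 3)))
    fit <- estimateAdmixture(list(l1 = D1, l2 = D2), K = 1)
    expect_true(all(qMatrix(fit) == 1))
    ## closed-form pooled log-likelihood
    ll <- 0
    for (D in list(D1, D2)) {
        ph <- colSums(D) / sum(D)
        ll <- ll + sum(sweep(D, 2, log(ph), "*"))
    }
    expect_equal(fit@loglik, ll, tolerance = 1e-8)
})

test_that("the EM log-likelihood never decreases", {
    cfg <- separatedConfig(seed = 41)
    p <- simulateAdmixedPopulation(cfg)
    dp <- asDosagePanel(p)
    fit <- estimateAdmixture(dp, K = 3, seed = 2, nRestarts = 1)
    expect_true(all(diff(fit@trace) >= -1e-8))
})

test_that("a richer model never fits worse (nesting in K)", {
    cfg <- separatedConfig(seed = 42, nLines = 40L, nSsrs = 8L)
    dp <- asDosagePanel(simulateAdmixedPopulation(cfg))
    f1 <- estimateAdmixture(dp, K = 1)
    f2 <- estimateAdmixture(dp, K = 2, seed = 3, nRestarts = 2)
    expect_gte(f2@loglik, f1@loglik - 1e-6)
})

test_that("relabeling subpopulations leaves the likelihood unchanged", {
    cfg <- separatedConfig(seed = 43, nLines = 30L, nSsrs = 6L)
    dp <- asDosagePanel(simulateAdmixedPopulation(cfg))
    fit <- estimateAdmixture(dp, K = 3, seed = 4, nRestarts = 1)
    perm <- c(3, 1, 2)
    ll <- admixtureLoglik(dp, qMatrix(fit)[, perm],
                          lapply(fit@freqs, function(f)
                              f[perm, , drop = FALSE]))
    expect_equal(ll, fit@loglik, tolerance = 1e-9)
})

test_that("well-separated subpopulations are assigned confidently", {
    ## two subpopulations with private alleles
    n <- 30
    grp <- rep(1:2, each = n / 2)
    set.seed(44)
    Dl <- lapply(1:4, function(l) {
        D <- matrix(0L, n, 4)
        for (i in seq_len(n)) {
            al <- sample(if (grp[i] == 1) 1:2 else 3:4, 4, TRUE)
            D[i, ] <- tabulate(al, 4)
        }
        makeLocus(D)
    })
    fit <- estimateAdmixture(Dl, K = 2, seed = 5, nRestarts = 2)
    expect_gt(mean(apply(qMatrix(fit), 1, max)), 0.95)
    ## and the two groups land in different clusters
    assign <- apply(qMatrix(fit), 1, which.max)
    expect_equal(length(unique(tapply(assign, grp, median))), 2L)
})

test_that("Evanno table matches a direct evaluation of the formula", {
    L <- c(-100, -50, -30, -28, -27, -26.5)
    set.seed(45)
    M <- sapply(1:3, function(r) L + rnorm(6, 0, 1))
    rownames(M) <- 1:6
    ev <- evannoDeltaK(M)
    ## independent brute-force recomputation
    for (i in 2:5) {
        sec <- abs(M[i + 1, ] - 2 * M[i, ] + M[i - 1, ])
        expect_equal(ev$labs2[i], mean(sec))
        expect_equal(ev$deltaK[i], mean(sec) / sd(M[i, ]))
    }
    ## the sharp bend after the second K dominates
    expect_equal(attr(ev, "bestK"),
                 ev$K[which.max(ev$deltaK)])
})

test_that("linear log-likelihood growth gives zero deltaK", {
    M <- sapply(1:3, function(r) seq(-100, -50, by = 10) + r / 10)
    rownames(M) <- 1:6
    ev <- evannoDeltaK(M)
    expect_true(all(abs(ev$deltaK[2:5]) < 1e-9))
})

test_that("degenerate replicate sd yields missing deltaK with warning", {
    M <- cbind(c(-10, -8, -7.5), c(-10, -8, -7.5), c(-10, -8, -7.5))
    rownames(M) <- 1:3
    expect_warning(ev <- evannoDeltaK(M), "sd is zero")
    expect_true(is.na(ev$deltaK[2]))
})

test_that("deltaK is invariant to shifting or scaling log-likelihoods", {
    set.seed(46)
    M <- matrix(rnorm(15, -100, 5), 5, 3,
                dimnames = list(1:5, NULL))
    ev <- evannoDeltaK(M)
    evShift <- evannoDeltaK(M + 1000)
    evScale <- evannoDeltaK(M * 3.7)
    expect_equal(ev$deltaK, evShift$deltaK, tolerance = 1e-9)
    expect_equal(ev$deltaK, evScale$deltaK, tolerance = 1e-9)
})

test_that("Loiselle kinship matches a brute-force double loop", {
    ## 4 lines x 2 loci, dosages chosen to include every pattern
    D1 <- makeLocus(rbind(c(2, 2, 0), c(1, 1, 2), c(0, 4, 0),
                          c(3, 0, 1)))
    D2 <- makeLocus(rbind(c(4, 0), c(2, 2), c(0, 4), c(1, 3)))
    kin <- loiselleKinship(list(l1 = D1, l2 = D2),
                           truncate = FALSE, repair = FALSE)
    n <- 4
    num <- matrix(0, n, n); den <- matrix(0, n, n)
    for (D in list(D1, D2)) {
        P <- D / 4
        for (a in seq_len(ncol(D))) {
            pbar <- mean(P[, a])
            for (i in 1:n) for (j in 1:n) {
                num[i, j] <- num[i, j] +
                    (P[i, a] - pbar) * (P[j, a] - pbar) +
                    pbar * (1 - pbar) / (n - 1)
                den[i, j] <- den[i, j] + pbar * (1 - pbar)
            }
        }
    }
    expect_equal(unname(kin@.Data), num / den, tolerance = 1e-12)
})

test_that("clones are more akin than the panel average", {
    cfg <- separatedConfig(seed = 47, nLines = 20L, nSsrs = 8L)
    p <- simulateAdmixedPopulation(cfg)
    Dl <- lapply(p@dosages[p@markerInfo$role == "structure"],
                 function(D) {
                     D <- rbind(D, D[1, , drop = FALSE])  # clone line 1
                     rownames(D) <- c(head(rownames(D), -1), "CLONE")
                     D
                 })
    kin <- loiselleKinship(Dl)
    f <- kin@.Data
    expect_gt(f["L001", "CLONE"],
              mean(f[upper.tri(f)]))
})

test_that("unrelated lines produce negative raw estimates, then zeros", {
    cfg <- simConfig(nLines = 40L, includeControl = FALSE, KTrue = 1L,
                     nStructureSsrs = 10L,
                     candidateMarkers = smallMarkers(), seed = 48)
    dp <- asDosagePanel(simulateAdmixedPopulation(cfg))
    raw <- loiselleKinship(dp, truncate = FALSE, repair = FALSE)
    expect_gt(sum(raw@.Data[upper.tri(raw@.Data)] < 0), 0)
    kin <- loiselleKinship(dp)
    expect_gt(kin@nTruncated, 0L)
    expect_true(all(kin@.Data >= 0))
    expect_gte(min(eigen(kin@.Data, symmetric = TRUE)$values), -1e-8)
})

test_that("kinship ignores allele labels and locus order", {
    D1 <- makeLocus(rbind(c(2, 2, 0), c(1, 1, 2), c(0, 4, 0)))
    D2 <- makeLocus(rbind(c(4, 0), c(2, 2), c(1, 3)))
    k1 <- loiselleKinship(list(a = D1, b = D2))
    ## permute allele columns and swap locus order
    D1p <- D1[, c(3, 1, 2)]; colnames(D1p) <- c("x", "y", "z")
    k2 <- loiselleKinship(list(b = D2, a = D1p))
    expect_equal(k1@.Data, k2@.Data, tolerance = 1e-12)
})

test_that("monomorphic-only input is an error", {
    D <- makeLocus(matrix(c(4L, 4L, 4L), 3, 1))
    expect_error(loiselleKinship(list(l = D)), "monomorphic")
})
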