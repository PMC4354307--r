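test_that("default layout satisfies every field-design constraint", {
    tr <- buildFieldLayout(seed = 31)
    pl <- tr@plots
    expect_equal(nrow(pl), 432L)
    expect_identical(validateLayout(tr), character(0))
    expect_true(all(tapply(pl$is_control, pl$col, sum) == 8L))
    set9 <- (pl$row - 1L) %/% 9L
    expect_true(all(tapply(pl$is_control, set9, sum) == 6L))
    expect_true(all(tapply(pl$is_control, pl$row, sum) <= 1L))
    ## one full replicate in each 3-column block
    for (cols in list(1:3, 4:6)) {
        blk <- pl[pl$col %in% cols & !pl$is_control, ]
        expect_true(all(table(blk$line_id) == 1L))
        expect_equal(nrow(blk), 192L)
    }
})

test_that("validateLayout names the offending column or plot", {
    tr <- buildFieldLayout(seed = 32)
    pl <- tr@plots
    ## move one control into a different column
    i <- which(pl$is_control & pl$col == 1L)[1]
    j <- which(!pl$is_control & pl$col == 2L &
               !(pl$row %in% pl$row[pl$is_control]))[1]
    pl$is_control[c(i, j)] <- c(FALSE, TRUE)
    pl$line_id[j] <- "CONTROL"
    v <- validateLayout(pl)
    expect_true(any(grepl("column 1", v)))
    ## drop a plot entirely
    v2 <- validateLayout(tr@plots[-1, ])
    expect_true(any(grepl("incomplete", v2)))
})

test_that("infeasible plot counts are rejected up front", {
    expect_error(buildFieldLayout(lineIds = sprintf("L%03d", 1:100)),
                 "infeasible")
})

test_that("identity-covariance fit reduces to one-way ANOVA", {
    cfg <- smallConfig(seed = 33)
    s <- simulateStudy(cfg, layout = smallLayout())
    noCov <- list(rhoRow = 0, rhoCol = 0, gammaC = 0, gammaB = 0)
    f <- fitSpatialReml(s$trial, "C6", "2011", fixed = noCov)
    ph <- s$trial@phenotypes
    ph <- ph[ph$trait == "C6" & ph$year == "2011", ]
    dat <- merge(s$trial@plots, ph[, c("plot_order", "value")],
                 by = "plot_order")
    a <- anova(lm(value ~ factor(line_id), dat))
    expect_lt(abs(f@fTest[["F"]] - a$`F value`[1]), 1e-8)
    expect_equal(f@fTest[["df1"]], a$Df[1])
    expect_equal(f@fTest[["df2"]], a$Df[2])
    ## and adjusted means equal raw line means
    raw <- tapply(dat$value, dat$line_id, mean)
    expect_equal(f@lineMeans[names(raw)], c(raw), tolerance = 1e-10)
})

test_that("AR(1)xAR(1) plus block components stays positive definite", {
    pl <- buildFieldLayout(seed = 34)@plots
    set.seed(34)
    for (i in 1:6) {
        W <- spatialCovariance(pl, runif(1, -0.94, 0.94),
                               runif(1, -0.94, 0.94),
                               runif(1, 0, 2), runif(1, 0, 2))
        expect_silent(chol(W))
    }
})

test_that("GLS residual sum of squares matches whitened OLS", {
    cfg <- smallConfig(seed = 35)
    s <- simulateStudy(cfg, layout = smallLayout())
    ph <- s$trial@phenotypes
    ph <- ph[ph$trait == "C6" & ph$year == "2011", ]
    dat <- merge(s$trial@plots, ph[, c("plot_order", "value")],
                 by = "plot_order")
    W <- spatialCovariance(dat, 0.5, 0.3, 0.4, 0.2)
    li <- as.integer(factor(dat$line_id))
    gls <- tetraQK:::remlEval(W, dat$value, li, max(li))
    ## whiten and refit by OLS
    cW <- chol(W)
    X <- model.matrix(~ 0 + factor(dat$line_id))
    yw <- forwardsolve(t(cW), dat$value)
    Xw <- forwardsolve(t(cW), X)
    ols <- lm.fit(Xw, yw)
    expect_lt(abs(gls$rss - sum(ols$residuals^2)), 1e-8)
})

test_that("REML log-likelihood is invariant to plot order", {
    cfg <- smallConfig(seed = 36)
    s <- simulateStudy(cfg, layout = smallLayout())
    f1 <- fitSpatialReml(s$trial, "C3", "2012", nStarts = 1)
    tr2 <- s$trial
    set.seed(1)
    perm <- sample(nrow(tr2@plots))
    tr2@plots <- tr2@plots[perm, ]
    f2 <- fitSpatialReml(tr2, "C3", "2012", nStarts = 1)
    expect_equal(f1@loglik, f2@loglik, tolerance = 1e-6)
    expect_equal(f1@lineMeans, f2@lineMeans, tolerance = 1e-6)
})

test_that("the REML optimum beats random parameter points", {
    cfg <- smallConfig(seed = 37)
    s <- simulateStudy(cfg, layout = smallLayout())
    f <- fitSpatialReml(s$trial, "C6", "2012", nStarts = 2)
    ph <- s$trial@phenotypes
    ph <- ph[ph$trait == "C6" & ph$year == "2012", ]
    dat <- merge(s$trial@plots, ph[, c("plot_order", "value")],
                 by = "plot_order")
    li <- as.integer(factor(dat$line_id))
    set.seed(37)
    for (i in 1:50) {
        W <- spatialCovariance(dat, runif(1, -0.9, 0.9),
                               runif(1, -0.9, 0.9),
                               runif(1, 0, 2), runif(1, 0, 2))
        ll <- -tetraQK:::remlEval(W, dat$value, li, max(li))$nll
        expect_lte(ll, f@loglik + 1e-6)
    }
})

test_that("spatial adjustment beats raw means under a row gradient", {
    ## strong spatial trend: adjusted means should track the true
    ## genetic values better than raw plot means (paired over trials)
    wins <- 0L
    for (s in 1:5) {
        cfg <- smallConfig(seed = 400 + s, rhoRow = 0.9, rhoCol = 0.5,
                           sigma2E = c(C6 = 8, C3 = 0.5))
        st <- simulateStudy(cfg, layout = smallLayout())
        f <- fitSpatialReml(st$trial, "C6", "2011", nStarts = 1)
        ph <- st$trial@phenotypes
        ph <- ph[ph$trait == "C6" & ph$year == "2011", ]
        dat <- merge(st$trial@plots, ph[, c("plot_order", "value")],
                     by = "plot_order")
        raw <- tapply(dat$value, dat$line_id, mean)
        g <- st$panel@geneticValues[, "C6"]
        g <- g + 15.8  # baseline
        adj <- f@lineMeans[names(g)]
        mseAdj <- mean((adj - g)^2)
        mseRaw <- mean((raw[names(g)] - g)^2)
        wins <- wins + (mseAdj < mseRaw)
    }
    expect_gte(wins, 4L)
})

test_that("line F-test keeps its size under the null", {
    ## no line effects, independent errors: the Wald F with residual df
    ## should reject at close to the nominal rate
    tr <- buildFieldLayout(lineIds = sprintf("L%02d", 1:48),
                           nRows = 18L, nCols = 6L, nControls = 12L,
                           seed = 38)
    noCov <- list(rhoRow = 0, rhoCol = 0, gammaC = 0, gammaB = 0)
    set.seed(38)
    rej <- 0L
    for (i in 1:200) {
        tr@phenotypes <- data.frame(
            plot_order = tr@plots$plot_order, trait = "C6",
            year = "2011", value = rnorm(nrow(tr@plots)))
        f <- fitSpatialReml(tr, "C6", "2011", fixed = noCov)
        rej <- rej + (f@fTest[["p"]] < 0.05)
    }
    expect_gte(rej / 200, 0.02)
    expect_lte(rej / 200, 0.09)
})

test_that("missing plots are dropped, not imputed", {
    cfg <- smallConfig(seed = 39)
    s <- simulateStudy(cfg, layout = smallLayout())
    ph <- s$trial@phenotypes
    sel <- ph$trait == "C6" & ph$year == "2011"
    ph$value[which(sel)[1:5]] <- NA
    s$trial@phenotypes <- ph
    f <- fitSpatialReml(s$trial, "C6", "2011", nStarts = 1)
    expect_equal(f@nObs, sum(sel) - 5L)
    expect_equal(length(f@lineMeans), 49L)  # all lines still estimable
})
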