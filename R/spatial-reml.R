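#' @include field-layout.R
NULL

#' Scaled covariance of the spatial field-trial model
#'
#' Builds the plot covariance matrix, up to the residual variance
#' scale: `W = R_row(rho_row) x R_col(rho_col) + gammaC * [same column
#' set] + gammaB * [same extraction batch]`, where the first term is the
#' separable AR(1) x AR(1) correlation over grid distance and the gamma
#' terms are the column-set and 36-plot-batch variance ratios. `W` is
#' symmetric positive definite for `|rho| < 1` and nonnegative gammas.
#'
#' @param plots data.frame with `row`, `col`, `colset_id`, `batch36_id`
#'   (any subset of plots, in any order).
#' @param rhoRow,rhoCol AR(1) correlations.
#' @param gammaC,gammaB variance ratios (component / residual).
#' @return covariance matrix of dimension `nrow(plots)`.
#' @export
spatialCovariance <- function(plots, rhoRow, rhoCol,
                              gammaC = 0, gammaB = 0) {
    W <- rhoRow^abs(outer(plots$row, plots$row, "-")) *
        rhoCol^abs(outer(plots$col, plots$col, "-"))
    if (gammaC != 0)
        W <- W + gammaC * outer(plots$colset_id, plots$colset_id, "==")
    if (gammaB != 0)
        W <- W + gammaB * outer(plots$batch36_id, plots$batch36_id, "==")
    W
}

## Profiled REML deviance pieces for the cell-means line model.
## Returns -logLik (up to a constant) plus the GLS solution.
remlEval <- function(W, y, lineIdx, nLev) {
    cho <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(cho)) return(list(nll = 1e10))
    Wi <- chol2inv(cho)
    B <- rowsum(Wi, lineIdx)      # nLev x n
    G <- rowsum(t(B), lineIdx)    # X' W^-1 X
    Wy <- drop(Wi %*% y)
    b <- drop(rowsum(matrix(Wy), lineIdx))
    cG <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(cG)) return(list(nll = 1e10))
    tau <- backsolve(cG, forwardsolve(t(cG), b))
    rss <- sum(y * Wy) - sum(b * tau)
    n <- length(y)
    df <- n - nLev
    if (rss <= 0) return(list(nll = 1e10))
    sigma2 <- rss / df
    nll <- 0.5 * (df * log(sigma2) + 2 * sum(log(diag(cho))) +
                  2 * sum(log(diag(cG))))
    list(nll = nll, tau = tau, sigma2 = sigma2, cG = cG, rss = rss)
}

#' Fit the spatial REML phenotype-adjustment model
#'
#' Fits, by restricted maximum likelihood, the mixed model used to
#' adjust plot phenotypes for spatial field trend and processing
#' effects: line as a fixed effect (all levels, including the control),
#' random column-set and 36-plot extraction-batch effects, and an
#' AR(1) x AR(1) correlated residual over the plot grid. The residual
#' variance is profiled out and the remaining four parameters
#' (`rho_row`, `rho_col` and the two variance ratios) are maximized
#' numerically from several starting points on an unconstrained
#' transform of the parameter space. Missing plots are dropped, which
#' subsets the covariance rather than imputing.
#'
#' @param trial a [FieldTrial-class] with phenotypes.
#' @param trait,year select the trait-year dataset.
#' @param nStarts number of optimizer starts (first two deterministic,
#'   further ones random).
#' @param fixed optional named list pinning any of `rhoRow`, `rhoCol`,
#'   `gammaC`, `gammaB` (variance ratios) instead of estimating them;
#'   e.g. `list(rhoRow = 0, rhoCol = 0, gammaC = 0, gammaB = 0)`
#'   reduces the fit to ordinary least squares.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed seed for the random restarts.
#' @return a [SpatialFit-class] with variance components, correlations,
#'   adjusted line means, standard errors and the overall line F-test
#'   (denominator df = plots minus line levels).
#' @seealso [adjustedMeans()], [lineFTest()]
#' @export
fitSpatialReml <- function(trial, trait = "C6", year = "2011",
                           nStarts = 3L, fixed = list(),
                           maxit = 600L, seed = 1L) {
    stopifnot(is(trial, "FieldTrial"))
    ph <- trial@phenotypes
    ph <- ph[ph$trait == trait & ph$year == year, , drop = FALSE]
    if (!nrow(ph))
        stop("no phenotypes for ", trait, " ", year)
    dat <- merge(trial@plots, ph[, c("plot_order", "value")],
                 by = "plot_order")
    dat <- dat[!is.na(dat$value), , drop = FALSE]
    dat <- dat[order(dat$plot_order), , drop = FALSE]
    lineF <- factor(dat$line_id)
    lineIdx <- as.integer(lineF)
    nLev <- nlevels(lineF)
    n <- nrow(dat)
    if (n <= nLev)
        stop("fewer plots than line levels after removing missing")
    y <- dat$value

    parNames <- c("rhoRow", "rhoCol", "gammaC", "gammaB")
    free <- setdiff(parNames, names(fixed))
    toNatural <- function(p) {
        full <- list(rhoRow = 0, rhoCol = 0, gammaC = 0, gammaB = 0)
        full[names(fixed)] <- fixed
        for (i in seq_along(free)) {
            v <- unname(p[i])
            full[[free[i]]] <- if (grepl("^rho", free[i]))
                0.95 * tanh(v) else exp(v)
        }
        full
    }
    ## compiled objective kernels (the pure-R remlEval is the reference
    ## implementation, cross-checked in the tests); complete grids use
    ## the sparse Kronecker/Woodbury route, anything else the dense one
    nR <- max(dat$row); nC <- max(dat$col)
    completeGrid <- nrow(dat) == nR * nC &&
        !anyDuplicated(dat[, c("row", "col")])
    evalAt <- function(th, full = FALSE) {
        if (completeGrid)
            .remlGridCpp(as.integer(dat$row), as.integer(dat$col),
                         nR, nC, as.integer(dat$colset_id),
                         as.integer(dat$batch36_id), y, lineIdx, nLev,
                         th$rhoRow, th$rhoCol, th$gammaC, th$gammaB,
                         full)
        else
            .remlEvalCpp(as.integer(dat$row), as.integer(dat$col),
                         as.integer(dat$colset_id),
                         as.integer(dat$batch36_id), y, lineIdx, nLev,
                         th$rhoRow, th$rhoCol, th$gammaC, th$gammaB,
                         full)
    }
    obj <- function(p) evalAt(toNatural(p))$nll

    best <- NULL
    if (length(free)) {
        ## local RNG stream for the random restarts; the caller's RNG
        ## state is untouched
        if (exists(".Random.seed", envir = globalenv())) {
            oldSeed <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", oldSeed,
                           envir = globalenv()), add = TRUE)
        }
        set.seed(seed)
        starts <- list(
            setNames(rep(0, length(free)), free),
            setNames(ifelse(grepl("^rho", free),
                            atanh(0.5 / 0.95), log(0.5)), free))
        while (length(starts) < nStarts)
            starts[[length(starts) + 1L]] <-
                setNames(runif(length(free), -1, 1), free)
        starts <- starts[seq_len(max(1L, nStarts))]
        for (s in starts) {
            op <- optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7))
            if (is.null(best) || op$value < best$value) best <- op
        }
        th <- toNatural(best$par)
        converged <- best$convergence == 0L
    } else {
        th <- toNatural(numeric(0))
        converged <- TRUE
        best <- list(value = obj(numeric(0)))
    }
    fit <- evalAt(th, full = TRUE)
    if (!is.finite(fit$nll) || fit$nll >= 1e10)
        stop("REML fit failed at the optimum; data may be degenerate")
    sigma2 <- fit$sigma2
    C <- fit$Ginv * sigma2
    tau <- setNames(drop(fit$tau), levels(lineF))
    se <- setNames(sqrt(diag(C)), levels(lineF))

    ## overall line F-test: all line means equal
    p1 <- nLev - 1L
    Lt <- tau[-nLev] - tau[nLev]
    LCL <- C[-nLev, -nLev] -
        matrix(C[-nLev, nLev], p1, p1) -
        t(matrix(C[-nLev, nLev], p1, p1)) + C[nLev, nLev]
    Fstat <- drop(crossprod(Lt, solve(LCL, Lt))) / p1
    df2 <- n - nLev
    pval <- pf(Fstat, p1, df2, lower.tail = FALSE)

    boundary <- abs(th$rhoRow) > 0.93 || abs(th$rhoCol) > 0.93 ||
        (!"gammaC" %in% names(fixed) && th$gammaC < 1e-5) ||
        (!"gammaB" %in% names(fixed) && th$gammaB < 1e-5)

    new("SpatialFit",
        trait = trait, year = as.character(year),
        varComponents = c(sigma2_e = sigma2,
                          sigma2_c = th$gammaC * sigma2,
                          sigma2_b = th$gammaB * sigma2),
        rho = c(rho_row = th$rhoRow, rho_col = th$rhoCol),
        lineMeans = tau, lineSE = se,
        loglik = -fit$nll,
        fTest = c(F = Fstat, df1 = p1, df2 = df2, p = pval),
        converged = converged, boundary = boundary,
        nObs = as.integer(n))
}

#' @rdname accessors
#' @export
setMethod("adjustedMeans", "SpatialFit", function(object, ...) {
    data.frame(line_id = names(object@lineMeans),
               trait = object@trait, year = object@year,
               mean = unname(object@lineMeans),
               se = unname(object@lineSE),
               stringsAsFactors = FALSE)
})

#' Adjusted line means across trait-year fits
#'
#' Combines one or more [SpatialFit-class]es into a single adjusted-mean
#' table (one row per line and trait-year, nmol/mg) and attaches the
#' per-dataset min/max range as the `"range"` attribute.
#'
#' @param fits a [SpatialFit-class] or list of them.
#' @return data.frame with columns `line_id`, `trait`, `year`, `mean`,
#'   `se`.
#' @export
adjustedLineMeans <- function(fits) {
    if (is(fits, "SpatialFit")) fits <- list(fits)
    tab <- do.call(rbind, lapply(fits, adjustedMeans))
    rng <- do.call(rbind, lapply(fits, function(f)
        data.frame(trait = f@trait, year = f@year,
                   min = min(f@lineMeans), max = max(f@lineMeans))))
    attr(tab, "range") <- rng
    tab
}

#' Overall line F-test from a spatial fit
#'
#' Wald F for the hypothesis that all line means are equal, using the
#' REML-estimated covariance and residual denominator degrees of freedom
#' (plots minus line levels) as the df approximation.
#'
#' @param fit a [SpatialFit-class].
#' @return named numeric `F`, `df1`, `df2`, `p`.
#' @export
lineFTest <- function(fit) {
    stopifnot(is(fit, "SpatialFit"))
    fit@fTest
}
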