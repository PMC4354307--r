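#' @include kinship.R spatial-reml.R
NULL

#' Minor allele frequency from a dosage column
#'
#' Allele frequency as copies over gene copies,
#' `sum(d) / (4 * n_nonmissing)`. For a biallelic marker the minor
#' allele frequency `min(f, 1 - f)` is returned; for an individual SSR
#' allele its own frequency is the relevant quantity (set
#' `biallelic = FALSE`). Rounding is left to reporting.
#'
#' @param d dosages 0-4, `NA` allowed.
#' @param biallelic fold the frequency onto [0, 0.5].
#' @return frequency.
#' @examples
#' minorAlleleFrequency(c(rep(1, 3), rep(0, 189)), biallelic = FALSE)
#' @export
minorAlleleFrequency <- function(d, biallelic = TRUE) {
    ok <- !is.na(d)
    if (!any(ok)) stop("all dosages missing")
    f <- sum(d[ok]) / (4 * sum(ok))
    if (biallelic) min(f, 1 - f) else f
}

#' Genotype factor design from a dosage column
#'
#' Builds the fixed-effect design for one tested allele: one indicator
#' per observed dosage class beyond the reference class (the most
#' frequent dosage), giving `#classes - 1` degrees of freedom, plus the
#' numeric copy count as the additive covariate used for the allele
#' substitution effect.
#'
#' @param d dosage column (no missing values).
#' @return list with `factorX` (matrix, may have 1..4 columns),
#'   `classes` (observed dosage classes), `reference`; or `NULL` when
#'   the column is monomorphic.
#' @export
encodeGenotypeFactor <- function(d) {
    classes <- sort(unique(d))
    if (length(classes) < 2L) return(NULL)
    tab <- table(d)
    ref <- as.numeric(names(tab)[which.max(tab)])
    other <- setdiff(classes, ref)
    X <- vapply(other, function(cl) as.numeric(d == cl),
                numeric(length(d)))
    X <- matrix(X, ncol = length(other),
                dimnames = list(NULL, paste0("dose", other)))
    list(factorX = X, classes = classes, reference = ref)
}

## Weighted (rotated-space) least squares pieces used by the Q+K model.
wls <- function(Xt, yt, w) {
    A <- crossprod(Xt, Xt * w)
    b <- drop(crossprod(Xt, yt * w))
    cA <- tryCatch(chol(A), error = function(e) NULL)
    aliased <- NULL
    if (is.null(cA)) {
        ## drop aliased columns
        q <- qr(A)
        keep <- q$pivot[seq_len(q$rank)]
        aliased <- colnames(Xt)[-keep]
        Xt <- Xt[, keep, drop = FALSE]
        A <- crossprod(Xt, Xt * w)
        b <- drop(crossprod(Xt, yt * w))
        cA <- chol(A)
    }
    beta <- backsolve(cA, forwardsolve(t(cA), b))
    rss <- sum(yt^2 * w) - sum(b * beta)
    list(beta = setNames(beta, colnames(Xt)), rss = rss, cA = cA,
         rank = ncol(Xt), aliased = aliased, Xt = Xt)
}

## REML profile over delta = sigma2_e / sigma2_g in the rotated model.
remlDelta <- function(Xt, yt, dEig, lower = -10, upper = 15) {
    n <- length(yt); p <- ncol(Xt)
    nll <- function(logd) {
        w <- 1 / (dEig + exp(logd))
        fit <- wls(Xt, yt, w)
        if (fit$rss <= 0) return(1e10)
        s2 <- fit$rss / (n - p)
        0.5 * ((n - p) * log(s2) + sum(log(dEig + exp(logd))) +
               2 * sum(log(diag(fit$cA))))
    }
    op <- optimize(nll, c(lower, upper), tol = 1e-8)
    exp(op$minimum)
}

#' Prepare the null Q+K model for a trait-year dataset
#'
#' Eigendecomposes the kinship matrix once and estimates the
#' variance-component ratio `delta = sigma2_e / sigma2_g` by REML under
#' the marker-free model `y = [1, Q] alpha + u + e`,
#' `u ~ (0, sigma2_g * KIN)`. The decomposition and `delta` are reused
#' across markers (fast mode); the exact mode re-estimates `delta` per
#' marker.
#'
#' @param y named numeric vector of adjusted line means.
#' @param Q [AdmixtureFit-class] or membership matrix; its first
#'   `K - 1` columns enter as covariates (the last is dropped against
#'   the intercept). `NULL` for no structure covariates.
#' @param kin [KinshipMatrix-class] or PSD matrix; `NULL` for identity.
#' @return list used by [fitQKModel()]: rotation `U`, eigenvalues `d`,
#'   `delta`, `sigma2g`, `sigma2e`, rotated design pieces and line ids.
#' @export
qkNull <- function(y, Q = NULL, kin = NULL) {
    lines <- names(y)
    if (is.null(lines)) stop("y must be named by line id")
    n <- length(y)
    if (is(Q, "AdmixtureFit")) Q <- qMatrix(Q)
    if (!is.null(Q)) {
        if (is.null(rownames(Q))) stop("Q must have line rownames")
        miss <- setdiff(lines, rownames(Q))
        if (length(miss))
            stop("lines missing from Q: ",
                 paste(head(miss, 5), collapse = ", "))
        Q <- Q[lines, , drop = FALSE]
        colnames(Q) <- paste0("Q", seq_len(ncol(Q)))
    }
    if (is.null(kin)) {
        kin <- diag(n); dimnames(kin) <- list(lines, lines)
    }
    kinM <- if (is(kin, "KinshipMatrix")) kin@.Data else as.matrix(kin)
    miss <- setdiff(lines, rownames(kinM))
    if (length(miss))
        stop("lines missing from kinship: ",
             paste(head(miss, 5), collapse = ", "))
    kinM <- kinM[lines, lines]
    e <- eigen(kinM, symmetric = TRUE)
    if (min(e$values) < -1e-6 * max(abs(e$values)))
        stop("kinship is not positive semidefinite; ",
             "repair it (e.g. loiselleKinship does) before use")
    d <- pmax(e$values, 0)
    U <- e$vectors
    W <- cbind(`(Intercept)` = rep(1, n))
    if (!is.null(Q) && ncol(Q) > 1L)
        W <- cbind(W, Q[, -ncol(Q), drop = FALSE])
    yt <- drop(crossprod(U, y))
    Wt <- crossprod(U, W)
    colnames(Wt) <- colnames(W)
    delta <- remlDelta(Wt, yt, d)
    w <- 1 / (d + delta)
    f0 <- wls(Wt, yt, w)
    sigma2g <- f0$rss / (n - ncol(Wt))
    list(lines = lines, U = U, d = d, delta = delta, w = w,
         sigma2g = sigma2g, sigma2e = delta * sigma2g,
         y = y, yt = yt, W = W, Wt = Wt, rss0 = f0$rss,
         p0 = ncol(Wt), Qorig = Q, kinM = kinM)
}

#' Test one marker allele with the Q+K mixed model
#'
#' Fits `y = W alpha + G gamma + u + e` where `W` holds the intercept
#' and structure covariates, `G` the genotype-as-factor indicators (one
#' per observed dosage class beyond the reference), `u ~ (0, sigma2_g *
#' KIN)` and `e ~ (0, sigma2_e * I)`. The p-value is a Wald F on the
#' genotype block with denominator df `n - rank(X)`; the allele
#' substitution effect is the additive per-copy coefficient refit at the
#' same variance components; dosage-class means are model-based.
#'
#' @param null result of [qkNull()] for the trait-year dataset.
#' @param d named dosage column (0-4; `NA` drops the line marker-wise).
#' @param exact re-estimate the variance ratio under this marker's full
#'   model instead of reusing the null-model ratio.
#' @return list with `p`, `effect`, `df1`, `df2`, `n`, `sigma2g`,
#'   `sigma2e`, `classes`, `classMeans`; or `NULL` if the column is
#'   monomorphic after missing-data removal.
#' @export
fitQKModel <- function(null, d, exact = FALSE) {
    d <- d[null$lines]
    ok <- !is.na(d)
    sub <- !all(ok)
    enc <- encodeGenotypeFactor(d[ok])
    if (is.null(enc)) return(NULL)
    if (sub) {
        ## marker-wise complete case: rebuild the rotation on the subset
        okLines <- null$lines[ok]
        nullSub <- qkNull(null$y[ok],
                          Q = if (is.null(null$Qorig)) NULL
                              else null$Qorig[okLines, , drop = FALSE],
                          kin = null$kinM[okLines, okLines])
        return(fitQKModel(nullSub, d[ok], exact = exact))
    }
    n <- length(d)
    U <- null$U
    Gt <- crossprod(U, enc$factorX)
    colnames(Gt) <- colnames(enc$factorX)
    Xt <- cbind(null$Wt, Gt)
    delta <- if (exact) remlDelta(Xt, null$yt, null$d) else null$delta
    w <- 1 / (null$d + delta)
    full <- wls(Xt, null$yt, w)
    red <- wls(null$Wt, null$yt, w)
    q <- full$rank - red$rank
    df2 <- n - full$rank
    if (q < 1L || df2 < 1L) return(NULL)
    Fstat <- ((red$rss - full$rss) / q) / (full$rss / df2)
    pval <- pf(Fstat, q, df2, lower.tail = FALSE)
    ## additive per-copy effect at the same variance components
    at <- crossprod(U, matrix(d, ncol = 1))
    colnames(at) <- "copies"
    addFit <- wls(cbind(null$Wt, at), null$yt, w)
    effect <- unname(addFit$beta["copies"])
    ## model-based class means: average non-genotype fixed part + class
    ## effect (reference class effect = 0)
    keep <- colnames(full$Xt)
    bW <- full$beta[intersect(keep, colnames(null$Wt))]
    baseMean <- mean(null$W[, names(bW), drop = FALSE] %*% bW)
    cls <- enc$classes
    eff <- setNames(rep(0, length(cls)), paste0("dose", cls))
    got <- intersect(names(full$beta), names(eff))
    eff[got] <- full$beta[got]
    s2g <- full$rss / df2
    list(p = pval, F = Fstat, effect = effect, df1 = q, df2 = df2,
         n = n, sigma2g = s2g, sigma2e = delta * s2g, delta = delta,
         classes = cls,
         classMeans = setNames(baseMean + eff, cls),
         aliased = full$aliased)
}

#' Marker-by-marker Q+K association scan
#'
#' Tests every candidate marker allele against every trait-year dataset
#' of adjusted means, one Q+K mixed model per test, then assigns Storey
#' q-values over the pooled p-values of all datasets. Control lines are
#' excluded; records are sorted by p within trait-year.
#'
#' @param means adjusted-mean table from [adjustedLineMeans()] (columns
#'   `line_id`, `trait`, `year`, `mean`).
#' @param panel a [DosagePanel-class]; candidate marker-allele rows are
#'   tested.
#' @param Q,kin structure and kinship inputs, see [qkNull()].
#' @param excludeLines line ids left out (default: any line flagged as
#'   control by matching `controlId`).
#' @param controlId id of the control line.
#' @param exact exact per-marker variance-component refits instead of
#'   the fast shared-ratio mode.
#' @param qvalueArgs list of arguments passed to [storeyQvalues()].
#' @return data.frame with one row per marker-allele x trait-year:
#'   `marker_id`, `allele`, `type`, `gene`, `trait`, `year`, `n`,
#'   `maf`, `p`, `q`, `neg_log10_p`, `effect`, `sigma2_g`, `sigma2_e`,
#'   `df1`, `class_means` (encoded `class:mean` pairs). Skipped
#'   monomorphic columns are recorded in the `"skipped"` attribute.
#' @export
associationScan <- function(means, panel, Q = NULL, kin = NULL,
                            excludeLines = NULL, controlId = "CONTROL",
                            exact = FALSE,
                            qvalueArgs = list(seed = 1L)) {
    stopifnot(is(panel, "DosagePanel"))
    rd <- as.data.frame(rowData(panel))
    cand <- which(rd$role == "candidate")
    if (!length(cand)) cand <- seq_len(nrow(rd))
    dm <- t(assay(panel, "dosage")[cand, , drop = FALSE])
    rdc <- rd[cand, , drop = FALSE]
    if (is.null(excludeLines))
        excludeLines <- intersect(controlId, rownames(dm))
    keepLines <- setdiff(rownames(dm), excludeLines)

    datasets <- unique(means[, c("trait", "year")])
    records <- list(); skipped <- list()
    for (i in seq_len(nrow(datasets))) {
        tr <- datasets$trait[i]; yr <- datasets$year[i]
        mrows <- means[means$trait == tr & means$year == yr, ]
        bad <- setdiff(mrows$line_id,
                       c(rownames(dm), excludeLines))
        if (length(bad))
            stop("phenotyped lines not genotyped: ",
                 paste(head(bad, 5), collapse = ", "))
        lines <- intersect(keepLines, mrows$line_id)
        if (!length(lines))
            stop("no lines shared between means and genotypes for ",
                 tr, " ", yr)
        y <- setNames(mrows$mean[match(lines, mrows$line_id)], lines)
        null <- qkNull(y, Q = Q, kin = kin)
        for (j in seq_len(ncol(dm))) {
            dcol <- dm[lines, j]
            fit <- tryCatch(fitQKModel(null, dcol, exact = exact),
                            error = function(e) NULL)
            if (is.null(fit)) {
                skipped[[length(skipped) + 1L]] <- data.frame(
                    marker_id = rdc$marker_id[j],
                    allele = rdc$allele[j], trait = tr, year = yr,
                    reason = "monomorphic or unfittable")
                next
            }
            maf <- minorAlleleFrequency(dcol,
                                        biallelic = rdc$type[j] != "SSR")
            records[[length(records) + 1L]] <- data.frame(
                marker_id = rdc$marker_id[j], allele = rdc$allele[j],
                type = rdc$type[j],
                gene = rdc$gene[j] %||% NA_character_,
                trait = tr, year = yr, n = fit$n, maf = maf,
                p = fit$p, effect = fit$effect, df1 = fit$df1,
                sigma2_g = fit$sigma2g, sigma2_e = fit$sigma2e,
                class_means = paste(fit$classes,
                                    round(fit$classMeans, 4),
                                    sep = ":", collapse = ";"),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(records)) stop("no testable markers")
    out <- do.call(rbind, records)
    qres <- do.call(storeyQvalues, c(list(p = out$p), qvalueArgs))
    out$q <- qres$qvalues
    out$neg_log10_p <- -log10(out$p)
    out <- out[order(out$trait, out$year, out$p), ]
    rownames(out) <- NULL
    attr(out, "pi0") <- qres$pi0
    attr(out, "skipped") <- if (length(skipped))
        do.call(rbind, skipped) else NULL
    out
}
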