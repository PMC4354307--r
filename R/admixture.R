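#' @include dosage-calling.R
NULL

## Per-locus dosage matrices (lines x alleles) from a DosagePanel,
## with null/missing copies renormalized to a weight total of 4.
structureDosageList <- function(x, role = "structure") {
    if (is(x, "DosagePanel")) {
        rd <- as.data.frame(rowData(x))
        keep <- which(rd$role %in% role)
        if (!length(keep)) stop("no loci with role ", role)
        sp <- split(keep, rd$marker_id[keep])
        out <- lapply(sp, function(ix)
            t(assay(x, "dosage")[ix, , drop = FALSE]))
        return(out[unique(rd$marker_id[keep])])
    }
    if (is.matrix(x)) return(list(locus1 = x))
    stopifnot(is.list(x))
    x
}

## weights: rows renormalized to sum 4; fully missing rows -> all 0
normalizeLocus <- function(D) {
    D <- as.matrix(D)
    D[is.na(D)] <- 0
    tot <- rowSums(D)
    w <- D * 0
    ok <- tot > 0
    w[ok, ] <- 4 * D[ok, , drop = FALSE] / tot[ok]
    w
}

#' Estimate admixture proportions by EM
#'
#' Maximizes the admixture log-likelihood
#' `sum_i sum_l sum_a d_ila * log( sum_k q_ik f_kla )`,
#' which treats each of the four allele copies of line `i` at locus `l`
#' as an independent draw: first an ancestry from the line's membership
#' row `q_i`, then an allele from that subpopulation's frequencies.
#' Fitting is by expectation-maximization (guaranteed nondecreasing
#' log-likelihood) with random restarts; copies hidden by null alleles
#' or missing genotypes are dropped and the remaining copies
#' renormalized.
#'
#' @param x a [DosagePanel-class] (its structure SSR loci are used), a
#'   list of per-locus lines-by-alleles dosage matrices, or one matrix.
#' @param K number of subpopulations (>= 1).
#' @param seed seed for the restart initializations.
#' @param nRestarts independent EM starts; the best is returned.
#' @param maxit,tol EM stopping rule (log-likelihood change).
#' @return an [AdmixtureFit-class]; `converged = FALSE` (with the best
#'   iterate) if `maxit` is hit.
#' @export
estimateAdmixture <- function(x, K, seed = 1L, nRestarts = 3L,
                              maxit = 2000L, tol = 1e-6) {
    stopifnot(K >= 1L)
    Dl <- lapply(structureDosageList(x), normalizeLocus)
    if (!length(Dl)) stop("no loci supplied")
    n <- nrow(Dl[[1]])
    lines <- rownames(Dl[[1]])
    if (K == 1L) {
        f <- lapply(Dl, function(D) {
            cs <- colSums(D)
            matrix(cs / sum(cs), 1L)
        })
        ll <- sum(vapply(seq_along(Dl), function(l) {
            D <- Dl[[l]]
            lf <- log(pmax(f[[l]][1, ], 1e-300))
            sum(sweep(D, 2, lf, "*"))
        }, numeric(1)))
        return(new("AdmixtureFit",
                   Q = matrix(1, n, 1L, dimnames = list(lines, NULL)),
                   freqs = f, K = 1L, loglik = ll, converged = TRUE,
                   nIter = 1L, trace = ll))
    }

    pooled <- lapply(Dl, function(D) {
        cs <- colSums(D) + 1e-6
        cs / sum(cs)
    })
    runEM <- function(rseed) {
        set.seed(rseed)
        q <- rdirichlet(n, rep(1, K))
        f <- lapply(pooled, function(p) {
            fm <- rdirichlet(K, p * 50)
            fm + 1e-9
        })
        trace <- numeric(0)
        llOld <- -Inf
        conv <- FALSE
        for (it in seq_len(maxit)) {
            S <- matrix(0, n, K)
            ll <- 0
            fNew <- f
            for (l in seq_along(Dl)) {
                D <- Dl[[l]]
                G <- q %*% f[[l]]
                G[G < 1e-300] <- 1e-300
                R <- D / G
                S <- S + R %*% t(f[[l]])
                fu <- f[[l]] * (t(q) %*% R)
                fu <- fu + 1e-12
                fNew[[l]] <- fu / rowSums(fu)
                ll <- ll + sum(D * log(G))
            }
            trace <- c(trace, ll)
            qNew <- q * S
            rs <- rowSums(qNew)
            ok <- rs > 0
            qNew[ok, ] <- qNew[ok, , drop = FALSE] / rs[ok]
            qNew[!ok, ] <- 1 / K
            q <- qNew; f <- fNew
            if (is.finite(llOld) && abs(ll - llOld) < tol) {
                conv <- TRUE
                break
            }
            llOld <- ll
        }
        ## likelihood at the final parameters
        llFinal <- 0
        for (l in seq_along(Dl)) {
            G <- q %*% f[[l]]
            G[G < 1e-300] <- 1e-300
            llFinal <- llFinal + sum(Dl[[l]] * log(G))
        }
        trace <- c(trace, llFinal)
        list(q = q, f = f, ll = llFinal, trace = trace, conv = conv,
             it = length(trace))
    }
    best <- NULL
    for (r in seq_len(max(1L, nRestarts))) {
        run <- runEM(seed + (r - 1L) * 1000L)
        if (is.null(best) || run$ll > best$ll) best <- run
    }
    rownames(best$q) <- lines
    new("AdmixtureFit", Q = best$q, freqs = best$f, K = as.integer(K),
        loglik = best$ll, converged = best$conv,
        nIter = as.integer(best$it), trace = best$trace)
}

#' Admixture log-likelihood at given parameters
#'
#' Evaluates the admixture log-likelihood for an explicit `(Q, freqs)`
#' pair, e.g. to verify invariance under subpopulation relabeling.
#'
#' @param x dosage input as in [estimateAdmixture()].
#' @param Q lines-by-K membership matrix.
#' @param freqs per-locus K-by-alleles frequency matrices.
#' @return log-likelihood value.
#' @export
admixtureLoglik <- function(x, Q, freqs) {
    Dl <- lapply(structureDosageList(x), normalizeLocus)
    ll <- 0
    for (l in seq_along(Dl)) {
        G <- Q %*% freqs[[l]]
        G[G < 1e-300] <- 1e-300
        ll <- ll + sum(Dl[[l]] * log(G))
    }
    ll
}

#' Replicated admixture runs over a range of K
#'
#' Runs [estimateAdmixture()] for each K in `Krange` with `nReps`
#' independently seeded replicates, collecting the replicate
#' log-likelihoods used by the Evanno delta-K criterion, and keeping the
#' best fit per K.
#'
#' @param x dosage input as in [estimateAdmixture()].
#' @param Krange contiguous K values, e.g. `1:10`.
#' @param nReps replicates per K.
#' @param seed base seed; replicate `r` of K uses
#'   `seed + 97 * K + 7919 * r`.
#' @param nRestarts EM restarts inside each replicate.
#' @param ... passed to [estimateAdmixture()].
#' @return list with `loglik` (K x replicate matrix, rownames = K),
#'   `fits` (best [AdmixtureFit-class] per K) and `Krange`.
#' @export
admixtureScan <- function(x, Krange = 1:10, nReps = 3L, seed = 1L,
                          nRestarts = 1L, ...) {
    Dl <- structureDosageList(x)
    ll <- matrix(NA_real_, length(Krange), nReps,
                 dimnames = list(as.character(Krange), NULL))
    fits <- list()
    for (i in seq_along(Krange)) {
        K <- Krange[i]
        bestFit <- NULL
        for (r in seq_len(nReps)) {
            fit <- estimateAdmixture(
                Dl, K, seed = seed + 97L * K + 7919L * r,
                nRestarts = nRestarts, ...)
            ll[i, r] <- fit@loglik
            if (is.null(bestFit) || fit@loglik > bestFit@loglik)
                bestFit <- fit
        }
        fits[[as.character(K)]] <- bestFit
    }
    list(loglik = ll, fits = fits, Krange = Krange)
}
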