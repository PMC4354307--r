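#' @include admixture.R
NULL

#' Loiselle pairwise kinship from SSR dosages
#'
#' Computes the allele-frequency-correlation kinship estimator: with
#' individual allele frequencies `p_ila` (dosage over observed copies)
#' and panel mean frequencies `p.bar_la` over the `n_l` genotyped lines
#' at locus `l`,
#' \deqn{f_{ij} = \frac{\sum_l \sum_a (p_{ila}-\bar p_{la})
#'   (p_{jla}-\bar p_{la}) + \bar p_{la}(1-\bar p_{la})/(n_l-1)}
#'   {\sum_l \sum_a \bar p_{la}(1-\bar p_{la})}}
#' accumulated over the loci at which both lines are genotyped. The
#' small-sample correction divides by the number of genotyped
#' individuals (not gene copies). Negative estimates -- expected for
#' unrelated pairs -- are truncated at zero, and positive
#' semidefiniteness is restored by clipping negative eigenvalues at
#' zero, as required for use as a genetic covariance.
#'
#' @param x a [DosagePanel-class] (structure SSR loci), list of
#'   per-locus dosage matrices, or one lines-by-alleles matrix.
#' @param truncate truncate negative estimates at zero (the default;
#'   turning it off returns the raw estimator, mainly for tests).
#' @param repair restore PSD by eigenvalue clipping after truncation.
#' @return a [KinshipMatrix-class] (lines x lines).
#' @export
loiselleKinship <- function(x, truncate = TRUE, repair = truncate) {
    Dl <- structureDosageList(x)
    n <- nrow(Dl[[1]])
    lines <- rownames(Dl[[1]])
    if (n < 2L) stop("need at least 2 lines")
    num <- matrix(0, n, n)
    den <- matrix(0, n, n)
    for (D in Dl) {
        D <- as.matrix(D)
        tot <- rowSums(D)
        g <- !is.na(tot) & tot > 0
        P <- D / ifelse(tot > 0, tot, 1)
        P[!g, ] <- NA
        nl <- sum(g)
        if (nl < 2L) next
        pbar <- colMeans(P[g, , drop = FALSE])
        h <- sum(pbar * (1 - pbar))
        if (h <= 0) next                      # monomorphic locus
        C <- sweep(P, 2, pbar)
        C[!g, ] <- 0
        gg <- outer(g, g)
        num <- num + tcrossprod(C) + (h / (nl - 1)) * gg
        den <- den + h * gg
    }
    if (all(den == 0))
        stop("all loci monomorphic (or unshared): kinship undefined")
    f <- num / den
    f[den == 0] <- NA
    f <- (f + t(f)) / 2
    nTrunc <- 0L
    repaired <- FALSE
    if (truncate) {
        neg <- f < 0 & !is.na(f)
        nTrunc <- as.integer((sum(neg[upper.tri(neg)]) +
                              sum(diag(neg))))
        f[neg] <- 0
    }
    if (repair) {
        if (anyNA(f))
            stop("kinship has undefined pairs; cannot PSD-repair")
        ## alternating projections onto the PSD cone and the
        ## nonnegative orthant (both convex)
        for (it in 1:50) {
            e <- eigen(f, symmetric = TRUE)
            if (min(e$values) >= -1e-10) break
            repaired <- TRUE
            v <- pmax(e$values, 0)
            f <- e$vectors %*% (v * t(e$vectors))
            f <- (f + t(f)) / 2
            f[f < 0] <- 0
        }
    }
    dimnames(f) <- list(lines, lines)
    new("KinshipMatrix", f, truncated = truncate,
        nTruncated = nTrunc, repaired = repaired)
}
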