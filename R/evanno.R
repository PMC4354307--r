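#' @include admixture.R
NULL

#' Evanno delta-K table for choosing the number of subpopulations
#'
#' From replicated structure log-likelihoods over a contiguous K range,
#' computes the rate-of-change statistics: `L'(K)` (first difference),
#' `|L''(K)|` (absolute second difference, averaged over paired
#' replicates) and `deltaK = mean_reps |L(K+1) - 2 L(K) + L(K-1)| /
#' sd_reps L(K)`, which peaks where the log-likelihood slope changes
#' most relative to replicate noise. `deltaK` is defined only for
#' interior K; where the replicate standard deviation is zero it is
#' reported missing with a warning.
#'
#' @param loglik K-by-replicate matrix of log-likelihoods with rownames
#'   giving the K values (as from [admixtureScan()]`$loglik`), or the
#'   list returned by [admixtureScan()].
#' @return data.frame with columns `K`, `meanL`, `sdL`, `lprime`,
#'   `labs2` (mean |L''|), `deltaK`; the selected K (argmax deltaK) is
#'   attached as attribute `"bestK"`.
#' @examples
#' L <- rbind(`1` = c(-100, -101), `2` = c(-50, -51),
#'            `3` = c(-30, -29),  `4` = c(-28, -28.5))
#' evannoDeltaK(L)
#' @export
evannoDeltaK <- function(loglik) {
    if (is.list(loglik) && !is.null(loglik$loglik))
        loglik <- loglik$loglik
    L <- as.matrix(loglik)
    if (ncol(L) < 2L)
        stop("at least 2 replicates per K are required")
    Ks <- as.integer(rownames(L))
    if (any(is.na(Ks)) || any(diff(Ks) != 1L))
        stop("K values must be contiguous (rownames of the matrix)")
    nK <- length(Ks)
    meanL <- rowMeans(L)
    sdL <- apply(L, 1, sd)
    lprime <- c(NA, diff(meanL))
    labs2 <- rep(NA_real_, nK)
    deltaK <- rep(NA_real_, nK)
    if (nK >= 3L) {
        for (i in 2:(nK - 1L)) {
            sec <- abs(L[i + 1L, ] - 2 * L[i, ] + L[i - 1L, ])
            labs2[i] <- mean(sec)
            if (sdL[i] > 0) {
                deltaK[i] <- labs2[i] / sdL[i]
            } else {
                warning("replicate sd is zero at K = ", Ks[i],
                        "; deltaK undefined there")
            }
        }
    }
    out <- data.frame(K = Ks, meanL = meanL, sdL = sdL,
                      lprime = lprime, labs2 = labs2, deltaK = deltaK)
    rownames(out) <- NULL
    bestK <- if (all(is.na(deltaK))) NA_integer_
             else Ks[which.max(deltaK)]
    attr(out, "bestK") <- bestK
    out
}
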