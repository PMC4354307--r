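#' @include association.R
NULL

#' Storey q-values with bootstrap lambda selection
#'
#' Estimates the null proportion `pi0` from the p-value distribution,
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` on a lambda grid,
#' choosing lambda by the bootstrap: the lambda minimizing the
#' bootstrap mean squared error of `pi0(lambda)` around the minimum
#' observed `pi0` over the grid. Q-values follow the step-down rule
#' `q_(m) = pi0 p_(m)`, `q_(i) = min(pi0 m p_(i) / i, q_(i+1))`. With
#' `pi0 = 1` the q-values reduce to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p p-values in [0, 1] (pool all datasets before calling, so a
#'   single null proportion is estimated).
#' @param lambda grid of lambda values.
#' @param B bootstrap resamples for the lambda choice.
#' @param seed seed for the bootstrap.
#' @param pi0 optionally force the null proportion (e.g. 1) instead of
#'   estimating it.
#' @return list with `qvalues` (in input order), `pi0`, `lambda` (the
#'   selected value, `NA` if `pi0` was forced) and `pi0Lambda` (the
#'   grid estimates).
#' @examples
#' storeyQvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)$qvalues  # BH
#' @export
storeyQvalues <- function(p, lambda = seq(0, 0.90, by = 0.05),
                          B = 100L, seed = 1L, pi0 = NULL) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no NA")
    m <- length(p)
    if (m < 1L) stop("need at least one p-value")
    pi0Lambda <- NULL
    lamStar <- NA_real_
    if (is.null(pi0)) {
        if (m < 20L)
            warning("fewer than 20 p-values: pi0 estimation is unstable")
        pi0Lambda <- vapply(lambda, function(l)
            sum(p > l) / (m * (1 - l)), numeric(1))
        minPi0 <- min(pi0Lambda)
        set.seed(seed)
        mse <- numeric(length(lambda))
        for (b in seq_len(B)) {
            pb <- p[sample.int(m, m, replace = TRUE)]
            pi0b <- vapply(lambda, function(l)
                sum(pb > l) / (m * (1 - l)), numeric(1))
            mse <- mse + (pi0b - minPi0)^2
        }
        lamStar <- lambda[which.min(mse)]
        pi0 <- min(pi0Lambda[which.min(mse)], 1)
        pi0 <- max(pi0, 1 / m)   # keep pi0 in (0, 1]
    }
    o <- order(p, decreasing = TRUE)
    qv <- numeric(m)
    qv[o[1]] <- min(pi0 * p[o[1]], 1)
    if (m > 1L)
        for (i in 2:m)
            qv[o[i]] <- min(pi0 * m * p[o[i]] / (m - i + 1L),
                            qv[o[i - 1L]])
    list(qvalues = qv, pi0 = pi0, lambda = lamStar,
         pi0Lambda = pi0Lambda)
}

#' Expected false discoveries at a q-value threshold
#'
#' The q-value is the false discovery rate incurred when calling a test
#' significant, so among `n` discoveries at q-value `q` the expected
#' number of false positives is `q * n` (e.g. 13 discoveries at
#' q = 0.02 imply 0.26 expected false positives).
#'
#' @param q q-value at the significance threshold used.
#' @param nDiscoveries number of tests called significant.
#' @return expected number of false discoveries.
#' @export
expectedFalseDiscoveries <- function(q, nDiscoveries) {
    stopifnot(q >= 0, q <= 1, nDiscoveries >= 0)
    q * nDiscoveries
}

#' Significance summary of an association scan
#'
#' Counts records below fixed p-value thresholds with the matching
#' worst-case q-value and expected false discoveries, groups records by
#' gene, and extracts the dosage-class mean tables of the significant
#' records.
#'
#' @param records result of [associationScan()].
#' @param pThresholds p-value thresholds to summarize at.
#' @return list with `thresholds` (data.frame: threshold, n, max_q,
#'   expected_false), `byGene` (records per gene; counts sum to the
#'   total record count) and `classMeans` (marker, trait-year and the
#'   encoded dosage-class means for records below the largest
#'   threshold).
#' @export
significanceSummary <- function(records,
                                pThresholds = c(0.001, 0.01)) {
    thr <- do.call(rbind, lapply(pThresholds, function(t) {
        sel <- records$p < t
        data.frame(threshold = t, n = sum(sel),
                   max_q = if (any(sel)) max(records$q[sel]) else NA,
                   expected_false = if (any(sel))
                       expectedFalseDiscoveries(max(records$q[sel]),
                                                sum(sel)) else 0)
    }))
    gene <- ifelse(is.na(records$gene), "(none)", records$gene)
    byGene <- as.data.frame(table(gene), stringsAsFactors = FALSE)
    names(byGene) <- c("gene", "n_records")
    sel <- records$p < max(pThresholds)
    cm <- records[sel, c("marker_id", "allele", "trait", "year", "p",
                         "q", "class_means")]
    rownames(cm) <- NULL
    list(thresholds = thr, byGene = byGene, classMeans = cm)
}
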