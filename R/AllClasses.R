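#' @include tetraQK-package.R
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the synthetic tetraploid panel
#'
#' Holds every parameter of the synthetic-data generator: panel
#' dimensions, the candidate-marker table (with per-copy causal effects
#' in nmol/mg), admixture and allele-frequency hyperparameters, the
#' trait model (baselines per trait-year, polygenic variances, spatial
#' residual parameters) and the raw-signal noise model. Construct with
#' [simConfig()].
#'
#' @slot nLines number of test lines (the control line is added on top).
#' @slot includeControl add one control line (grown in 48 plots).
#' @slot ploidy fixed at 4.
#' @slot KTrue number of ancestral subpopulations.
#' @slot nStructureSsrs number of multi-allelic structure SSR loci.
#' @slot ssrAlleleRange inclusive range of allele counts per SSR locus.
#' @slot candidateMarkers data.frame of marker specs (see
#'   [defaultCandidateMarkers()]).
#' @slot admixtureConcentration Dirichlet concentration of the admixture
#'   proportions; small values give near-pure lines.
#' @slot fst Balding-Nichols-type divergence of subpopulation allele
#'   frequencies around the panel frequency.
#' @slot baseline named numeric, trait-year baseline means (nmol/mg).
#' @slot sigma2Poly named numeric, polygenic variance per trait.
#' @slot polyShare fraction of polygenic variance shared between traits.
#' @slot sigma2E,sigma2C,sigma2B named numerics per trait: residual,
#'   column-set and extraction-batch variances.
#' @slot rhoRow,rhoCol AR(1) residual correlations along rows/columns.
#' @slot signalNoise multiplicative (lognormal sdlog) noise on peak
#'   areas; trace fractions get additive Gaussian noise of sd
#'   `signalNoise / 4`.
#' @slot nullAlleleProb per line-by-SSR probability that one allele copy
#'   is a null (amplification failure).
#' @slot seed RNG seed; a fixed seed makes the generator bit-identical.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nLines = "integer",
    includeControl = "logical",
    ploidy = "integer",
    KTrue = "integer",
    nStructureSsrs = "integer",
    ssrAlleleRange = "integer",
    candidateMarkers = "data.frame",
    admixtureConcentration = "numeric",
    fst = "numeric",
    baseline = "numeric",
    sigma2Poly = "numeric",
    polyShare = "numeric",
    sigma2E = "numeric",
    sigma2C = "numeric",
    sigma2B = "numeric",
    rhoRow = "numeric",
    rhoCol = "numeric",
    signalNoise = "numeric",
    nullAlleleProb = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@ploidy != 4L)
        msg <- c(msg, "ploidy must be 4 (autotetraploid)")
    if (object@KTrue < 1L)
        msg <- c(msg, "KTrue must be >= 1")
    if (length(object@ssrAlleleRange) != 2L ||
        any(object@ssrAlleleRange < 2L))
        msg <- c(msg, "ssrAlleleRange must be two integers >= 2")
    if (any(c(object@sigma2Poly, object@sigma2E, object@sigma2C,
              object@sigma2B) < 0))
        msg <- c(msg, "all variances must be >= 0")
    if (abs(object@rhoRow) >= 1 || abs(object@rhoCol) >= 1)
        msg <- c(msg, "|rhoRow| and |rhoCol| must be < 1")
    if (object@polyShare < 0 || object@polyShare > 1)
        msg <- c(msg, "polyShare must lie in [0, 1]")
    if (object@nullAlleleProb < 0 || object@nullAlleleProb > 1)
        msg <- c(msg, "nullAlleleProb must lie in [0, 1]")
    cm <- object@candidateMarkers
    need <- c("marker_id", "type", "n_alleles", "freq",
              "effect_C6", "effect_C3", "gene")
    if (!all(need %in% names(cm)))
        msg <- c(msg, paste("candidateMarkers must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(cm$marker_id))
            msg <- c(msg, "duplicate candidate marker ids")
        if (!all(cm$type %in% c("SNP", "SSR", "InDel")))
            msg <- c(msg, "marker type must be SNP, SSR or InDel")
        if (any(cm$type != "SSR" & cm$n_alleles != 2L))
            msg <- c(msg, "SNP/InDel markers must be biallelic")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TruePanel: generator ground truth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated panel
#'
#' The generator's internal truth: admixture proportions, subpopulation
#' allele frequencies, true allele dosages and genetic values. Used as
#' the oracle in recovery tests; downstream stages see only the raw
#' signal tables derived from it.
#'
#' @slot lineIds character vector of line names.
#' @slot isControl logical flag per line.
#' @slot Q lines-by-KTrue admixture proportions (rows sum to 1).
#' @slot markerInfo data.frame describing every locus (structure SSRs
#'   and candidate markers).
#' @slot freqs named list: per locus, a KTrue-by-alleles frequency
#'   matrix (rows on the simplex).
#' @slot dosages named list: per locus, a lines-by-alleles integer
#'   dosage matrix; rows sum to 4 minus the null count.
#' @slot nullCopies named list: per SSR locus, integer vector of null
#'   copies per line (0 or 1).
#' @slot geneticValues lines-by-2 matrix (C6, C3), genetic deviations
#'   from the trait baseline in nmol/mg (filled by
#'   [simulateCausalArchitecture()]).
#' @slot config the originating [SimConfig-class].
#' @exportClass TruePanel
setClass("TruePanel", representation(
    lineIds = "character",
    isControl = "logical",
    Q = "matrix",
    markerInfo = "data.frame",
    freqs = "list",
    dosages = "list",
    nullCopies = "list",
    geneticValues = "matrix",
    config = "SimConfig"
))

setValidity("TruePanel", function(object) {
    msg <- character()
    if (nrow(object@Q) != length(object@lineIds))
        msg <- c(msg, "Q must have one row per line")
    if (any(abs(rowSums(object@Q) - 1) > 1e-8))
        msg <- c(msg, "Q rows must sum to 1")
    pl <- object@config@ploidy
    for (m in names(object@dosages)) {
        tot <- rowSums(object@dosages[[m]])
        nc <- if (m %in% names(object@nullCopies))
            object@nullCopies[[m]] else 0L
        if (any(tot + nc != pl)) {
            msg <- c(msg, sprintf("dosages at %s do not sum to ploidy", m))
            break
        }
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DosagePanel: called dosages as a SummarizedExperiment
## ---------------------------------------------------------------------------

#' Called allele dosages for a panel of tetraploid lines
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"dosage"` holds copy numbers (0-4, `NA` = missing) with one row per
#' tested marker allele (biallelic SNPs and InDels contribute one row,
#' an SSR one row per allele) and one column per line. `rowData` carries
#' `marker_id`, `allele`, `type`, `role` (structure or candidate),
#' `gene`, `chrom` and `pos`; `metadata()` carries per-call flags.
#'
#' @exportClass DosagePanel
setClass("DosagePanel", contains = "SummarizedExperiment")

setValidity("DosagePanel", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        if (any(d[!is.na(d)] < 0 | d[!is.na(d)] > 4))
            msg <- c(msg, "dosages must lie in 0..4")
    }
    need <- c("marker_id", "allele", "type", "role")
    if (!all(need %in% names(SummarizedExperiment::rowData(object))))
        msg <- c(msg, paste("rowData must contain",
                            paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FieldTrial
## ---------------------------------------------------------------------------

#' A replicated field trial on a 72 x 6 plot grid
#'
#' Plot-level layout and phenotypes for one trial: 432 plots in 72 rows
#' and 6 columns, two replicate plots per test line plus 48 control
#' plots, with column-set and extraction-batch labels derived from the
#' processing order (plots processed down each column; starch extracted
#' in batches of 36, phosphorylation measured in batches of 72).
#'
#' @slot plots data.frame with columns `plot_order`, `row`, `col`,
#'   `line_id`, `is_control`, `colset_id`, `batch36_id`, `batch72_id`.
#' @slot phenotypes data.frame with columns `plot_order`, `trait`,
#'   `year`, `value` (nmol/mg); may have zero rows before phenotyping.
#' @exportClass FieldTrial
setClass("FieldTrial", representation(
    plots = "data.frame",
    phenotypes = "data.frame"
))

setValidity("FieldTrial", function(object) {
    v <- validateLayout(object)
    if (length(v)) paste(v, collapse = "; ") else TRUE
})

## ---------------------------------------------------------------------------
## SpatialFit
## ---------------------------------------------------------------------------

#' REML fit of the spatial phenotype-adjustment model
#'
#' Result of [fitSpatialReml()]: variance components, AR(1)
#' correlations, generalized-least-squares line means with standard
#' errors, the REML log-likelihood and the overall line F-test.
#'
#' @slot trait,year the trait-year dataset fitted.
#' @slot varComponents named numeric: `sigma2_e`, `sigma2_c`, `sigma2_b`.
#' @slot rho named numeric: `rho_row`, `rho_col`.
#' @slot lineMeans named numeric, adjusted mean per line (nmol/mg).
#' @slot lineSE standard errors of the adjusted means.
#' @slot loglik REML log-likelihood at the optimum.
#' @slot fTest named numeric: `F`, `df1`, `df2`, `p`.
#' @slot converged,boundary optimizer status flags.
#' @slot nObs number of non-missing plots used.
#' @exportClass SpatialFit
setClass("SpatialFit", representation(
    trait = "character",
    year = "character",
    varComponents = "numeric",
    rho = "numeric",
    lineMeans = "numeric",
    lineSE = "numeric",
    loglik = "numeric",
    fTest = "numeric",
    converged = "logical",
    boundary = "logical",
    nObs = "integer"
))

setValidity("SpatialFit", function(object) {
    msg <- character()
    if (any(object@varComponents < 0))
        msg <- c(msg, "variance components must be >= 0")
    if (any(abs(object@rho) >= 1))
        msg <- c(msg, "|rho| must be < 1")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## AdmixtureFit
## ---------------------------------------------------------------------------

#' EM admixture model fit
#'
#' Membership proportions (the Q matrix) estimated by maximizing the
#' admixture likelihood with expectation-maximization, treating each of
#' the four allele copies at a locus as an independent draw from the
#' line's ancestry-weighted allele-frequency mixture.
#'
#' @slot Q lines-by-K matrix of membership proportions, rows sum to 1.
#' @slot freqs per-locus list of K-by-alleles frequency matrices.
#' @slot K number of subpopulations.
#' @slot loglik final log-likelihood.
#' @slot converged TRUE if the EM tolerance was reached.
#' @slot nIter iterations used by the best restart.
#' @slot trace per-iteration log-likelihood of the best restart
#'   (nondecreasing by construction of EM).
#' @exportClass AdmixtureFit
setClass("AdmixtureFit", representation(
    Q = "matrix",
    freqs = "list",
    K = "integer",
    loglik = "numeric",
    converged = "logical",
    nIter = "integer",
    trace = "numeric"
))

setValidity("AdmixtureFit", function(object) {
    msg <- character()
    if (ncol(object@Q) != object@K)
        msg <- c(msg, "Q must have K columns")
    if (any(object@Q < -1e-12 | object@Q > 1 + 1e-12))
        msg <- c(msg, "Q entries must lie in [0, 1]")
    if (any(abs(rowSums(object@Q) - 1) > 1e-8))
        msg <- c(msg, "Q rows must sum to 1")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## KinshipMatrix
## ---------------------------------------------------------------------------

#' Pairwise kinship matrix
#'
#' A symmetric lines-by-lines matrix of Loiselle kinship coefficients,
#' with negative estimates truncated at zero and positive
#' semidefiniteness restored by eigenvalue clipping.
#'
#' @slot truncated TRUE once negative estimates have been set to zero;
#'   the raw (diagnostic) estimator leaves it FALSE.
#' @slot nTruncated number of entries (upper triangle plus diagonal)
#'   that were negative before truncation.
#' @slot repaired TRUE if eigenvalue clipping changed the matrix.
#' @exportClass KinshipMatrix
setClass("KinshipMatrix", contains = "matrix",
         representation(truncated = "logical", nTruncated = "integer",
                        repaired = "logical"))

setValidity("KinshipMatrix", function(object) {
    msg <- character()
    m <- object@.Data
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
        msg <- c(msg, "kinship must be symmetric")
    if (isTRUE(object@truncated) && min(m) < -1e-8)
        msg <- c(msg, "entries must be >= 0 after truncation")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
    cm <- object@candidateMarkers
    cat("SimConfig:", object@nLines, "test lines",
        if (object@includeControl) "+ 1 control" else "",
        "| ploidy", object@ploidy, "\n")
    cat("  structure SSRs:", object@nStructureSsrs,
        sprintf("(%d-%d alleles), K_true = %d\n",
                object@ssrAlleleRange[1], object@ssrAlleleRange[2],
                object@KTrue))
    cat("  candidate markers:", nrow(cm),
        sprintf("(%d SNP, %d SSR, %d InDel); causal: %d\n",
                sum(cm$type == "SNP"), sum(cm$type == "SSR"),
                sum(cm$type == "InDel"),
                sum(cm$effect_C6 != 0 | cm$effect_C3 != 0)))
    cat(sprintf("  spatial: rho = (%.2f, %.2f); seed = %d\n",
                object@rhoRow, object@rhoCol, object@seed))
})

setMethod("show", "TruePanel", function(object) {
    cat("TruePanel:", length(object@lineIds), "lines x",
        nrow(object@markerInfo), "loci; K_true =", ncol(object@Q), "\n")
    cat("  genetic values:",
        if (nrow(object@geneticValues)) "filled" else "not yet drawn",
        "\n")
})

setMethod("show", "FieldTrial", function(object) {
    cat("FieldTrial:", nrow(object@plots), "plots in",
        max(object@plots$row), "rows x", max(object@plots$col),
        "columns;", sum(object@plots$is_control), "control plots\n")
    if (nrow(object@phenotypes))
        cat("  phenotypes:",
            paste(unique(paste(object@phenotypes$trait,
                               object@phenotypes$year)), collapse = ", "),
            "\n")
})

setMethod("show", "SpatialFit", function(object) {
    cat(sprintf("SpatialFit [%s %s]: REML logLik = %.3f (%s)\n",
                object@trait, object@year, object@loglik,
                if (object@converged) "converged" else "NOT converged"))
    cat(sprintf("  sigma2_e = %.3f, sigma2_c = %.3f, sigma2_b = %.3f\n",
                object@varComponents["sigma2_e"],
                object@varComponents["sigma2_c"],
                object@varComponents["sigma2_b"]))
    cat(sprintf("  rho_row = %.3f, rho_col = %.3f\n",
                object@rho["rho_row"], object@rho["rho_col"]))
    cat(sprintf("  line F(%d, %d) = %.2f, p = %.3g\n",
                as.integer(object@fTest["df1"]),
                as.integer(object@fTest["df2"]),
                object@fTest["F"], object@fTest["p"]))
})

setMethod("show", "AdmixtureFit", function(object) {
    cat(sprintf("AdmixtureFit: K = %d, logLik = %.3f, %s (%d iter)\n",
                object@K, object@loglik,
                if (object@converged) "converged" else "not converged",
                object@nIter))
})

setMethod("show", "KinshipMatrix", function(object) {
    cat(sprintf(
        "KinshipMatrix: %d x %d%s%s\n",
        nrow(object@.Data), ncol(object@.Data),
        if (isTRUE(object@truncated))
            sprintf(", %d negative entries truncated", object@nTruncated)
        else " (raw estimator)",
        if (object@repaired) ", PSD-repaired" else ""))
})
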