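#' @include AllClasses.R
NULL

#' Default candidate-marker table
#'
#' The default candidate set emulates a starch-pathway candidate-gene
#' panel: 104 biallelic SNPs spread over seven genes, four multi-allelic
#' SSRs (11, 11, 12 and 5 alleles) and one biallelic InDel, i.e. 144
#' tested marker columns once each SSR allele is counted as its own
#' test. Three SNPs carry causal per-copy effects by default: a GWD SNP
#' acting on C6 phosphorylation (1.42 nmol/mg per copy), an SBEI SNP
#' acting on both traits (1.24 and 0.21) and an SSIII SNP acting on C3
#' (0.32), with intermediate allele frequencies.
#'
#' @return data.frame with columns `marker_id`, `type`, `n_alleles`,
#'   `freq` (alternate/defining allele frequency; `NA` for multi-allelic
#'   SSRs whose frequencies are drawn at simulation time), `effect_C6`,
#'   `effect_C3` (nmol/mg per copy), `gene`, `chrom`, `pos`.
#' @examples
#' cm <- defaultCandidateMarkers()
#' sum(ifelse(cm$type == "SSR", cm$n_alleles, 1L))  # 144 tested columns
#' @export
defaultCandidateMarkers <- function() {
    snpPerGene <- c(ssi = 5L, ssii = 17L, ssiii = 14L, sbei = 8L,
                    sbeii = 12L, gwd = 32L, pwd = 16L)
    baseCycle <- list(c("C", "T"), c("G", "T"), c("G", "A"),
                      c("A", "G"), c("A", "C"), c("C", "G"))
    freqCycle <- c(0.10, 0.22, 0.31, 0.40, 0.06, 0.26,
                   0.45, 0.15, 0.36, 0.48, 0.19, 0.08)
    rows <- list()
    j <- 0L
    for (g in names(snpPerGene)) {
        for (i in seq_len(snpPerGene[[g]])) {
            j <- j + 1L
            b <- baseCycle[[(j - 1L) %% length(baseCycle) + 1L]]
            rows[[length(rows) + 1L]] <- data.frame(
                marker_id = sprintf("%s_snp%02d", g, i),
                type = "SNP", n_alleles = 2L,
                freq = freqCycle[(j - 1L) %% length(freqCycle) + 1L],
                effect_C6 = 0, effect_C3 = 0, gene = g,
                ref = b[1], alt = b[2],
                stringsAsFactors = FALSE)
        }
    }
    cm <- do.call(rbind, rows)
    ## causal SNPs emulating strong starch-phosphorylation associations;
    ## the defining (alt) allele is the one raising phosphorylation
    cm[cm$marker_id == "gwd_snp01",
       c("freq", "effect_C6", "ref", "alt")] <-
        list(0.42, 1.42, "C", "T")
    cm[cm$marker_id == "sbei_snp02",
       c("freq", "effect_C6", "effect_C3", "ref", "alt")] <-
        list(0.475, 1.24, 0.21, "G", "A")
    cm[cm$marker_id == "ssiii_snp07",
       c("freq", "effect_C3", "ref", "alt")] <-
        list(0.27, 0.32, "C", "T")
    ssr <- data.frame(
        marker_id = c("gbss_ssr1", "gbss_ssr2", "sbeii_ssr", "gwd_ssr"),
        type = "SSR", n_alleles = c(11L, 11L, 12L, 5L),
        freq = NA_real_, effect_C6 = 0, effect_C3 = 0,
        gene = c("gbss", "gbss", "sbeii", "gwd"),
        ref = NA_character_, alt = NA_character_,
        stringsAsFactors = FALSE)
    indel <- data.frame(
        marker_id = "gbss_indel", type = "InDel", n_alleles = 2L,
        freq = 0.30, effect_C6 = 0, effect_C3 = 0, gene = "gbss",
        ref = "60", alt = "200", stringsAsFactors = FALSE)
    cm <- rbind(cm, ssr, indel)
    genes <- unique(cm$gene)
    cm$chrom <- paste0("chr", sprintf("%02d", match(cm$gene, genes)))
    cm$pos <- as.integer(10000L + 250L *
        ave(seq_len(nrow(cm)), cm$gene, FUN = seq_along))
    rownames(cm) <- NULL
    cm
}

#' Build a simulation configuration
#'
#' Assembles and validates a [SimConfig-class]. Defaults emulate the
#' study panel: 192 tetraploid test lines plus one control, 21 structure
#' SSRs with 3-17 alleles each, the 144-column candidate set of
#' [defaultCandidateMarkers()], four trait-year datasets (C6 and C3
#' phosphorylation in two seasons with season-specific baselines) and a
#' 72 x 6 field-trial error model with AR(1) x AR(1) spatial
#' correlation.
#'
#' @param nLines number of test lines.
#' @param includeControl add a control line (planted in 48 plots).
#' @param KTrue number of ancestral subpopulations.
#' @param nStructureSsrs number of structure SSR loci.
#' @param ssrAlleleRange length-2 integer range of alleles per SSR.
#' @param candidateMarkers candidate marker table; see
#'   [defaultCandidateMarkers()].
#' @param admixtureConcentration Dirichlet concentration for admixture
#'   rows.
#' @param fst divergence of subpopulation allele frequencies.
#' @param baseline named trait-year baseline means, nmol/mg.
#' @param sigma2Poly named per-trait polygenic variances.
#' @param polyShare fraction of polygenic variance shared between C6 and
#'   C3.
#' @param sigma2E,sigma2C,sigma2B named per-trait residual, column-set
#'   and extraction-batch variances.
#' @param rhoRow,rhoCol AR(1) correlations along field rows and columns.
#' @param signalNoise raw-signal noise scale (lognormal sdlog on areas;
#'   Gaussian sd `signalNoise/4` on trace fractions).
#' @param nullAlleleProb probability that an SSR genotype hides one
#'   allele copy behind a null.
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(nLines = 192L,
                      includeControl = TRUE,
                      KTrue = 4L,
                      nStructureSsrs = 21L,
                      ssrAlleleRange = c(3L, 17L),
                      candidateMarkers = defaultCandidateMarkers(),
                      admixtureConcentration = 0.5,
                      fst = 0.1,
                      baseline = c(C6_2011 = 15.8, C6_2012 = 23.0,
                                   C3_2011 = 4.7, C3_2012 = 4.9),
                      sigma2Poly = c(C6 = 16, C3 = 1.0),
                      polyShare = 0.7,
                      sigma2E = c(C6 = 4, C3 = 0.25),
                      sigma2C = c(C6 = 1, C3 = 0.0625),
                      sigma2B = c(C6 = 1, C3 = 0.0625),
                      rhoRow = 0.6,
                      rhoCol = 0.4,
                      signalNoise = 0.1,
                      nullAlleleProb = 0.02,
                      seed = 20110301L) {
    for (col in c("ref", "alt", "chrom", "pos")) {
        if (is.null(candidateMarkers[[col]]))
            candidateMarkers[[col]] <- if (col == "pos") NA_integer_
                                       else NA_character_
    }
    rownames(candidateMarkers) <- NULL
    new("SimConfig",
        nLines = as.integer(nLines),
        includeControl = isTRUE(includeControl),
        ploidy = 4L,
        KTrue = as.integer(KTrue),
        nStructureSsrs = as.integer(nStructureSsrs),
        ssrAlleleRange = as.integer(ssrAlleleRange),
        candidateMarkers = candidateMarkers,
        admixtureConcentration = admixtureConcentration,
        fst = fst,
        baseline = baseline,
        sigma2Poly = sigma2Poly,
        polyShare = polyShare,
        sigma2E = sigma2E,
        sigma2C = sigma2C,
        sigma2B = sigma2B,
        rhoRow = rhoRow,
        rhoCol = rhoCol,
        signalNoise = signalNoise,
        nullAlleleProb = nullAlleleProb,
        seed = as.integer(seed))
}

#' Expected genetic (co)variance implied by a configuration
#'
#' Computes, from the generating model alone, the expected variance of
#' the genetic values of each trait and their cross-trait correlation:
#' causal markers contribute `4 p (1 - p) beta^2` per trait (binomial
#' dosage approximation at the panel frequency) and the polygenic term
#' contributes its full variance, of which `polyShare` is common to the
#' two traits. Used as the independent oracle when checking that
#' simulated C6 and C3 genetic values are correlated.
#'
#' @param config a [SimConfig-class].
#' @return list with `var` (named per trait), `cov` and `cor`.
#' @export
geneticCovariance <- function(config) {
    cm <- config@candidateMarkers
    causal <- cm[(cm$effect_C6 != 0 | cm$effect_C3 != 0) &
                 !is.na(cm$freq), , drop = FALSE]
    vd <- 4 * causal$freq * (1 - causal$freq)
    v6 <- sum(vd * causal$effect_C6^2) + config@sigma2Poly[["C6"]]
    v3 <- sum(vd * causal$effect_C3^2) + config@sigma2Poly[["C3"]]
    cv <- sum(vd * causal$effect_C6 * causal$effect_C3) +
        config@polyShare * sqrt(config@sigma2Poly[["C6"]] *
                                config@sigma2Poly[["C3"]])
    list(var = c(C6 = v6, C3 = v3), cov = unname(cv),
         cor = unname(cv / sqrt(v6 * v3)))
}

## Dirichlet draws via gamma normalization; alpha recycled over k.
rdirichlet <- function(n, alpha) {
    k <- length(alpha)
    x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
    sweep(x, 1, rowSums(x), "/")
}
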