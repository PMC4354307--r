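## Shared fixtures: small configurations and direct constructions used
## across the test files. Everything is generated in code at test time.

## A reduced candidate set: 1 causal SNP, 2 neutral SNPs, 1 SSR, 1 InDel
smallMarkers <- function() {
    cm <- defaultCandidateMarkers()
    cm[cm$marker_id %in% c("gwd_snp01", "ssi_snp01", "pwd_snp02",
                           "sbeii_ssr", "gbss_indel"), ]
}

## Small panel: 48 test lines + control fits an 18 x 6 grid with 12
## controls (2 * 48 + 12 = 108)
smallConfig <- function(seed = 1L, ...) {
    args <- list(nLines = 48L, KTrue = 3L, nStructureSsrs = 10L,
                 candidateMarkers = smallMarkers(), seed = seed)
    do.call(simConfig, utils::modifyList(args, list(...)))
}

smallLayout <- function() list(nRows = 18L, nCols = 6L, nControls = 12L)

## Well-separated subpopulations for structure-recovery checks:
## near-pure admixture rows and strongly diverged SSR frequencies.
separatedConfig <- function(seed = 1L, nLines = 60L, KTrue = 3L,
                            nSsrs = 12L) {
    simConfig(nLines = nLines, includeControl = FALSE, KTrue = KTrue,
              nStructureSsrs = nSsrs, ssrAlleleRange = c(4L, 8L),
              candidateMarkers = smallMarkers(),
              admixtureConcentration = 0.05, fst = 0.35, seed = seed)
}

## Direct dosage matrix (lines x alleles) with optional missing rows
makeLocus <- function(dosages, lines = NULL, alleles = NULL) {
    D <- as.matrix(dosages)
    if (is.null(lines)) lines <- sprintf("L%02d", seq_len(nrow(D)))
    if (is.null(alleles)) alleles <- paste0("a", seq_len(ncol(D)))
    dimnames(D) <- list(lines, alleles)
    D
}
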