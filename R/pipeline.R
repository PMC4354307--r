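#' @include simulate.R vcf.R qvalue.R evanno.R
NULL

#' Run the full analysis pipeline
#'
#' Executes the stages end to end on synthetic data: simulate the panel
#' and trials, call dosages from the raw signals, fit the spatial REML
#' adjustment for each trait-year, estimate structure (admixture over a
#' K range with Evanno delta-K selection) and Loiselle kinship from the
#' called structure-SSR dosages, run the Q+K association scan with
#' pooled Storey q-values, and write the significance summary. Every
#' artifact is written as TSV (plus a dosage VCF for the SNPs) under
#' `outDir`, together with a JSON manifest recording the stage, seed
#' and md5 of every file, so silent input changes are detectable.
#'
#' @param config a [SimConfig-class]; `seed` overrides its seed.
#' @param outDir output directory (created if needed).
#' @param seed master seed for every stochastic stage.
#' @param layout field-layout dimensions, see [simulateStudy()].
#' @param Krange,nReps structure scan settings.
#' @param nStarts REML optimizer starts per trait-year.
#' @param exact exact per-marker variance refits in the scan.
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory objects (`panel`,
#'   `dosagePanel`, `fits`, `means`, `structure`, `evanno`, `kinship`,
#'   `records`, `summary`) and `files` (the manifest).
#' @export
runPipeline <- function(config = simConfig(), outDir = tempfile("qk"),
                        seed = config@seed,
                        layout = list(nRows = 72L, nCols = 6L,
                                      nControls = 48L),
                        Krange = 1:5, nReps = 3L,
                        nStarts = 2L, exact = FALSE, verbose = TRUE) {
    t0 <- Sys.time()
    say <- function(...) if (verbose)
        message(sprintf("[%5.1fs] ",
                        as.numeric(difftime(Sys.time(), t0,
                                            units = "secs"))), ...)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outDir, f)
    config@seed <- as.integer(seed)
    manifest <- list()
    note <- function(stage, files) {
        manifest[[stage]] <<- list(
            stage = stage, seed = as.integer(seed),
            files = lapply(setNames(files, basename(files)), function(f)
                unname(tools::md5sum(f))))
    }

    say("simulate: panel, signals, field trials")
    writeConfigYaml(config, fp("config.yaml"))
    sim <- simulateStudy(config, layout = layout)
    writePeakTable(sim$signals$peaks, fp("peaks.tsv"))
    writeTraceTable(sim$signals$traces, fp("traces.tsv"))
    writeBandTable(sim$signals$bands, fp("bands.tsv"))
    writeLayout(sim$trial, fp("layout.tsv"))
    writePhenotypes(sim$trial, fp("phenotypes.tsv"))
    note("simulate", fp(c("config.yaml", "peaks.tsv", "traces.tsv",
                          "bands.tsv", "layout.tsv", "phenotypes.tsv")))

    say("call-dosage: ", nrow(sim$panel@markerInfo), " loci")
    dp <- callDosages(sim$signals, sim$panel@markerInfo,
                      lineIds = sim$panel@lineIds)
    writeDosageTable(dp, fp("dosages.tsv"))
    writeDosageVcf(dp[rowData(dp)$type == "SNP", ],
                   fp("snp_dosages.vcf"))
    note("call-dosage", fp(c("dosages.tsv", "snp_dosages.vcf")))

    say("adjust: spatial REML per trait-year")
    datasets <- unique(sim$trial@phenotypes[, c("trait", "year")])
    fits <- list()
    for (i in seq_len(nrow(datasets))) {
        key <- paste(datasets$trait[i], datasets$year[i], sep = "_")
        fits[[key]] <- fitSpatialReml(sim$trial, datasets$trait[i],
                                      datasets$year[i],
                                      nStarts = nStarts,
                                      seed = seed + i)
        say("  ", key, ": logLik ", round(fits[[key]]@loglik, 2))
    }
    means <- adjustedLineMeans(fits)
    writeAdjustedMeans(means, fp("adjusted_means.tsv"))
    note("adjust", fp("adjusted_means.tsv"))

    say("structure: admixture K = ", min(Krange), "..", max(Krange))
    scan <- admixtureScan(dp, Krange = Krange, nReps = nReps,
                          seed = seed)
    ev <- evannoDeltaK(scan$loglik)
    bestK <- attr(ev, "bestK")
    if (is.na(bestK)) bestK <- Krange[which.max(rowMeans(scan$loglik))]
    qfit <- scan$fits[[as.character(bestK)]]
    writeQMatrix(qfit, fp("q_matrix.tsv"))
    writeEvannoTable(ev, fp("evanno.tsv"))
    note("structure", fp(c("q_matrix.tsv", "evanno.tsv")))

    say("kinship: Loiselle estimator")
    kin <- loiselleKinship(dp)
    writeKinship(kin, fp("kinship.tsv"))
    note("kinship", fp("kinship.tsv"))

    say("scan: Q+K association, ", nrow(datasets), " datasets")
    records <- associationScan(means, dp, Q = qfit, kin = kin,
                               exact = exact,
                               qvalueArgs = list(seed = seed))
    writeAssociationTable(records, fp("association.tsv"))
    note("scan", fp("association.tsv"))

    say("report: significance summary")
    sm <- significanceSummary(records)
    writeTsv(sm$thresholds, fp("significance_summary.tsv"))
    note("report", fp("significance_summary.tsv"))

    jsonlite::write_json(manifest, fp("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("done: ", length(unlist(lapply(manifest, `[[`, "files"))),
        " artifacts in ", outDir)
    invisible(list(panel = sim$panel, trial = sim$trial,
                   dosagePanel = dp, fits = fits, means = means,
                   structure = scan, evanno = ev, bestK = bestK,
                   kinship = kin, records = records, summary = sm,
                   outDir = outDir, files = manifest))
}
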