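#' @include dosage-calling.R
NULL

writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

readTsv <- function(path, required, what = "table") {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     check.names = FALSE)
    miss <- setdiff(required, names(df))
    if (length(miss))
        stop("unknown ", what, " schema in ", path, ": missing column",
             if (length(miss) > 1) "s", " ",
             paste(miss, collapse = ", "))
    df
}

#' Read and write pipeline tables
#'
#' Plain TSV serialization for every pipeline artifact. Each writer
#' emits a header line; each reader validates the expected columns and
#' rejects unknown schemas.
#'
#' @param x the table (or object) to write.
#' @param path file path.
#' @return readers return the table (or object); writers return the
#'   path invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writePeakTable <- function(x, path) writeTsv(x, path)

#' @rdname pipeline-io
#' @export
readPeakTable <- function(path)
    readTsv(path, c("sample_id", "marker_id", "allele", "area"),
            "peak table")

#' @rdname pipeline-io
#' @export
writeTraceTable <- function(x, path) writeTsv(x, path)

#' @rdname pipeline-io
#' @export
readTraceTable <- function(path)
    readTsv(path, c("sample_id", "marker_id", "strand", "alt_fraction",
                    "quality"), "trace table")

#' @rdname pipeline-io
#' @export
writeBandTable <- function(x, path) writeTsv(x, path)

#' @rdname pipeline-io
#' @export
readBandTable <- function(path)
    readTsv(path, c("sample_id", "marker_id", "allele", "intensity"),
            "band table")

#' @rdname pipeline-io
#' @export
writeLayout <- function(x, path) {
    pl <- if (is(x, "FieldTrial")) x@plots else x
    writeTsv(pl, path)
}

#' @rdname pipeline-io
#' @export
readLayout <- function(path) {
    pl <- readTsv(path, c("plot_order", "row", "col", "line_id",
                          "is_control", "colset_id", "batch36_id",
                          "batch72_id"), "layout")
    new("FieldTrial", plots = pl,
        phenotypes = data.frame(plot_order = integer(),
                                trait = character(),
                                year = character(), value = numeric()))
}

#' @rdname pipeline-io
#' @export
writePhenotypes <- function(x, path) {
    ph <- if (is(x, "FieldTrial")) x@phenotypes else x
    writeTsv(ph, path)
}

#' @rdname pipeline-io
#' @param trial a [FieldTrial-class] to attach the phenotypes to.
#' @export
readPhenotypes <- function(path, trial = NULL) {
    ph <- readTsv(path, c("plot_order", "trait", "year", "value"),
                  "phenotype table")
    ph$year <- as.character(ph$year)
    if (is.null(trial)) return(ph)
    trial@phenotypes <- ph
    trial
}

#' @rdname pipeline-io
#' @export
writeDosageTable <- function(x, path) {
    stopifnot(is(x, "DosagePanel"))
    rd <- as.data.frame(rowData(x))
    writeTsv(cbind(rd, as.data.frame(assay(x, "dosage"),
                                     check.names = FALSE)), path)
}

#' @rdname pipeline-io
#' @export
readDosageTable <- function(path) {
    meta <- c("marker_id", "allele", "type", "role", "gene", "chrom",
              "pos", "ref")
    df <- readTsv(path, meta, "dosage matrix")
    lines <- setdiff(names(df), meta)
    mat <- as.matrix(df[, lines, drop = FALSE])
    mode(mat) <- "integer"
    rd <- df[, meta, drop = FALSE]
    rd$allele <- as.character(rd$allele)
    rd$ref <- as.character(rd$ref)
    rownames(mat) <- ifelse(rd$type == "SSR",
                            paste(rd$marker_id, rd$allele, sep = "."),
                            rd$marker_id)
    dp <- SummarizedExperiment(
        assays = list(dosage = mat),
        rowData = DataFrame(rd, row.names = rownames(mat)),
        colData = DataFrame(line_id = lines, row.names = lines))
    new("DosagePanel", dp)
}

#' @rdname pipeline-io
#' @export
writeAdjustedMeans <- function(x, path) writeTsv(x, path)

#' @rdname pipeline-io
#' @export
readAdjustedMeans <- function(path) {
    df <- readTsv(path, c("line_id", "trait", "year", "mean"),
                  "adjusted means")
    df$year <- as.character(df$year)
    df
}

#' @rdname pipeline-io
#' @export
writeQMatrix <- function(x, path) {
    Q <- if (is(x, "AdmixtureFit")) qMatrix(x) else as.matrix(x)
    df <- data.frame(line_id = rownames(Q), Q, check.names = FALSE)
    names(df)[-1] <- paste0("q", seq_len(ncol(Q)))
    writeTsv(df, path)
}

#' Import an externally computed Q matrix
#'
#' Reads a membership-proportion table (e.g. exported from an external
#' structure run) with columns `line_id, q1..qK`. Rows whose sum is
#' within `1e-3` of 1 are renormalized; rows further off are an error,
#' as are unknown or missing line ids. Rows are aligned to `lineIds`
#' when given.
#'
#' @param path TSV path.
#' @param lineIds optional line ids the rows must cover (in this order).
#' @return an [AdmixtureFit-class] (loglik `NA`, converged `NA`).
#' @export
importExternalQ <- function(path, lineIds = NULL) {
    df <- readTsv(path, "line_id", "Q matrix")
    qcols <- grep("^q[0-9]+$", names(df), value = TRUE)
    if (!length(qcols)) stop("unknown Q matrix schema: no q columns")
    Q <- as.matrix(df[, qcols, drop = FALSE])
    rownames(Q) <- df$line_id
    rs <- rowSums(Q)
    bad <- abs(rs - 1) > 1e-3
    if (any(bad))
        stop("Q rows not on the simplex for: ",
             paste(head(df$line_id[bad], 5), collapse = ", "))
    Q <- Q / rs
    if (!is.null(lineIds)) {
        unknown <- setdiff(df$line_id, lineIds)
        if (length(unknown))
            stop("unknown line ids in Q: ",
                 paste(head(unknown, 5), collapse = ", "))
        miss <- setdiff(lineIds, df$line_id)
        if (length(miss))
            stop("lines missing from Q: ",
                 paste(head(miss, 5), collapse = ", "))
        Q <- Q[lineIds, , drop = FALSE]
    }
    new("AdmixtureFit", Q = Q, freqs = list(),
        K = ncol(Q), loglik = NA_real_, converged = NA,
        nIter = 0L, trace = numeric(0))
}

#' @rdname pipeline-io
#' @export
writeKinship <- function(x, path) {
    m <- if (is(x, "KinshipMatrix")) x@.Data else as.matrix(x)
    writeTsv(data.frame(line_id = rownames(m), m, check.names = FALSE),
             path)
}

#' @rdname pipeline-io
#' @export
readKinship <- function(path) {
    df <- readTsv(path, "line_id", "kinship matrix")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$line_id
    if (nrow(m) != ncol(m))
        stop("kinship table is not square")
    colnames(m) <- rownames(m)
    m <- (m + t(m)) / 2
    new("KinshipMatrix", m, truncated = all(m >= 0),
        nTruncated = NA_integer_, repaired = FALSE)
}

#' @rdname pipeline-io
#' @export
writeEvannoTable <- function(x, path) {
    x$bestK <- attr(x, "bestK")
    writeTsv(x, path)
}

#' @rdname pipeline-io
#' @export
writeAssociationTable <- function(x, path) writeTsv(x, path)

#' @rdname pipeline-io
#' @export
readAssociationTable <- function(path)
    readTsv(path, c("marker_id", "allele", "trait", "year", "p", "q",
                    "effect", "maf"), "association results")

#' Write or read a simulation configuration as YAML
#'
#' @param config a [SimConfig-class].
#' @param path YAML file path.
#' @return `readConfigYaml` returns a [SimConfig-class].
#' @export
writeConfigYaml <- function(config, path) {
    stopifnot(is(config, "SimConfig"))
    slots <- slotNames(config)
    lst <- lapply(setNames(slots, slots), function(s) {
        v <- slot(config, s)
        if (is.data.frame(v)) return(as.list(v))
        ## keep element names: yaml writes named atomics as sequences
        if (!is.null(names(v))) return(as.list(v))
        v
    })
    yaml::write_yaml(lst, path)
    invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
    lst <- yaml::read_yaml(path)
    cm <- as.data.frame(lst$candidateMarkers, stringsAsFactors = FALSE)
    nm <- function(x) setNames(unlist(x), names(x))
    simConfig(nLines = lst$nLines,
              includeControl = lst$includeControl,
              KTrue = lst$KTrue,
              nStructureSsrs = lst$nStructureSsrs,
              ssrAlleleRange = unlist(lst$ssrAlleleRange),
              candidateMarkers = cm,
              admixtureConcentration = lst$admixtureConcentration,
              fst = lst$fst,
              baseline = nm(lst$baseline),
              sigma2Poly = nm(lst$sigma2Poly),
              polyShare = lst$polyShare,
              sigma2E = nm(lst$sigma2E),
              sigma2C = nm(lst$sigma2C),
              sigma2B = nm(lst$sigma2B),
              rhoRow = lst$rhoRow,
              rhoCol = lst$rhoCol,
              signalNoise = lst$signalNoise,
              nullAlleleProb = lst$nullAlleleProb,
              seed = lst$seed)
}
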