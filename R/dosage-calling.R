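#' @include AllClasses.R
NULL

dosageCall <- function(line_id, marker_id, alleles = integer(),
                       null = 0L, flags = character(),
                       missing = FALSE) {
    structure(list(line_id = line_id, marker_id = marker_id,
                   alleles = alleles, null = as.integer(null),
                   flags = flags, missing = missing),
              class = "DosageCall")
}

#' @export
print.DosageCall <- function(x, ...) {
    cat(sprintf("<%s @ %s> ", x$line_id, x$marker_id))
    if (x$missing) cat("missing\n")
    else cat(paste(names(x$alleles), x$alleles, sep = ":",
                   collapse = " "),
             if (x$null > 0L) sprintf("null:%d", x$null), "\n")
    invisible(x)
}

#' Call tetraploid SSR dosage from peak areas
#'
#' Applies peak-area scoring rules for a tetraploid microsatellite
#' genotype. Four peaks are scored as one copy each and a single peak as
#' four copies. With two peaks the area ratio (larger/smaller) is
#' classified to the nearest of the expected ratios 1 (2:2 copies), 2
#' (2:1 plus a null allele) or 3 (3:1), using class boundaries at the
#' geometric midpoints sqrt(2) and sqrt(6); a ratio falling exactly on a
#' boundary goes to the lower ratio class. With three peaks, a null
#' allele is assumed (1:1:1) when all areas are similar
#' (max/min < `similarity`); otherwise the largest peak is scored as two
#' copies.
#'
#' @param peaks data.frame with columns `allele` and `area` (positive)
#'   for one line at one marker; extra columns are ignored.
#' @param line_id,marker_id identifiers carried into the call.
#' @param ratioBoundaries two increasing thresholds separating the
#'   two-peak ratio classes.
#' @param similarity three-peak max/min area threshold below which a
#'   null allele is assumed.
#' @return a `DosageCall`: named allele copy numbers summing with the
#'   null count to 4, with flags `assumed_null` where a null allele was
#'   inferred. Zero peaks give a missing call; more than four peaks are
#'   an error.
#' @examples
#' callSsrDosage(data.frame(allele = c("170", "180"),
#'                          area = c(600, 300)))
#' @export
callSsrDosage <- function(peaks, line_id = "?", marker_id = "?",
                          ratioBoundaries = c(sqrt(2), sqrt(6)),
                          similarity = 1.5) {
    if (is.null(peaks) || nrow(peaks) == 0L)
        return(dosageCall(line_id, marker_id, missing = TRUE))
    if (any(peaks$area <= 0)) stop("peak areas must be positive")
    if (anyDuplicated(peaks$allele))
        stop("duplicate peaks for one allele at ", marker_id,
             " / ", line_id)
    if (nrow(peaks) > 4L)
        stop("more than 4 peaks at ", marker_id, " / ", line_id,
             ": tetraploid violation")
    ## deterministic ordering: area descending, allele label tie-break
    peaks <- peaks[order(-peaks$area, peaks$allele), , drop = FALSE]
    al <- as.character(peaks$allele)
    a <- peaks$area
    n <- nrow(peaks)
    if (n == 4L)
        return(dosageCall(line_id, marker_id,
                          setNames(rep(1L, 4L), al)))
    if (n == 1L)
        return(dosageCall(line_id, marker_id, setNames(4L, al)))
    if (n == 2L) {
        r <- a[1] / a[2]
        if (r <= ratioBoundaries[1])
            return(dosageCall(line_id, marker_id,
                              setNames(c(2L, 2L), al)))
        if (r <= ratioBoundaries[2])
            return(dosageCall(line_id, marker_id,
                              setNames(c(2L, 1L), al), null = 1L,
                              flags = "assumed_null"))
        return(dosageCall(line_id, marker_id, setNames(c(3L, 1L), al)))
    }
    ## three peaks
    if (max(a) / min(a) < similarity)
        return(dosageCall(line_id, marker_id,
                          setNames(rep(1L, 3L), al), null = 1L,
                          flags = "assumed_null"))
    dosageCall(line_id, marker_id, setNames(c(2L, 1L, 1L), al))
}

## nearest dosage class for a fraction in [0,1]; ties go to the lower d
classifyFraction <- function(f) {
    which.min(abs(f - (0:4) / 4)) - 1L
}

#' Call SNP dosage from bidirectional trace fractions
#'
#' The alternate-allele dosage (0-4 copies) is read separately from the
#' forward and reverse sequencing traces as the class `d` minimizing
#' `|fraction - d/4|` (ties to the lower dosage). Agreeing strands give
#' that dosage; disagreeing strands are resolved in favour of the strand
#' with the higher sequence quality (flag `discordant_strands`); with
#' equal qualities the fractions are averaged before classification.
#'
#' @param fwd,rev numeric vectors `c(fraction, quality)`, or `NULL` for
#'   a missing strand.
#' @param line_id,marker_id identifiers carried into the call.
#' @return list with `dosage` (0-4 alternate-allele copies, `NA` if both
#'   strands are missing) and `flags`.
#' @examples
#' callSnpDosage(c(0.27, 20), c(0.55, 40))  # dosage 2, discordant
#' @export
callSnpDosage <- function(fwd = NULL, rev = NULL,
                          line_id = "?", marker_id = "?") {
    chk <- function(x) {
        if (is.null(x)) return(NULL)
        if (is.na(x[1])) return(NULL)
        if (x[1] < 0 || x[1] > 1) stop("trace fraction outside [0,1]")
        if (length(x) < 2L || is.na(x[2])) x[2] <- 0
        if (x[2] < 0) stop("quality must be >= 0")
        x
    }
    fwd <- chk(fwd); rev <- chk(rev)
    if (is.null(fwd) && is.null(rev))
        return(list(dosage = NA_integer_, flags = character()))
    if (is.null(fwd) || is.null(rev)) {
        x <- if (is.null(fwd)) rev else fwd
        return(list(dosage = classifyFraction(x[1]),
                    flags = "single_strand"))
    }
    dF <- classifyFraction(fwd[1])
    dR <- classifyFraction(rev[1])
    if (dF == dR) return(list(dosage = dF, flags = character()))
    d <- if (fwd[2] > rev[2]) dF
         else if (rev[2] > fwd[2]) dR
         else classifyFraction((fwd[1] + rev[1]) / 2)
    list(dosage = d, flags = "discordant_strands")
}

#' Call InDel dosage from band intensities
#'
#' A single band is four copies of that allele. With two bands the
#' intensity fraction of the first is assigned to the nearest of 0.25,
#' 0.5 or 0.75, grouping heterozygotes into 1:3, 2:2 and 3:1.
#'
#' @param bands data.frame with columns `allele` and `intensity` for one
#'   line (1 or 2 rows).
#' @param line_id,marker_id identifiers carried into the call.
#' @return a `DosageCall`; zero bands give a missing call.
#' @examples
#' callIndelDosage(data.frame(allele = c("60", "200"),
#'                            intensity = c(300, 100)))
#' @export
callIndelDosage <- function(bands, line_id = "?", marker_id = "?") {
    if (is.null(bands) || nrow(bands) == 0L)
        return(dosageCall(line_id, marker_id, missing = TRUE))
    if (any(bands$intensity <= 0)) stop("band intensities must be positive")
    if (nrow(bands) > 2L)
        stop("more than 2 bands at ", marker_id, " / ", line_id)
    al <- as.character(bands$allele)
    if (nrow(bands) == 1L)
        return(dosageCall(line_id, marker_id, setNames(4L, al)))
    f <- bands$intensity[1] / sum(bands$intensity)
    d1 <- c(1L, 2L, 3L)[which.min(abs(f - c(0.25, 0.5, 0.75)))]
    dosageCall(line_id, marker_id, setNames(c(d1, 4L - d1), al))
}

#' Assemble dosage calls into a DosagePanel
#'
#' Expands a collection of per-line, per-marker `DosageCall`s into a
#' per-allele dosage matrix: one row for each allele of every
#' multi-allelic marker, one row (alternate-allele copies) for biallelic
#' SNPs and InDels. Missing genotypes become `NA` across the marker's
#' rows; call flags and null counts are kept in `metadata()$calls`, and
#' markers whose missingness exceeds `maxMissing` are listed in
#' `metadata()$flaggedMarkers`.
#'
#' @param calls list of `DosageCall` objects (plus SNP calls given as
#'   lists with `line_id`, `marker_id`, `dosage`, `flags`).
#' @param lineIds character vector fixing the panel lines and order.
#' @param markerInfo data.frame with at least `marker_id`, `type`,
#'   `role`; optionally `gene`, `chrom`, `pos`, `ref`, `alt`.
#' @param maxMissing missingness fraction above which a marker is
#'   flagged for exclusion.
#' @return a [DosagePanel-class].
#' @export
assembleDosagePanel <- function(calls, lineIds, markerInfo,
                                maxMissing = 0.2) {
    key <- vapply(calls, function(x)
        paste(x$line_id, x$marker_id, sep = "\r"), character(1))
    if (anyDuplicated(key))
        stop("duplicate line x marker calls: ",
             paste(head(sub("\r", " @ ", key[duplicated(key)]), 3),
                   collapse = ", "))
    byMarker <- split(calls, vapply(calls, `[[`, character(1),
                                    "marker_id"))
    mi <- markerInfo
    rows <- list(); rmeta <- list(); flagRows <- list()
    for (m in mi$marker_id) {
        cls <- byMarker[[m]]
        type <- mi$type[mi$marker_id == m]
        multi <- type == "SSR"
        if (multi) {
            alleles <- sort(unique(unlist(lapply(cls, function(x)
                names(x$alleles)))))
            M <- matrix(NA_integer_, length(alleles), length(lineIds),
                        dimnames = list(NULL, lineIds))
            for (x in cls) {
                if (is.null(x) || isTRUE(x$missing)) next
                v <- rep(0L, length(alleles))
                v[match(names(x$alleles), alleles)] <- x$alleles
                M[, x$line_id] <- v
            }
        } else {
            alleles <- mi$alt[mi$marker_id == m]
            if (is.na(alleles)) alleles <- "alt"
            M <- matrix(NA_integer_, 1L, length(lineIds),
                        dimnames = list(NULL, lineIds))
            for (x in cls) {
                if (!is.null(x$dosage)) {          # SNP-style call
                    M[, x$line_id] <- x$dosage
                } else if (!isTRUE(x$missing)) {    # InDel DosageCall
                    M[, x$line_id] <-
                        if (alleles %in% names(x$alleles))
                            x$alleles[[alleles]] else 0L
                }
            }
        }
        rows[[m]] <- M
        rmeta[[m]] <- data.frame(
            marker_id = m, allele = alleles, type = type,
            role = mi$role[mi$marker_id == m],
            gene = mi$gene[match(m, mi$marker_id)] %||% NA_character_,
            chrom = mi$chrom[match(m, mi$marker_id)] %||% NA_character_,
            pos = mi$pos[match(m, mi$marker_id)] %||% NA_integer_,
            ref = mi$ref[match(m, mi$marker_id)] %||% NA_character_,
            stringsAsFactors = FALSE)
        for (x in cls) {
            fl <- x$flags
            nullc <- if (is.null(x$null)) 0L else x$null
            if (length(fl) || nullc > 0L)
                flagRows[[length(flagRows) + 1L]] <- data.frame(
                    line_id = x$line_id, marker_id = m,
                    null_copies = nullc,
                    flags = paste(fl, collapse = ","),
                    stringsAsFactors = FALSE)
        }
    }
    dosage <- do.call(rbind, rows)
    rd <- do.call(rbind, rmeta)
    rownames(dosage) <- ifelse(rd$type == "SSR",
                               paste(rd$marker_id, rd$allele, sep = "."),
                               rd$marker_id)
    missFrac <- vapply(mi$marker_id, function(m) {
        i <- which(rd$marker_id == m)[1]
        mean(is.na(dosage[i, ]))
    }, numeric(1))
    dp <- SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = DataFrame(rd, row.names = rownames(dosage)),
        colData = DataFrame(line_id = lineIds, row.names = lineIds))
    dp <- new("DosagePanel", dp)
    metadata(dp)$calls <- if (length(flagRows))
        do.call(rbind, flagRows) else NULL
    metadata(dp)$flaggedMarkers <-
        names(missFrac)[missFrac > maxMissing]
    validObject(dp)
    dp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call all dosages from raw signal tables
#'
#' Runs the three callers over complete peak, trace and band tables (as
#' produced by [simulateSignals()] or read from TSV) and assembles a
#' [DosagePanel-class]. A line absent from a marker's signal table is a
#' missing genotype.
#'
#' @param signals list with data.frames `peaks`, `traces`, `bands`.
#' @param markerInfo marker metadata (see [assembleDosagePanel()]).
#' @param lineIds panel lines; defaults to every sample seen.
#' @param ratioBoundaries,similarity passed to [callSsrDosage()].
#' @param maxMissing passed to [assembleDosagePanel()].
#' @return a [DosagePanel-class].
#' @export
callDosages <- function(signals, markerInfo, lineIds = NULL,
                        ratioBoundaries = c(sqrt(2), sqrt(6)),
                        similarity = 1.5, maxMissing = 0.2) {
    if (is.null(lineIds))
        lineIds <- sort(unique(c(signals$peaks$sample_id,
                                 signals$traces$sample_id,
                                 signals$bands$sample_id)))
    calls <- list()
    add <- function(x) calls[[length(calls) + 1L]] <<- x
    for (m in markerInfo$marker_id[markerInfo$type == "SSR"]) {
        tab <- signals$peaks[signals$peaks$marker_id == m, , drop = FALSE]
        sp <- split(tab, factor(tab$sample_id, levels = lineIds))
        for (ln in lineIds)
            add(callSsrDosage(sp[[ln]], ln, m,
                              ratioBoundaries = ratioBoundaries,
                              similarity = similarity))
    }
    for (m in markerInfo$marker_id[markerInfo$type == "SNP"]) {
        tab <- signals$traces[signals$traces$marker_id == m, ,
                              drop = FALSE]
        for (ln in lineIds) {
            sub <- tab[tab$sample_id == ln, , drop = FALSE]
            getStrand <- function(s) {
                i <- which(sub$strand == s)
                if (length(i) > 1L)
                    stop("duplicate line x marker calls: ", ln, " @ ", m)
                if (!length(i)) NULL
                else c(sub$alt_fraction[i], sub$quality[i])
            }
            res <- callSnpDosage(getStrand("F"), getStrand("R"), ln, m)
            add(list(line_id = ln, marker_id = m, dosage = res$dosage,
                     null = 0L, flags = res$flags,
                     missing = is.na(res$dosage)))
        }
    }
    for (m in markerInfo$marker_id[markerInfo$type == "InDel"]) {
        tab <- signals$bands[signals$bands$marker_id == m, ,
                             drop = FALSE]
        sp <- split(tab, factor(tab$sample_id, levels = lineIds))
        for (ln in lineIds)
            add(callIndelDosage(sp[[ln]], ln, m))
    }
    assembleDosagePanel(calls, lineIds, markerInfo,
                        maxMissing = maxMissing)
}
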