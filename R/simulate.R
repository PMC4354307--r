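#' @include simconfig.R
NULL

## One categorical draw per row of a row-stochastic matrix P.
drawCategoricalRows <- function(P) {
    A <- ncol(P)
    if (A == 1L) return(rep(1L, nrow(P)))
    cp <- P
    for (j in 2:A) cp[, j] <- cp[, j - 1L] + P[, j]
    u <- runif(nrow(P))
    pmin(rowSums(u > cp) + 1L, A)
}

## Balding-Nichols-style subpopulation frequencies around base (simplex).
divergedFreqs <- function(K, base, fst) {
    if (fst <= 0)
        return(matrix(base, K, length(base), byrow = TRUE))
    f <- rdirichlet(K, base * (1 - fst) / fst)
    ## guard against exact zeros that would make the likelihood degenerate
    f <- f + 1e-9
    sweep(f, 1, rowSums(f), "/")
}

#' Simulate an admixed autotetraploid panel
#'
#' Draws admixture proportions (Dirichlet rows), per-subpopulation
#' allele frequencies (hierarchical Dirichlet for SSRs,
#' Balding-Nichols beta for biallelic markers) and true allele dosages.
#' Each of the four allele copies at a locus is drawn independently:
#' first an ancestry from the line's admixture row, then an allele from
#' that subpopulation's frequencies at the locus. Copies are i.i.d. --
#' no double reduction or preferential pairing is modelled, matching the
#' free 0-4 dosage view of the downstream analysis.
#'
#' @param config a [SimConfig-class].
#' @return a [TruePanel-class] with empty genetic values (fill with
#'   [simulateCausalArchitecture()]).
#' @examples
#' panel <- simulateAdmixedPopulation(simConfig(nLines = 20, seed = 7))
#' panel
#' @export
simulateAdmixedPopulation <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nLines + as.integer(config@includeControl)
    lineIds <- c(sprintf("L%03d", seq_len(config@nLines)),
                 if (config@includeControl) "CONTROL")
    isControl <- c(rep(FALSE, config@nLines),
                   if (config@includeControl) TRUE)
    K <- config@KTrue
    Q <- if (K == 1L) matrix(1, n, 1L)
         else rdirichlet(n, rep(config@admixtureConcentration, K))
    rownames(Q) <- lineIds

    info <- list(); freqs <- list(); dosages <- list()
    addLocus <- function(id, role, type, gene, labels, f, rec) {
        f <- f + 0; colnames(f) <- labels
        freqs[[id]] <<- f
        d <- matrix(0L, n, length(labels),
                    dimnames = list(lineIds, labels))
        for (cp in seq_len(config@ploidy)) {
            anc <- drawCategoricalRows(Q)
            al <- drawCategoricalRows(f[anc, , drop = FALSE])
            ix <- cbind(seq_len(n), al)
            d[ix] <- d[ix] + 1L
        }
        dosages[[id]] <<- d
        info[[length(info) + 1L]] <<- data.frame(
            marker_id = id, role = role, type = type, gene = gene,
            n_alleles = length(labels),
            freq = rec$freq, effect_C6 = rec$effect_C6,
            effect_C3 = rec$effect_C3, ref = rec$ref, alt = rec$alt,
            chrom = rec$chrom, pos = rec$pos, stringsAsFactors = FALSE)
    }
    noRec <- list(freq = NA_real_, effect_C6 = 0, effect_C3 = 0,
                  ref = NA_character_, alt = NA_character_,
                  chrom = NA_character_, pos = NA_integer_)

    ## structure SSRs: one to two per chromosome, 3-17 alleles each
    r <- config@ssrAlleleRange
    nA <- sample(seq(r[1], r[2]), config@nStructureSsrs, replace = TRUE)
    for (l in seq_len(config@nStructureSsrs)) {
        labels <- as.character(100L + 4L * l + 2L * (seq_len(nA[l]) - 1L))
        base <- drop(rdirichlet(1L, rep(1, nA[l])))
        rec <- noRec
        rec$chrom <- paste0("chr", sprintf("%02d", (l - 1L) %% 12L + 1L))
        rec$pos <- 1000L + 100L * l
        addLocus(sprintf("ssr%02d", l), "structure", "SSR", NA_character_,
                 labels, divergedFreqs(K, base, config@fst), rec)
    }

    ## candidate markers
    cm <- config@candidateMarkers
    for (i in seq_len(nrow(cm))) {
        rec <- as.list(cm[i, ])
        if (cm$type[i] == "SSR") {
            labels <- as.character(165L + 3L * (seq_len(cm$n_alleles[i]) - 1L))
            base <- drop(rdirichlet(1L, rep(1, cm$n_alleles[i])))
            f <- divergedFreqs(K, base, config@fst)
        } else {
            labels <- c(cm$ref[i], cm$alt[i])
            p <- cm$freq[i]
            fa <- if (config@fst <= 0) rep(p, K)
                  else rbeta(K, p * (1 - config@fst) / config@fst,
                             (1 - p) * (1 - config@fst) / config@fst)
            fa <- pmin(pmax(fa, 1e-6), 1 - 1e-6)
            f <- cbind(1 - fa, fa)
        }
        addLocus(cm$marker_id[i], "candidate", cm$type[i], cm$gene[i],
                 labels, f, rec)
    }

    new("TruePanel", lineIds = lineIds, isControl = isControl, Q = Q,
        markerInfo = do.call(rbind, info), freqs = freqs,
        dosages = dosages, nullCopies = list(),
        geneticValues = matrix(numeric(0), 0, 0), config = config)
}

#' Draw genetic values from the causal architecture
#'
#' Genetic value of a line for each trait = sum over causal markers of
#' (copies of the causal allele) x (per-copy effect, nmol/mg) plus a
#' polygenic deviate with ancestry-structured covariance. The polygenic
#' covariance is `Q Q'` scaled to unit mean diagonal; a fraction
#' `polyShare` of the polygenic variance is carried by a component
#' common to C6 and C3, which (together with markers causal for both
#' traits) generates the cross-trait correlation of the two
#' phosphorylation measures.
#'
#' @param panel a [TruePanel-class].
#' @param seed RNG seed; defaults to the panel seed offset by 1.
#' @return the panel with `geneticValues` filled (lines x C6/C3,
#'   deviations from the trait-year baselines).
#' @export
simulateCausalArchitecture <- function(panel,
                                       seed = panel@config@seed + 1L) {
    stopifnot(is(panel, "TruePanel"))
    set.seed(seed)
    cfg <- panel@config
    n <- length(panel@lineIds)
    g <- matrix(0, n, 2, dimnames = list(panel@lineIds, c("C6", "C3")))
    mi <- panel@markerInfo
    causal <- mi[mi$effect_C6 != 0 | mi$effect_C3 != 0, , drop = FALSE]
    for (i in seq_len(nrow(causal))) {
        m <- causal$marker_id[i]
        d <- panel@dosages[[m]][, causal$alt[i]]
        g[, "C6"] <- g[, "C6"] + d * causal$effect_C6[i]
        g[, "C3"] <- g[, "C3"] + d * causal$effect_C3[i]
    }
    A <- tcrossprod(panel@Q)
    ## Polygenic covariance: ancestry-shared part (Q Q', scaled so its
    ## across-line variance is 1; the sample variance of N(0, A) is
    ## mean(diag(A)) - mean(A)) blended half-half with an independent
    ## line-specific part. Q Q' alone has rank K_true, which would make
    ## the polygenic term a subpopulation effect rather than a
    ## line-level one; with K = 1 the ancestry part vanishes entirely.
    sc <- mean(diag(A)) - mean(A)
    A <- if (sc > 1e-12) 0.5 * A / sc + 0.5 * diag(n) else diag(n)
    U <- chol(A + diag(1e-8, n))
    a <- drop(crossprod(U, rnorm(n)))
    sh <- cfg@polyShare
    for (tr in c("C6", "C3")) {
        b <- drop(crossprod(U, rnorm(n)))
        g[, tr] <- g[, tr] + sqrt(cfg@sigma2Poly[[tr]]) *
            (sqrt(sh) * a + sqrt(1 - sh) * b)
    }
    panel@geneticValues <- g
    validObject(panel)
    panel
}

#' Simulate raw genotyping signals from true dosages
#'
#' Forward model for the dosage caller. SSR peak areas are proportional
#' to allele copy number with multiplicative lognormal noise
#' (`sdlog = signalNoise`); with probability `nullAlleleProb` one allele
#' of an SSR genotype is a null and its peak is absent. SNP trace
#' fractions are `dosage / 4` plus clipped Gaussian noise
#' (`sd = signalNoise / 4`), reported independently for the forward and
#' reverse strands each with a simulated quality score. InDel band
#' intensities are proportional to copy number.
#'
#' @param panel a [TruePanel-class].
#' @param seed RNG seed; defaults to the panel seed offset by 2.
#' @return list with data.frames `peaks` (`sample_id`, `marker_id`,
#'   `allele`, `area`), `traces` (`sample_id`, `marker_id`, `strand`,
#'   `alt_fraction`, `quality`) and `bands` (`sample_id`, `marker_id`,
#'   `allele`, `intensity`). The peaks table carries a `silenced`
#'   attribute listing null-allele events (line, marker, hidden copies).
#' @export
simulateSignals <- function(panel, seed = panel@config@seed + 2L) {
    stopifnot(is(panel, "TruePanel"))
    set.seed(seed)
    cfg <- panel@config
    n <- length(panel@lineIds)
    mi <- panel@markerInfo
    noise <- cfg@signalNoise
    peaks <- list(); traces <- list(); bands <- list()
    silenced <- list()

    for (i in seq_len(nrow(mi))) {
        m <- mi$marker_id[i]
        D <- panel@dosages[[m]]
        if (mi$type[i] == "SSR") {
            obs <- D
            if (cfg@nullAlleleProb > 0) {
                hit <- which(runif(n) < cfg@nullAlleleProb)
                for (h in hit) {
                    present <- which(obs[h, ] > 0L)
                    al <- if (length(present) == 1L) present
                          else sample(present, 1L)
                    silenced[[length(silenced) + 1L]] <- data.frame(
                        sample_id = panel@lineIds[h], marker_id = m,
                        allele = colnames(obs)[al],
                        copies = obs[h, al])
                    obs[h, al] <- 0L
                }
            }
            idx <- which(obs > 0L, arr.ind = TRUE)
            area <- obs[idx] * 500 *
                exp(rnorm(nrow(idx), 0, noise))
            peaks[[length(peaks) + 1L]] <- data.frame(
                sample_id = panel@lineIds[idx[, 1]], marker_id = m,
                allele = colnames(obs)[idx[, 2]], area = area,
                stringsAsFactors = FALSE)
        } else if (mi$type[i] == "SNP") {
            d <- D[, mi$alt[i]]
            for (strand in c("F", "R")) {
                fr <- d / 4 + rnorm(n, 0, noise / 4)
                traces[[length(traces) + 1L]] <- data.frame(
                    sample_id = panel@lineIds, marker_id = m,
                    strand = strand,
                    alt_fraction = pmin(pmax(fr, 0), 1),
                    quality = round(runif(n, 20, 60), 1),
                    stringsAsFactors = FALSE)
            }
        } else {  # InDel
            idx <- which(D > 0L, arr.ind = TRUE)
            bands[[length(bands) + 1L]] <- data.frame(
                sample_id = panel@lineIds[idx[, 1]], marker_id = m,
                allele = colnames(D)[idx[, 2]],
                intensity = D[idx] * 200 *
                    exp(rnorm(nrow(idx), 0, noise)),
                stringsAsFactors = FALSE)
        }
    }
    pk <- do.call(rbind, peaks)
    attr(pk, "silenced") <- if (length(silenced))
        do.call(rbind, silenced) else NULL
    list(peaks = pk,
         traces = do.call(rbind, traces),
         bands = do.call(rbind, bands))
}

#' Simulate plot-level phenotypes on a field layout
#'
#' For each trait-year dataset, plot value = trait-year baseline +
#' genetic value of the line (reused across years, so year-to-year
#' correlation of adjusted means is an emergent property) + column-set
#' effect + 36-plot extraction-batch effect + AR(1) x AR(1) spatial
#' residual, all in nmol/mg. Variances and correlations come from the
#' panel's [SimConfig-class].
#'
#' @param trial a [FieldTrial-class] from [buildFieldLayout()].
#' @param panel a [TruePanel-class] with genetic values filled; line ids
#'   must cover the layout's lines.
#' @param seed RNG seed; defaults to the panel seed offset by 3.
#' @param years character vector of year labels.
#' @return the trial with its `phenotypes` table filled.
#' @export
simulatePhenotypes <- function(trial, panel,
                               seed = panel@config@seed + 3L,
                               years = c("2011", "2012")) {
    stopifnot(is(trial, "FieldTrial"), is(panel, "TruePanel"))
    if (!nrow(panel@geneticValues))
        stop("panel has no genetic values; run simulateCausalArchitecture()")
    set.seed(seed)
    cfg <- panel@config
    pl <- trial@plots
    miss <- setdiff(pl$line_id, rownames(panel@geneticValues))
    if (length(miss))
        stop("layout lines missing from panel: ",
             paste(head(miss, 5), collapse = ", "))
    nr <- max(pl$row); nc <- max(pl$col)
    cR <- chol(ar1Correlation(nr, cfg@rhoRow))
    cC <- chol(ar1Correlation(nc, cfg@rhoCol))
    out <- list()
    for (tr in c("C6", "C3")) {
        for (yr in years) {
            key <- paste(tr, yr, sep = "_")
            uC <- rnorm(nc, 0, sqrt(cfg@sigma2C[[tr]]))
            uB <- rnorm(max(pl$batch36_id), 0, sqrt(cfg@sigma2B[[tr]]))
            E <- sqrt(cfg@sigma2E[[tr]]) *
                crossprod(cR, matrix(rnorm(nr * nc), nr, nc)) %*% cC
            val <- cfg@baseline[[key]] +
                panel@geneticValues[pl$line_id, tr] +
                uC[pl$colset_id] + uB[pl$batch36_id] +
                E[cbind(pl$row, pl$col)]
            out[[key]] <- data.frame(
                plot_order = pl$plot_order, trait = tr, year = yr,
                value = unname(val), stringsAsFactors = FALSE)
        }
    }
    trial@phenotypes <- do.call(rbind, c(out, make.row.names = FALSE))
    trial
}

#' Simulate a complete study in one call
#'
#' Convenience wrapper: admixed panel, causal architecture, raw signals,
#' field layout and plot phenotypes, all from one configuration seed.
#'
#' @param config a [SimConfig-class].
#' @param layout list with `nRows`, `nCols`, `nControls` for
#'   [buildFieldLayout()]; the default fits the standard 192-line panel
#'   (2 x 192 + 48 = 432 plots). Scaled panels must supply consistent
#'   dimensions.
#' @return list with `panel` ([TruePanel-class]), `signals` (see
#'   [simulateSignals()]) and `trial` ([FieldTrial-class] with
#'   phenotypes).
#' @export
simulateStudy <- function(config,
                          layout = list(nRows = 72L, nCols = 6L,
                                        nControls = 48L)) {
    panel <- simulateAdmixedPopulation(config)
    panel <- simulateCausalArchitecture(panel)
    signals <- simulateSignals(panel)
    trial <- buildFieldLayout(
        lineIds = panel@lineIds[!panel@isControl],
        controlId = if (any(panel@isControl))
            panel@lineIds[panel@isControl] else "CONTROL",
        nRows = layout$nRows, nCols = layout$nCols,
        nControls = layout$nControls,
        seed = config@seed + 4L)
    trial <- simulatePhenotypes(trial, panel)
    list(panel = panel, signals = signals, trial = trial)
}

#' Dosage panel directly from generator truth
#'
#' Packs the true dosages of a [TruePanel-class] into a
#' [DosagePanel-class], bypassing the signal and calling stages. Used
#' when a downstream stage is studied in isolation (the caller's
#' zero-noise output is identical by construction).
#'
#' @param panel a [TruePanel-class].
#' @return a [DosagePanel-class].
#' @export
asDosagePanel <- function(panel) {
    stopifnot(is(panel, "TruePanel"))
    mi <- panel@markerInfo
    rows <- list(); rmeta <- list()
    for (i in seq_len(nrow(mi))) {
        m <- mi$marker_id[i]
        D <- panel@dosages[[m]]
        if (mi$type[i] == "SSR") {
            keep <- colSums(D) > 0
            M <- t(D[, keep, drop = FALSE])
            alleles <- colnames(D)[keep]
        } else {
            M <- t(D[, mi$alt[i], drop = FALSE])
            alleles <- mi$alt[i]
        }
        rows[[m]] <- M
        rmeta[[m]] <- data.frame(
            marker_id = m, allele = alleles, type = mi$type[i],
            role = mi$role[i], gene = mi$gene[i], chrom = mi$chrom[i],
            pos = mi$pos[i], ref = mi$ref[i], stringsAsFactors = FALSE)
    }
    dosage <- do.call(rbind, rows)
    rd <- do.call(rbind, rmeta)
    rownames(dosage) <- ifelse(rd$type == "SSR",
                               paste(rd$marker_id, rd$allele, sep = "."),
                               rd$marker_id)
    dp <- SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = DataFrame(rd, row.names = rownames(dosage)),
        colData = DataFrame(line_id = panel@lineIds,
                            row.names = panel@lineIds))
    new("DosagePanel", dp)
}
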