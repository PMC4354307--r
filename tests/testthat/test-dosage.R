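test_that("SSR peak patterns follow the tetraploid scoring rules", {
    ## 2:1 area ratio implies one null allele
    x <- callSsrDosage(data.frame(allele = c("170", "180"),
                                  area = c(600, 300)))
    expect_equal(x$alleles, c(`170` = 2L, `180` = 1L))
    expect_equal(x$null, 1L)
    expect_true("assumed_null" %in% x$flags)
    ## three similar peaks: null assumed, one copy each
    x <- callSsrDosage(data.frame(allele = c("165", "171", "177"),
                                  area = c(500, 480, 510)))
    expect_equal(sort(names(x$alleles)), c("165", "171", "177"))
    expect_true(all(x$alleles == 1L))
    expect_equal(x$null, 1L)
    ## three dissimilar peaks: the largest is two copies
    x <- callSsrDosage(data.frame(allele = c("165", "171", "177"),
                                  area = c(900, 400, 380)))
    expect_equal(x$alleles[["165"]], 2L)
    expect_equal(x$null, 0L)
    ## single peak: four copies
    x <- callSsrDosage(data.frame(allele = "180", area = 1000))
    expect_equal(x$alleles, c(`180` = 4L))
    ## equal areas: 2:2
    x <- callSsrDosage(data.frame(allele = c("150", "156"),
                                  area = c(400, 400)))
    expect_equal(unname(x$alleles), c(2L, 2L))
    ## four peaks: single copy each
    x <- callSsrDosage(data.frame(allele = as.character(1:4),
                                  area = c(9, 7, 8, 6) * 100))
    expect_true(all(x$alleles == 1L) && x$null == 0L)
})

test_that("two-peak ratios exactly on a boundary go to the lower class", {
    x <- callSsrDosage(data.frame(allele = c("a", "b"),
                                  area = c(300 * sqrt(2), 300)))
    expect_equal(unname(x$alleles), c(2L, 2L))   # sqrt(2) -> ratio 1
    x <- callSsrDosage(data.frame(allele = c("a", "b"),
                                  area = c(300 * sqrt(6), 300)))
    expect_equal(unname(x$alleles), c(2L, 1L))   # sqrt(6) -> ratio 2
    expect_equal(x$null, 1L)
    ## just past the boundary
    x <- callSsrDosage(data.frame(allele = c("a", "b"),
                                  area = c(300 * sqrt(6) + 1, 300)))
    expect_equal(unname(x$alleles), c(3L, 1L))
})

test_that("SSR edge inputs are missing calls or errors", {
    expect_true(callSsrDosage(data.frame(allele = character(),
                                         area = numeric()))$missing)
    expect_error(callSsrDosage(data.frame(allele = as.character(1:5),
                                          area = rep(100, 5))),
                 "tetraploid")
    expect_error(callSsrDosage(data.frame(allele = c("a", "a"),
                                          area = c(1, 2))),
                 "duplicate")
})

test_that("SNP dosage combines strands by agreement then quality", {
    expect_equal(callSnpDosage(c(0.49, 30), c(0.52, 28))$dosage, 2L)
    x <- callSnpDosage(c(0.27, 20), c(0.55, 40))
    expect_equal(x$dosage, 2L)
    expect_true("discordant_strands" %in% x$flags)
    expect_equal(callSnpDosage(c(0, 30), c(0, 30))$dosage, 0L)
    ## equal quality: fractions averaged before classification
    x <- callSnpDosage(c(0.27, 30), c(0.55, 30))
    expect_equal(x$dosage, 2L)   # mean 0.41 is nearest 0.5
    ## single strand, and ties to the lower dosage at midpoints
    expect_equal(callSnpDosage(c(0.125, 30), NULL)$dosage, 0L)
    expect_true(is.na(callSnpDosage(NULL, NULL)$dosage))
})

test_that("InDel bands group heterozygotes into three genotypes", {
    x <- callIndelDosage(data.frame(allele = "200", intensity = 500))
    expect_equal(x$alleles, c(`200` = 4L))
    x <- callIndelDosage(data.frame(allele = c("60", "200"),
                                    intensity = c(300, 100)))
    expect_equal(x$alleles, c(`60` = 3L, `200` = 1L))
    x <- callIndelDosage(data.frame(allele = c("60", "200"),
                                    intensity = c(250, 250)))
    expect_equal(unname(x$alleles), c(2L, 2L))
    expect_true(callIndelDosage(
        data.frame(allele = character(), intensity = numeric()))$missing)
})

test_that("assembled dosage columns conserve ploidy and classes", {
    cfg <- smallConfig(seed = 21, signalNoise = 0.05,
                       nullAlleleProb = 0.05)
    p <- simulateAdmixedPopulation(cfg)
    sg <- simulateSignals(p)
    dp <- callDosages(sg, p@markerInfo, lineIds = p@lineIds)
    rd <- as.data.frame(SummarizedExperiment::rowData(dp))
    d <- SummarizedExperiment::assay(dp, "dosage")
    expect_true(all(d[!is.na(d)] %in% 0:4))
    ## per SSR marker: column sums + called null copies = 4
    calls <- S4Vectors::metadata(dp)$calls
    for (m in unique(rd$marker_id[rd$type == "SSR"])) {
        rows <- which(rd$marker_id == m)
        tot <- colSums(d[rows, , drop = FALSE])
        nullc <- setNames(rep(0L, ncol(d)), colnames(d))
        if (!is.null(calls)) {
            cm <- calls[calls$marker_id == m, ]
            nullc[cm$line_id] <- cm$null_copies
        }
        ok <- !is.na(tot)
        expect_true(all(tot[ok] + nullc[ok] == 4L))
    }
})

test_that("duplicate line x marker calls are rejected", {
    calls <- list(
        callSsrDosage(data.frame(allele = "1", area = 100), "L1", "m"),
        callSsrDosage(data.frame(allele = "2", area = 100), "L1", "m"))
    mi <- data.frame(marker_id = "m", type = "SSR", role = "candidate",
                     alt = NA_character_)
    expect_error(assembleDosagePanel(calls, "L1", mi), "duplicate")
})

test_that("calls at zero noise reproduce the simulated truth exactly", {
    ## full-size panel, all marker types, no noise, no nulls
    cfg <- simConfig(seed = 22, signalNoise = 0, nullAlleleProb = 0)
    p <- simulateAdmixedPopulation(cfg)
    sg <- simulateSignals(p)
    dp <- callDosages(sg, p@markerInfo, lineIds = p@lineIds)
    rd <- as.data.frame(SummarizedExperiment::rowData(dp))
    d <- SummarizedExperiment::assay(dp, "dosage")
    mismatches <- 0L
    for (m in p@markerInfo$marker_id) {
        rows <- which(rd$marker_id == m)
        truth <- t(p@dosages[[m]][, rd$allele[rows], drop = FALSE])
        mismatches <- mismatches +
            sum(truth != d[rows, , drop = FALSE], na.rm = TRUE) +
            sum(is.na(d[rows, , drop = FALSE]))
    }
    expect_identical(mismatches, 0L)
})

test_that("calling accuracy degrades monotonically with signal noise", {
    accuracy <- function(noise, seed = 23) {
        cfg <- simConfig(nLines = 50L, KTrue = 2L, nStructureSsrs = 15L,
                         candidateMarkers = smallMarkers(),
                         signalNoise = noise, nullAlleleProb = 0,
                         seed = seed)
        p <- simulateAdmixedPopulation(cfg)
        sg <- simulateSignals(p)
        dp <- callDosages(sg, p@markerInfo, lineIds = p@lineIds)
        rd <- as.data.frame(SummarizedExperiment::rowData(dp))
        d <- SummarizedExperiment::assay(dp, "dosage")
        hits <- 0L; cells <- 0L
        for (m in p@markerInfo$marker_id) {
            rows <- which(rd$marker_id == m)
            truth <- t(p@dosages[[m]][, rd$allele[rows], drop = FALSE])
            called <- d[rows, , drop = FALSE]
            hits <- hits + sum(truth == called, na.rm = TRUE)
            cells <- cells + length(truth)
        }
        hits / cells
    }
    acc <- vapply(c(0, 0.05, 0.1, 0.2), accuracy, numeric(1))
    expect_equal(acc[1], 1)
    expect_true(all(diff(acc) <= 0))
})

test_that("markers above the missingness cap are flagged", {
    mi <- data.frame(marker_id = c("m1", "m2"), type = "SSR",
                     role = "candidate", alt = NA_character_)
    calls <- list(
        callSsrDosage(data.frame(allele = "1", area = 9), "L1", "m1"),
        callSsrDosage(data.frame(allele = "1", area = 9), "L2", "m1"),
        callSsrDosage(data.frame(allele = "1", area = 9), "L1", "m2"),
        callSsrDosage(NULL, "L2", "m2"))
    dp <- assembleDosagePanel(calls, c("L1", "L2"), mi,
                              maxMissing = 0.2)
    expect_identical(S4Vectors::metadata(dp)$flaggedMarkers, "m2")
})
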