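#' @include AllClasses.R
NULL

## AR(1) correlation matrix, unit diagonal.
ar1Correlation <- function(n, rho) {
    rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

#' Build a randomized control-augmented field layout
#'
#' Generates a 72 x 6 plot layout holding two replicate plots of each of
#' 192 test lines plus 48 plots of a control line, by randomized
#' constraint satisfaction. The constraints mirror the augmented
#' resolvable design of the emulated trial: one full replicate in each
#' of two adjacent 3-column blocks, eight control plots per column, six
#' controls per consecutive set of nine rows, and at most one control
#' per row. Plots are numbered in processing order down each column;
#' starch-extraction batches cover 36 consecutive plots and
#' measurement-run batches 72.
#'
#' @param lineIds ids of the test lines (two plots each).
#' @param controlId id of the control line.
#' @param nRows,nCols grid dimensions (rows must be divisible by 9 and
#'   columns even).
#' @param nControls number of control plots (divisible by the column
#'   count and by the number of 9-row sets).
#' @param seed RNG seed for the randomized assignment.
#' @return a [FieldTrial-class] with no phenotypes.
#' @examples
#' trial <- buildFieldLayout(seed = 1)
#' validateLayout(trial)   # character(0)
#' @export
buildFieldLayout <- function(lineIds = sprintf("L%03d", 1:192),
                             controlId = "CONTROL",
                             nRows = 72L, nCols = 6L, nControls = 48L,
                             seed = 1L) {
    nTest <- length(lineIds)
    if (2L * nTest + nControls != nRows * nCols)
        stop("infeasible counts: 2*", nTest, " + ", nControls,
             " != ", nRows * nCols)
    if (nCols %% 2L != 0L || nRows %% 9L != 0L)
        stop("layout needs an even column count and rows divisible by 9")
    nSets <- nRows %/% 9L
    if (nControls %% nCols != 0L || nControls %% nSets != 0L ||
        nControls > nRows)
        stop("control count incompatible with column/row-set/row rules")
    if (anyDuplicated(c(lineIds, controlId)))
        stop("duplicated line ids")
    set.seed(seed)
    perSet <- nControls %/% nSets
    ctrlRows <- sort(unlist(lapply(seq_len(nSets) - 1L, function(s)
        9L * s + sample.int(9L, perSet))))
    ctrlCols <- sample(rep(seq_len(nCols), each = nControls %/% nCols))
    isCtrl <- matrix(FALSE, nRows, nCols)
    isCtrl[cbind(ctrlRows, ctrlCols)] <- TRUE

    half <- nCols %/% 2L
    lineGrid <- matrix(NA_character_, nRows, nCols)
    for (b in 0:1) {
        cols <- b * half + seq_len(half)
        open <- which(!isCtrl[, cols, drop = FALSE], arr.ind = TRUE)
        if (nrow(open) != nTest)
            stop("block ", b + 1L, " does not hold one replicate")
        perm <- sample(nTest)
        lineGrid[cbind(open[, 1], cols[open[, 2]])] <- lineIds[perm]
    }
    lineGrid[isCtrl] <- controlId

    grid <- expand.grid(row = seq_len(nRows), col = seq_len(nCols))
    ord <- (grid$col - 1L) * nRows + grid$row
    plots <- data.frame(
        plot_order = ord, row = grid$row, col = grid$col,
        line_id = lineGrid[cbind(grid$row, grid$col)],
        is_control = isCtrl[cbind(grid$row, grid$col)],
        colset_id = grid$col,
        batch36_id = (ord - 1L) %/% 36L + 1L,
        batch72_id = (ord - 1L) %/% 72L + 1L,
        stringsAsFactors = FALSE)
    plots <- plots[order(plots$plot_order), ]
    rownames(plots) <- NULL
    new("FieldTrial", plots = plots,
        phenotypes = data.frame(plot_order = integer(),
                                trait = character(),
                                year = character(),
                                value = numeric()))
}

#' Check field-layout invariants
#'
#' Verifies the layout rules: a complete rectangular grid, two plots per
#' test line, controls evenly spread over columns, six controls per
#' 9-row set, and at most one control per row. Expected counts are
#' inferred from the trial itself so the checks also apply to scaled
#' layouts.
#'
#' @param trial a [FieldTrial-class] (or its `plots` data.frame).
#' @return character vector of violations, empty if the layout is valid.
#' @export
validateLayout <- function(trial) {
    pl <- if (is(trial, "FieldTrial")) trial@plots else trial
    v <- character()
    need <- c("plot_order", "row", "col", "line_id", "is_control",
              "colset_id", "batch36_id")
    if (!all(need %in% names(pl)))
        return(paste("missing plot columns:",
                     paste(setdiff(need, names(pl)), collapse = ", ")))
    nR <- max(pl$row); nC <- max(pl$col)
    if (nrow(pl) != nR * nC ||
        anyDuplicated(pl[, c("row", "col")]) ||
        nrow(unique(pl[, c("row", "col")])) != nR * nC)
        v <- c(v, sprintf("grid incomplete: %d plots for a %d x %d array",
                          nrow(pl), nR, nC))
    nCtrl <- sum(pl$is_control)
    tab <- table(pl$line_id[!pl$is_control])
    bad <- names(tab)[tab != 2L]
    if (length(bad))
        v <- c(v, paste("test lines without exactly 2 plots:",
                        paste(head(bad, 5), collapse = ", ")))
    if (nCtrl) {
        byCol <- tapply(pl$is_control, pl$col, sum)
        exp <- nCtrl / nC
        for (cc in names(byCol)[byCol != exp])
            v <- c(v, sprintf("column %s has %d controls, expected %g",
                              cc, byCol[[cc]], exp))
        byRow <- tapply(pl$is_control, pl$row, sum)
        if (any(byRow > 1L))
            v <- c(v, sprintf("rows with >1 control: %s",
                              paste(names(byRow)[byRow > 1L],
                                    collapse = ", ")))
        if (nR %% 9L == 0L) {
            set <- (pl$row - 1L) %/% 9L + 1L
            bySet <- tapply(pl$is_control, set, sum)
            expSet <- nCtrl / (nR / 9L)
            for (s in names(bySet)[bySet != expSet])
                v <- c(v, sprintf(
                    "9-row set %s has %d controls, expected %g",
                    s, bySet[[s]], expSet))
        }
    }
    v
}
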