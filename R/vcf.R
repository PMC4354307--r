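#' @include io-tsv.R
NULL

#' Write biallelic SNP dosages as VCF 4.2
#'
#' Serializes the biallelic SNP subset of a [DosagePanel-class] as a
#' VCF with one record per SNP, contig/position from the marker
#' metadata, and the tetraploid dosage (0-4, alternate-allele copies)
#' in a per-sample numeric `DS` FORMAT field; missing genotypes are
#' written as `.`. Multi-allelic markers and InDels have no standard
#' dosage container and are skipped with a warning when present in the
#' selection.
#'
#' @param panel a [DosagePanel-class].
#' @param path output file path (`.vcf`).
#' @return the path, invisibly.
#' @export
writeDosageVcf <- function(panel, path) {
    stopifnot(is(panel, "DosagePanel"))
    rd <- as.data.frame(rowData(panel))
    nonSnp <- rd$type != "SNP"
    if (any(nonSnp & rd$role == "candidate"))
        warning("skipping ", sum(nonSnp & rd$role == "candidate"),
                " non-SNP marker rows (no standard dosage container)")
    sel <- which(rd$type == "SNP")
    if (!length(sel)) stop("no biallelic SNP markers to write")
    rd <- rd[sel, , drop = FALSE]
    DS <- SummarizedExperiment::assay(panel, "dosage")[sel, ,
                                                       drop = FALSE]
    mode(DS) <- "numeric"
    rownames(DS) <- rd$marker_id
    o <- order(rd$chrom, rd$pos)
    rd <- rd[o, , drop = FALSE]; DS <- DS[o, , drop = FALSE]
    gr <- GRanges(rd$chrom, IRanges(rd$pos, width = 1L))
    names(gr) <- rd$marker_id
    samples <- colnames(DS)
    hdr <- VariantAnnotation::VCFHeader(
        samples = samples,
        header = IRanges::DataFrameList(
                   fileformat = DataFrame(Value = "VCFv4.2",
                                          row.names = "fileformat"),
                   FORMAT = DataFrame(
                       Number = "1", Type = "Float",
                       Description = "Tetraploid alternate-allele dosage (0-4)",
                       row.names = "DS")))
    vcf <- VariantAnnotation::VCF(
        rowRanges = gr,
        colData = DataFrame(Samples = seq_along(samples),
                            row.names = samples),
        exptData = list(header = hdr),
        fixed = DataFrame(
            REF = Biostrings::DNAStringSet(rd$ref),
            ALT = Biostrings::DNAStringSetList(as.list(rd$allele)),
            QUAL = rep(NA_real_, nrow(rd)),
            FILTER = rep(".", nrow(rd))),
        geno = S4Vectors::SimpleList(DS = DS))
    VariantAnnotation::writeVcf(vcf, path)
    invisible(path)
}

#' Read a dosage VCF back into a matrix
#'
#' @param path VCF written by [writeDosageVcf()].
#' @return numeric markers-by-lines matrix of the `DS` field.
#' @export
readDosageVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    ds <- VariantAnnotation::geno(vcf)$DS
    if (is.null(ds)) stop("VCF has no DS dosage field")
    mat <- matrix(as.numeric(ds), nrow(ds), ncol(ds),
                  dimnames = dimnames(ds))
    mat
}
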