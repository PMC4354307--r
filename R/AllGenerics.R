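#' @include AllClasses.R
NULL

#' Accessors for tetraQK objects
#'
#' Small accessor generics: `qMatrix()` returns the membership matrix of
#' an [AdmixtureFit-class] (or the true Q of a [TruePanel-class]);
#' `dosageMatrix()` returns a lines-by-marker-allele copy-number matrix
#' from a [DosagePanel-class]; `varComponents()` and `adjustedMeans()`
#' extract pieces of a [SpatialFit-class]; `lineIds()` lists panel
#' lines.
#'
#' @param object an object of the documented classes.
#' @return see details per method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qMatrix", function(object) standardGeneric("qMatrix"))

#' @rdname accessors
#' @export
setMethod("qMatrix", "AdmixtureFit", function(object) object@Q)

#' @rdname accessors
#' @export
setMethod("qMatrix", "TruePanel", function(object) object@Q)

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(object, ...)
    standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @param role optionally restrict to `"structure"` or `"candidate"`
#'   marker-allele rows.
#' @param ... passed between methods.
#' @export
setMethod("dosageMatrix", "DosagePanel", function(object, role = NULL) {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!is.null(role)) {
        keep <- SummarizedExperiment::rowData(object)$role %in% role
        d <- d[keep, , drop = FALSE]
    }
    t(d)
})

#' @rdname accessors
#' @export
setGeneric("varComponents", function(object)
    standardGeneric("varComponents"))

#' @rdname accessors
#' @export
setMethod("varComponents", "SpatialFit", function(object)
    c(object@varComponents, object@rho))

#' @rdname accessors
#' @export
setGeneric("adjustedMeans", function(object, ...)
    standardGeneric("adjustedMeans"))

#' @rdname accessors
#' @export
setGeneric("lineIds", function(object) standardGeneric("lineIds"))

#' @rdname accessors
#' @export
setMethod("lineIds", "TruePanel", function(object) object@lineIds)

#' @rdname accessors
#' @export
setMethod("lineIds", "DosagePanel", function(object) colnames(object))

#' @rdname accessors
#' @export
setMethod("lineIds", "FieldTrial", function(object)
    sort(unique(object@plots$line_id)))
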