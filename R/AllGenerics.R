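#' Accessors for gshscreen containers
#'
#' @param x An object.
#' @param name For [getTrack()], the track class to extract (one of
#'   `"ucr"`, `"dnase"`, `"gene_tx"`, `"tss"`, `"cancer_gene"`, `"mirna"`,
#'   `"lncrna"`, `"tad_border"`).
#' @return `getTrack` returns a `GRanges`; `trackNames` and `tissueNames`
#'   character vectors; `chromLengths` a named numeric vector; `buffers` the
#'   named buffer vector; `compartmentLabels` the bins x tissues label
#'   matrix; accessors on `GshResult` return the corresponding slot.
#' @name gshscreen-accessors
NULL

#' @rdname gshscreen-accessors
#' @export
setGeneric("getTrack", function(x, name) standardGeneric("getTrack"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("trackNames", function(x) standardGeneric("trackNames"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("buffers", function(x) standardGeneric("buffers"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("compartmentBins", function(x) standardGeneric("compartmentBins"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("compartmentLabels",
           function(x) standardGeneric("compartmentLabels"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("tissueNames", function(x) standardGeneric("tissueNames"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("safeSites", function(x) standardGeneric("safeSites"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("activeRegions", function(x) standardGeneric("activeRegions"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("candidateTable", function(x) standardGeneric("candidateTable"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("housekeepingGenes", function(x) standardGeneric("housekeepingGenes"))

#' @rdname gshscreen-accessors
#' @export
setGeneric("funnelCounts", function(x) standardGeneric("funnelCounts"))

#' @rdname gshscreen-accessors
#' @export
setMethod("getTrack", "AnnotationSet", function(x, name) {
    name <- match.arg(name, .TRACK_CLASSES)
    x@tracks[[name]]
})

#' @rdname gshscreen-accessors
#' @export
setMethod("trackNames", "AnnotationSet", function(x) names(x@tracks))

#' @rdname gshscreen-accessors
#' @export
setMethod("chromLengths", "AnnotationSet", function(x) {
    sl <- GenomeInfoDb::seqlengths(x@seqinfo)
    stats::setNames(as.numeric(sl), names(sl))
})

#' @rdname gshscreen-accessors
#' @export
setMethod("buffers", "ExclusionPolicy", function(x) x@buffers)

#' @rdname gshscreen-accessors
#' @export
setMethod("compartmentBins", "CompartmentCalls", function(x) x@bins)

#' @rdname gshscreen-accessors
#' @export
setMethod("compartmentLabels", "CompartmentCalls", function(x) x@labels)

#' @rdname gshscreen-accessors
#' @export
setMethod("tissueNames", "CompartmentCalls", function(x) colnames(x@labels))

#' @rdname gshscreen-accessors
#' @export
setMethod("safeSites", "GshResult", function(x) x@safeSites)

#' @rdname gshscreen-accessors
#' @export
setMethod("activeRegions", "GshResult", function(x) x@activeRegions)

#' @rdname gshscreen-accessors
#' @export
setMethod("candidates", "GshResult", function(x) x@candidates)

#' @rdname gshscreen-accessors
#' @export
setMethod("candidateTable", "GshResult", function(x) x@table)

#' @rdname gshscreen-accessors
#' @export
setMethod("housekeepingGenes", "GshResult", function(x) x@housekeeping)

#' @rdname gshscreen-accessors
#' @export
setMethod("funnelCounts", "GshResult", function(x) x@funnel)

setMethod("show", "AnnotationSet", function(object) {
    n <- vapply(object@tracks, length, integer(1))
    cat("AnnotationSet with", length(GenomeInfoDb::seqlevels(object@seqinfo)),
        "chromosomes\n")
    cat("  features per track:\n")
    for (nm in names(n)) cat(sprintf("    %-12s %d\n", nm, n[[nm]]))
})

setMethod("show", "ExclusionPolicy", function(object) {
    cat("ExclusionPolicy (buffer bp):\n")
    b <- object@buffers
    for (nm in names(b)) cat(sprintf("  %-12s %s\n", nm, format(b[[nm]], big.mark = ",")))
})

setMethod("show", "CompartmentCalls", function(object) {
    cat("CompartmentCalls:", length(object@bins), "bins x",
        ncol(object@labels), "tissues (",
        format(object@binSize, big.mark = ","), "bp grid )\n")
    cat("  A calls:", sum(object@labels == "A", na.rm = TRUE),
        " B calls:", sum(object@labels == "B", na.rm = TRUE),
        " missing:", sum(is.na(object@labels)), "\n")
})

setMethod("show", "GshResult", function(object) {
    cat("GshResult - screening funnel:\n")
    f <- object@funnel
    for (nm in names(f)) cat(sprintf("  %-22s %d\n", nm, f[[nm]]))
})
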