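#' Tile the genome into fixed-size bins
#'
#' Per chromosome, bins `[k*size + 1, (k+1)*size]` for `k = 0, 1, ...`,
#' with the final partial bin truncated at the chromosome length. The 1-Mb
#' default matches the compartment-call grid (e.g. the bin containing
#' position 113,289,036 of chromosome 1 is 113000001-114000000).
#'
#' @param chromLengths Named chromosome lengths.
#' @param binSize Bin width in bp (default 1 Mb).
#' @return Sorted `GRanges` of bins.
#' @examples
#' binGenome(c(chr1 = 2.5e6))
#' @export
binGenome <- function(chromLengths, binSize = 1e6) {
    stopifnot(binSize >= 1)
    chromLengths <- .checkChromLengths(chromLengths)
    si <- .asSeqinfo(chromLengths)
    grl <- lapply(names(chromLengths), function(chrom) {
        L <- chromLengths[[chrom]]
        s <- seq(1, L, by = binSize)
        GRanges(chrom, IRanges(s, pmin(s + binSize - 1, L)), seqinfo = si)
    })
    sort(do.call(c, grl))
}

#' Bins consistently in the active (A) compartment across tissues
#'
#' Keeps the bins whose absolute count of A calls reaches `minActive`
#' (default: one less than the number of tissues, i.e. "at least 20 of
#' 21"). By default a bin with missing calls in some tissues must still
#' reach `minActive` in absolute count, so a bin unlabelled in more than
#' `total - minActive` tissues can never qualify; `proportional = TRUE`
#' instead requires `A / called >= minActive / total` among labelled
#' tissues.
#'
#' @param calls A [CompartmentCalls-class] object.
#' @param minActive Minimum number of A calls (default `total - 1`).
#' @param proportional Use the proportional rule for missing calls.
#' @return `GRanges` of retained bins with metadata columns
#'   `n_active_tissues` and `n_tissues_with_call`.
#' @export
consistentActive <- function(calls, minActive = NULL, proportional = FALSE) {
    stopifnot(is(calls, "CompartmentCalls"))
    lab <- compartmentLabels(calls)
    total <- ncol(lab)
    if (is.null(minActive)) minActive <- total - 1L
    if (minActive > total)
        stop("minActive (", minActive, ") exceeds the tissue count (", total, ")")
    nA <- rowSums(lab == "A", na.rm = TRUE)
    nCalled <- rowSums(!is.na(lab))
    keep <- if (proportional) nCalled > 0L & nA / nCalled >= minActive / total
            else nA >= minActive
    out <- compartmentBins(calls)[keep]
    out$n_active_tissues <- as.integer(nA[keep])
    out$n_tissues_with_call <- as.integer(nCalled[keep])
    out
}

#' Keep active bins that overlap a housekeeping gene
#'
#' A bin is retained when at least 1 bp of a selected housekeeping gene's
#' body lies inside it (a gene straddling a bin border therefore keeps
#' both bins). Overlapping gene ids are recorded in genomic order.
#' Housekeeping genes without a location are logged and skipped.
#'
#' @param regions Active bins from [consistentActive()].
#' @param hkGenes Character vector of housekeeping gene ids.
#' @param geneLocations `GRanges` of gene bodies carrying a `gene_id`
#'   metadata column (or names).
#' @return The retained bins with a `housekeeping_genes` `CharacterList`
#'   metadata column.
#' @export
attachHousekeeping <- function(regions, hkGenes, geneLocations) {
    ids <- mcols(geneLocations)$gene_id
    if (is.null(ids)) ids <- names(geneLocations)
    if (is.null(ids)) stop("geneLocations must carry gene ids")
    missing <- setdiff(hkGenes, ids)
    if (length(missing))
        message(length(missing),
                " housekeeping gene(s) without a location skipped: ",
                paste(head(missing, 5L), collapse = ", "))
    sel <- ids %in% hkGenes
    loc <- granges(geneLocations)[sel]
    loc$gene_id <- ids[sel]
    loc <- sort(loc, ignore.strand = TRUE)
    hits <- findOverlaps(regions, loc, minoverlap = 1L, ignore.strand = TRUE)
    genes <- S4Vectors::splitAsList(loc$gene_id[subjectHits(hits)],
                                    factor(queryHits(hits),
                                           levels = seq_along(regions)))
    keep <- lengths(genes) > 0L
    out <- regions[keep]
    out$housekeeping_genes <- genes[keep]
    out
}
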