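#' Expand features by a symmetric buffer, clipped to the chromosome
#'
#' Each interval becomes `[max(1, start - buffer), min(L, end + buffer)]`
#' where `L` is the chromosome length. The buffered zone is inclusive on
#' both sides, so "more than N bp away" is strict: a base exactly N bp from
#' a feature still falls inside the zone.
#'
#' @param gr Feature `GRanges`.
#' @param buffer Non-negative buffer in bp.
#' @param chromLengths Named chromosome lengths; a feature on a chromosome
#'   absent from the map is an error.
#' @return Unstranded `GRanges` of buffered zones.
#' @examples
#' bufferIntervals(GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000)),
#'                 2000, c(chr1 = 1e6))
#' @export
bufferIntervals <- function(gr, buffer, chromLengths) {
    stopifnot(length(buffer) == 1L, !is.na(buffer), buffer >= 0)
    chromLengths <- .checkChromLengths(chromLengths)
    if (length(gr) == 0L)
        return(GRanges(seqinfo = .asSeqinfo(chromLengths)))
    chrom <- as.character(seqnames(gr))
    if (!all(chrom %in% names(chromLengths)))
        stop("feature chromosome(s) absent from the map: ",
             paste(unique(setdiff(chrom, names(chromLengths))), collapse = ", "))
    GRanges(chrom,
            IRanges(pmax(1, start(gr) - buffer),
                    pmin(chromLengths[chrom], end(gr) + buffer)),
            seqinfo = .asSeqinfo(chromLengths))
}

#' Merge intervals into a sorted disjoint set
#'
#' Overlapping and book-ended (gap 0) closed intervals are merged; output
#' is sorted by chromosome then start; covered bases are preserved.
#'
#' @param gr A `GRanges`.
#' @return Sorted disjoint unstranded `GRanges`.
#' @export
mergeIntervals <- function(gr) {
    sort(reduce(granges(gr), ignore.strand = TRUE), ignore.strand = TRUE)
}

#' Complement of an interval set over the mapped genome
#'
#' Returns the maximal intervals covering exactly the bases of every mapped
#' chromosome not covered by the input. Chromosomes with no input interval
#' return one full-length interval.
#'
#' @param gr Interval `GRanges` (any chromosomes outside the map are
#'   dropped with a message).
#' @param chromLengths Named chromosome lengths.
#' @return Sorted disjoint `GRanges` covering the uncovered bases.
#' @export
complementIntervals <- function(gr, chromLengths) {
    chromLengths <- .checkChromLengths(chromLengths)
    si <- .asSeqinfo(chromLengths)
    genome <- GRanges(names(chromLengths), IRanges(1, chromLengths),
                      seqinfo = si)
    gr <- .conformToMap(granges(gr), chromLengths, what = "intervals")
    sort(GenomicRanges::setdiff(genome, gr, ignore.strand = TRUE))
}

#' Genome-wide safe sites from buffered exclusion zones
#'
#' Applies all exclusion criteria simultaneously: every feature track is
#' expanded by its class buffer (see [exclusionPolicy()]), the zones are
#' unioned, and the safe set is the complement over the mapped genome.
#' Because the criteria enter a single union, their order cannot matter.
#' Single-base safe sites are retained (no minimum width). An empty track
#' is allowed but logged prominently, since it silently weakens the screen.
#'
#' @param annotations An [AnnotationSet-class] carrying the seven excluded
#'   tracks (`ucr`, `dnase`, `tss`, `gene_tx`, `cancer_gene`, `mirna`,
#'   `lncrna`) and the chromosome map.
#' @param policy An [ExclusionPolicy-class]; defaults to
#'   [exclusionPolicy()].
#' @param quiet Suppress the per-stage count log.
#' @return Sorted `GRanges` of safe intervals.
#' @examples
#' ann <- AnnotationSet(c(chr1 = 1e6),
#'                      tss = GenomicRanges::GRanges("chr1",
#'                            IRanges::IRanges(500000, 500000)))
#' findSafeSites(ann)
#' @export
findSafeSites <- function(annotations, policy = exclusionPolicy(),
                          quiet = FALSE) {
    stopifnot(is(annotations, "AnnotationSet"), is(policy, "ExclusionPolicy"))
    cl <- chromLengths(annotations)
    buf <- buffers(policy)
    zones <- vector("list", length(buf))
    names(zones) <- names(buf)
    for (cls in names(buf)) {
        trk <- getTrack(annotations, cls)
        if (length(trk) == 0L)
            message("NOTE: exclusion track '", cls,
                    "' is empty; this criterion is not constraining the screen")
        zones[[cls]] <- bufferIntervals(trk, buf[[cls]], cl)
    }
    excl <- mergeIntervals(do.call(c, unname(zones)))
    safe <- complementIntervals(excl, cl)
    if (!quiet) {
        nfeat <- vapply(names(buf), function(cls)
            length(getTrack(annotations, cls)), integer(1))
        message("safety filter: ",
                paste(sprintf("%s=%d", names(nfeat), nfeat), collapse = " "),
                "; excluded bases ", sum(width(excl)),
                "; safe sites ", length(safe),
                if (length(safe)) paste0(" (width ", min(width(safe)), "-",
                                         max(width(safe)), " bp)") else "")
    }
    safe
}
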