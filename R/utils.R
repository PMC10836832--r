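# Internal helpers shared across modules.

# Validate a chromosome-length map: named integer-ish vector, lengths >= 1.
.checkChromLengths <- function(chromLengths) {
    if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
        stop("chromosome lengths must be a named vector")
    if (anyDuplicated(names(chromLengths)))
        stop("duplicated chromosome names in the chromosome map")
    if (!is.numeric(chromLengths) || any(is.na(chromLengths)) ||
        any(chromLengths < 1) || any(chromLengths != round(chromLengths)))
        stop("chromosome lengths must be positive integers")
    stats::setNames(as.numeric(chromLengths), names(chromLengths))
}

.asSeqinfo <- function(chromLengths) {
    chromLengths <- .checkChromLengths(chromLengths)
    GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                          seqlengths = as.integer(chromLengths))
}

# Drop ranges on chromosomes absent from the map (logged), attach seqinfo,
# and fail on ranges running past the chromosome end.
.conformToMap <- function(gr, chromLengths, what = "features") {
    chromLengths <- .checkChromLengths(chromLengths)
    chrom <- as.character(seqnames(gr))
    unmapped <- !(chrom %in% names(chromLengths))
    if (any(unmapped)) {
        message(sum(unmapped), " ", what,
                " on chromosomes absent from the map dropped (",
                paste(unique(chrom[unmapped]), collapse = ", "), ")")
        gr <- gr[!unmapped]
        chrom <- chrom[!unmapped]
    }
    over <- end(gr) > chromLengths[chrom]
    if (any(over))
        stop("interval end exceeds chromosome length for ",
             paste(head(paste0(chrom[over], ":", start(gr)[over], "-",
                               end(gr)[over]), 3L), collapse = ", "))
    mc <- mcols(gr, use.names = FALSE)
    out <- GRanges(chrom, ranges(gr), strand = strand(gr),
                   seqinfo = .asSeqinfo(chromLengths))
    mcols(out) <- mc
    out
}

# Minimal positional distance between each query and any subject on the same
# chromosome: 0 when overlapping, 1 when book-ended, Inf when the chromosome
# carries no subject. This is the "N bp away" convention of the screen: a
# base at positional distance d from a feature end is d bp away from it.
.positionalDistance <- function(query, subject) {
    out <- rep(Inf, length(query))
    if (length(subject) == 0L || length(query) == 0L)
        return(out)
    # chromosomes carrying no subject are a legitimate input (distance Inf),
    # so the cross-seqlevel chatter from the nearest-neighbour search is
    # silenced here
    hit <- suppressWarnings(GenomicRanges::distanceToNearest(
        query, subject, ignore.strand = TRUE))
    qh <- queryHits(hit)
    out[qh] <- mcols(hit)$distance + 1L
    ov <- suppressWarnings(countOverlaps(query, subject,
                                         ignore.strand = TRUE)) > 0L
    out[ov] <- 0
    out
}

# Stable candidate identifiers used to key BLAT results.
.queryIds <- function(gr) {
    sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr), end(gr))
}

.stripChr <- function(x) sub("^chr", "", x)
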