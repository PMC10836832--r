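# Independent per-base boolean-mask oracles for interval algebra, used to
# cross-check the GRanges-based implementations on toy chromosomes.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

# One logical vector per chromosome, TRUE where covered.
maskFromIntervals <- function(gr, chromLengths, buffer = 0) {
    masks <- lapply(chromLengths, function(L) logical(L))
    for (i in seq_along(gr)) {
        chrom <- as.character(seqnames(gr))[i]
        L <- chromLengths[[chrom]]
        s <- max(1, start(gr)[i] - buffer)
        e <- min(L, end(gr)[i] + buffer)
        masks[[chrom]][s:e] <- TRUE
    }
    masks
}

# Maximal TRUE runs of a mask set back to a sorted GRanges.
intervalsFromMask <- function(masks) {
    chroms <- character(0); s <- integer(0); e <- integer(0)
    for (chrom in names(masks)) {
        r <- rle(masks[[chrom]])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values
        chroms <- c(chroms, rep(chrom, sum(keep)))
        s <- c(s, starts[keep]); e <- c(e, ends[keep])
    }
    sort(GRanges(chroms, IRanges(s, e)))
}

# Oracle safe sites: per-base union of buffered tracks, complemented.
oracleSafeSites <- function(tracks, buffers, chromLengths) {
    masks <- lapply(chromLengths, function(L) logical(L))
    for (cls in names(buffers)) {
        gr <- tracks[[cls]]
        if (is.null(gr) || length(gr) == 0L) next
        m <- maskFromIntervals(gr, chromLengths, buffer = buffers[[cls]])
        for (chrom in names(masks))
            masks[[chrom]] <- masks[[chrom]] | m[[chrom]]
    }
    intervalsFromMask(lapply(masks, `!`))
}

randomIntervals <- function(n, chromLengths, maxWidth = 2000) {
    chrom <- sample(names(chromLengths), n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    s <- vapply(seq_len(n), function(i)
        sample.int(chromLengths[[chrom[i]]] - w[i] + 1L, 1L), integer(1))
    sort(GRanges(chrom, IRanges(s, s + w - 1L)))
}

grEqual <- function(a, b) {
    if (length(a) != length(b)) return(FALSE)
    key <- function(g) {
        k <- paste0(as.character(seqnames(g)), ":", start(g), "-", end(g))
        sort(k)
    }
    identical(key(a), key(b))
}
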