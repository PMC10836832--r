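#' Intersect safe sites with active regions
#'
#' Each safe interval is clipped to every active 1-Mb bin it overlaps;
#' clipped pieces of width >= 1 become candidate sites carrying the bin's
#' coordinates, tissue counts and housekeeping gene(s). A safe interval
#' spanning two active bins yields two candidates. `mode = "within"`
#' instead requires the safe interval to lie entirely inside the bin.
#' Exact duplicate intervals (if any) are removed and logged.
#'
#' @param safe Safe-site `GRanges` from [findSafeSites()].
#' @param regions Active bins from [attachHousekeeping()].
#' @param mode `"clip"` (default) or `"within"`.
#' @return Candidate `GRanges` with metadata columns `query_id`,
#'   `active_start`, `active_end`, `housekeeping_genes` and, when present
#'   on `regions`, `n_active_tissues`.
#' @export
intersectSafeActive <- function(safe, regions, mode = c("clip", "within")) {
    mode <- match.arg(mode)
    if (length(safe) == 0L || length(regions) == 0L) {
        warning("empty ", if (length(safe) == 0L) "safe-site" else "active-region",
                " input: no candidates")
        out <- GRanges()
        out$query_id <- character(0)
        return(out)
    }
    type <- if (mode == "within") "within" else "any"
    hits <- findOverlaps(safe, regions, type = type, ignore.strand = TRUE)
    piece <- pintersect(granges(safe)[queryHits(hits)],
                        granges(regions)[subjectHits(hits)],
                        ignore.strand = TRUE)
    mcols(piece) <- NULL
    sub <- subjectHits(hits)
    piece$query_id <- .queryIds(piece)
    piece$active_start <- start(regions)[sub]
    piece$active_end <- end(regions)[sub]
    if (!is.null(regions$housekeeping_genes))
        piece$housekeeping_genes <- regions$housekeeping_genes[sub]
    if (!is.null(regions$n_active_tissues))
        piece$n_active_tissues <- regions$n_active_tissues[sub]
    dup <- duplicated(piece$query_id)
    if (any(dup)) {
        message(sum(dup), " exact duplicate candidate interval(s) removed")
        piece <- piece[!dup]
    }
    sort(piece, ignore.strand = TRUE)
}

#' Split a long query into overlapping BLAT segments
#'
#' Queries at most `maxLen` bp (the web-BLAT input limit, 25 kb) go in one
#' piece. Longer queries are cut into the smallest number of equal-length
#' segments whose length lies in `[segMin, segMax]` (9-11 kb), evenly
#' spaced so that consecutive segments overlap by at least 1 bp and the
#' union covers the whole query. The target overlap fraction steers the
#' segment length via `L = ceiling(len * (1 + overlapFrac) / n)`.
#'
#' @param queryLength Query length in bp (>= 1).
#' @param maxLen Single-segment limit (default 25,000).
#' @param segMin,segMax Allowed segment-length band (defaults 9,000 and
#'   11,000).
#' @param overlapFrac Target total overlap as a fraction of the query
#'   length (default 0.1).
#' @return `data.frame` with columns `offset` (0-based) and `length`.
#' @examples
#' splitQuery(30000)
#' @export
splitQuery <- function(queryLength, maxLen = 25000, segMin = 9000,
                       segMax = 11000, overlapFrac = 0.1) {
    stopifnot(queryLength >= 1, segMin >= 1, overlapFrac >= 0)
    if (segMax < segMin)
        stop("infeasible segment bounds: segMax (", segMax,
             ") < segMin (", segMin, ")")
    if (queryLength <= maxLen)
        return(data.frame(offset = 0, length = queryLength))
    n <- max(2L, ceiling(queryLength / segMax))
    repeat {
        L <- ceiling(queryLength * (1 + overlapFrac) / n)
        L <- min(max(L, segMin), segMax)
        if (n * L >= queryLength + (n - 1L)) break
        n <- n + 1L
        if (n > queryLength)
            stop("cannot split query of length ", queryLength,
                 " into segments within [", segMin, ", ", segMax,
                 "] at overlapFrac ", overlapFrac)
    }
    offsets <- round((0:(n - 1L)) * (queryLength - L) / (n - 1L))
    data.frame(offset = offsets, length = L)
}

# Aggregate per-query ratios, resolving segment results ("<id>/seg<k>")
# by the maximum segment ratio: a candidate is only as unique as its
# least-unique segment.
.candidateRatios <- function(queryIds, results) {
    results <- as.data.frame(results)
    if (!"ratio" %in% names(results)) {
        if (all(c("query_id", "score") %in% names(results)))
            results <- as.data.frame(
                .blatFromScores(as.character(results$query_id),
                                as.numeric(results$score)))
        else stop("BLAT results must carry a 'ratio' column or query_id/score")
    }
    rq <- as.character(results$query)
    base <- sub("/seg[0-9]+$", "", rq)
    agg <- tapply(results$ratio, base, max)
    ratio <- as.numeric(agg[queryIds])
    miss <- is.na(ratio) & !(queryIds %in% names(agg))
    if (any(miss))
        stop("no BLAT result for candidate(s): ",
             paste(head(queryIds[miss], 5L), collapse = ", "))
    ratio
}

#' Flag candidates by BLAT uniqueness ratio
#'
#' The uniqueness ratio of a candidate is the second-best BLAT hit score
#' divided by the top score (the top hit being the candidate locus
#' itself). Candidates pass when the ratio is at most `threshold` (strict
#' "over 0.5" is filtered). Results for split queries (`"<id>/seg<k>"`)
#' are aggregated by the maximum segment ratio. A candidate with no BLAT
#' result is an error listing the missing query ids.
#'
#' @param candidates Candidate `GRanges` with a `query_id` column (see
#'   [intersectSafeActive()]).
#' @param results BLAT results: a `DataFrame`/`data.frame` with `query`
#'   and `ratio` columns ([readPsl()], [readBlatScores()]) or a raw
#'   `query_id`/`score` table.
#' @param threshold Pass threshold (default 0.5, inclusive).
#' @return `candidates` with `blat_ratio` and `passed_blat` columns set.
#' @export
uniquenessFilter <- function(candidates, results, threshold = 0.5) {
    if (length(candidates) == 0L) {
        candidates$blat_ratio <- numeric(0)
        candidates$passed_blat <- logical(0)
        return(candidates)
    }
    if (is.null(candidates$query_id))
        candidates$query_id <- .queryIds(candidates)
    ratio <- .candidateRatios(candidates$query_id, results)
    candidates$blat_ratio <- ratio
    candidates$passed_blat <- ratio <= threshold
    candidates
}

#' Report candidate distance to the nearest TAD border
#'
#' Computes, per candidate, the minimal positional distance to any TAD
#' border on the same chromosome (0 when overlapping a border) and flags
#' whether it exceeds `minDist` (strict "more than 80 kb away"). The flag
#' is report-only -- it never drops candidates -- matching its role as a
#' post-hoc check on the shortlisted sites. A chromosome without borders
#' gives distance `Inf` and a `TRUE` flag.
#'
#' @param candidates Candidate `GRanges`.
#' @param tadBorders Border `GRanges` (points or intervals).
#' @param minDist Distance threshold in bp (default 80,000).
#' @return `candidates` with `tad_border_distance` and `tad_clear` columns.
#' @export
tadBorderCheck <- function(candidates, tadBorders, minDist = 80000) {
    d <- .positionalDistance(candidates, tadBorders)
    candidates$tad_border_distance <- d
    candidates$tad_clear <- d > minDist
    candidates
}

#' Draw validation candidates by rounded uniform sampling
#'
#' Reproduces the historical selection procedure: repeatedly draw
#' `u ~ Uniform(1, total)`, round half-to-even to an integer, reject
#' duplicates, until `n` distinct indices are collected. Note the
#' endpoint artefact this inherits: indices 1 and `total` receive half
#' the probability of interior indices.
#'
#' @param n Number of indices to draw (default 7).
#' @param total Number of candidates to draw from (default 25).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of `n` distinct 1-based indices, in draw order.
#' @export
pickValidationCandidates <- function(n = 7L, total = 25L, seed = NULL) {
    if (n > total) stop("cannot draw ", n, " distinct indices from ", total)
    if (!is.null(seed)) set.seed(seed)
    picked <- integer(0)
    guard <- 0L
    while (length(picked) < n) {
        i <- as.integer(round(stats::runif(1L, min = 1, max = total)))
        if (!(i %in% picked)) picked <- c(picked, i)
        guard <- guard + 1L
        if (guard > 1e6L) stop("sampling did not terminate")
    }
    picked
}

#' Emit the candidate table
#'
#' One row per candidate with chromosome, start, end, width
#' (`end - start + 1`), active-region bounds, housekeeping gene(s), BLAT
#' ratio and flags, sorted by chromosome (in map order) then start.
#'
#' @param candidates Candidate `GRanges`.
#' @param chromOrder Optional chromosome ordering (defaults to the
#'   seqlevels of `candidates`).
#' @return A `data.frame`.
#' @export
emitCandidateTable <- function(candidates, chromOrder = NULL) {
    if (is.null(chromOrder)) chromOrder <- GenomeInfoDb::seqlevels(candidates)
    chrom <- as.character(seqnames(candidates))
    hk <- candidates$housekeeping_genes
    hkCol <- if (is.null(hk)) rep(NA_character_, length(candidates))
             else vapply(as.list(hk), function(g)
                 paste(g, collapse = ","), character(1))
    grab <- function(col, default) {
        v <- mcols(candidates)[[col]]
        if (is.null(v)) rep(default, length(candidates)) else v
    }
    df <- data.frame(
        chrom = chrom,
        start = start(candidates),
        end = end(candidates),
        width = end(candidates) - start(candidates) + 1L,
        active_start = grab("active_start", NA_integer_),
        active_end = grab("active_end", NA_integer_),
        housekeeping_gene = hkCol,
        blat_ratio = grab("blat_ratio", NA_real_),
        passed_blat = grab("passed_blat", NA),
        tad_border_distance = grab("tad_border_distance", NA_real_),
        shortlisted = grab("shortlisted", NA))
    df[order(match(df$chrom, chromOrder), df$start), , drop = FALSE]
}

#' Write a candidate table as TSV
#'
#' @param table Output of [emitCandidateTable()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCandidateTable <- function(table, path) {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write candidates as BED6 with the uniqueness ratio as score
#'
#' The BED score column carries `round(1000 * blat_ratio)`.
#'
#' @param candidates Candidate `GRanges`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCandidateBed <- function(candidates, path) {
    ratio <- candidates$blat_ratio
    if (is.null(ratio)) ratio <- rep(0, length(candidates))
    gr <- granges(candidates)
    gr$name <- if (is.null(candidates$query_id)) .queryIds(candidates)
               else candidates$query_id
    writeBed(gr, path, scores = as.integer(round(1000 * ratio)))
}
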