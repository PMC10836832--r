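#' Read a BED3/BED6 file as 1-based closed intervals
#'
#' BED is 0-based half-open; internal coordinates are 1-based closed (so an
#' interval's width is `end - start + 1`). Conversion happens here, at the
#' boundary: `start_internal = start_bed + 1`, `end_internal = end_bed`.
#' Optional columns 4-6 supply name, score and strand. Malformed lines are
#' reported with their line numbers.
#'
#' @param path Path to a BED file. `track`/`browser`/`#` lines are skipped.
#' @param trackClass Feature class tag recorded in `mcols(.)$feature_class`.
#' @param chromLengths Optional named chromosome lengths; when given,
#'   features on unmapped chromosomes are dropped with a message and an
#'   interval end past the chromosome length is an error.
#' @param stripChrPrefix Drop a leading `"chr"` from chromosome names.
#' @return A `GRanges` with metadata columns `name` and `feature_class`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t99\t200\tsite1\t0\t+", bed)
#' readBed(bed, "dnase")
#' @export
readBed <- function(path, trackClass = "region", chromLengths = NULL,
                    stripChrPrefix = FALSE) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lineNo <- seq_along(lines)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    lines <- lines[keep]; lineNo <- lineNo[keep]
    if (length(lines) == 0L)
        return(GRanges(name = character(0), feature_class = character(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED line ", lineNo[which(nf < 3L)[1L]], ": fewer than 3 fields")
    chrom <- vapply(fields, `[`, character(1), 1L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    bad <- is.na(s) | is.na(e) | s < 0 | e <= s
    if (any(bad))
        stop("BED line ", lineNo[which(bad)[1L]],
             ": invalid coordinates (need 0 <= start < end)")
    name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4L], character(1)), NA)
    str <- ifelse(nf >= 6L, vapply(fields, function(f) f[6L], character(1)), "*")
    str[!str %in% c("+", "-")] <- "*"
    if (stripChrPrefix) chrom <- .stripChr(chrom)
    gr <- GRanges(chrom, IRanges(s + 1L, e), strand = str,
                  name = as.character(name), feature_class = trackClass)
    if (!is.null(chromLengths))
        gr <- .conformToMap(gr, chromLengths, what = "BED features")
    gr
}

#' Write intervals as BED6
#'
#' Converts the internal 1-based closed intervals back to BED's 0-based
#' half-open convention, so `readBed(writeBed(x))` round-trips.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param scores Optional numeric score column (default 0).
#' @return The path, invisibly.
#' @export
writeBed <- function(gr, path, scores = NULL) {
    name <- mcols(gr)$name
    if (is.null(name)) name <- rep(".", length(gr))
    name[is.na(name)] <- "."
    if (is.null(scores)) scores <- rep(0L, length(gr))
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     name = name, score = scores, strand = str)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a flattened gene table and derive TSS / biotype tracks
#'
#' The contract is a tab-separated table with header columns `chrom`,
#' `start` (1-based), `end`, `strand`, `gene_id`, `biotype`. Each row yields
#' one transcription-unit record; a width-1 TSS record is derived at the
#' gene start for `+` strand and at the gene end for `-` strand. Rows with
#' biotype `miRNA` / `lncRNA` are additionally emitted on the corresponding
#' noncoding tracks.
#'
#' @param path Path to the gene table.
#' @param chromLengths Optional chromosome-length map (see [readBed()]).
#' @param stripChrPrefix Drop a leading `"chr"` from chromosome names.
#' @return A named list of `GRanges`: `gene_tx`, `tss`, `mirna`, `lncrna`.
#' @export
readGeneTable <- function(path, chromLengths = NULL, stripChrPrefix = FALSE) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "gene_id", "biotype")
    if (!all(need %in% names(df)))
        stop("gene table must have columns: ", paste(need, collapse = ", "))
    badStrand <- !df$strand %in% c("+", "-")
    if (any(badStrand))
        stop("cannot derive TSS: unknown strand for gene(s) ",
             paste(head(df$gene_id[badStrand], 5L), collapse = ", "))
    chrom <- if (stripChrPrefix) .stripChr(df$chrom) else df$chrom
    genes <- GRanges(chrom, IRanges(df$start, df$end), strand = df$strand,
                     name = df$gene_id, feature_class = "gene_tx",
                     gene_id = df$gene_id, biotype = df$biotype)
    if (!is.null(chromLengths))
        genes <- .conformToMap(genes, chromLengths, what = "genes")
    tss <- promoters(genes, upstream = 0L, downstream = 1L)
    tss$feature_class <- "tss"
    mk <- function(sel, cls) { g <- genes[sel]; g$feature_class <- cls; g }
    list(gene_tx = genes, tss = tss,
         mirna = mk(genes$biotype == "miRNA", "mirna"),
         lncrna = mk(genes$biotype == "lncRNA", "lncrna"))
}

#' Read a chromosome-length table
#'
#' Two tab-separated columns: chromosome name and length in bp. A header
#' line is detected (second field non-numeric) and skipped.
#'
#' @param path Path to the table.
#' @return Named numeric vector of lengths.
#' @export
readChromLengths <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("chromosome-length table needs two columns")
    if (is.na(suppressWarnings(as.numeric(df[1L, 2L]))))
        df <- df[-1L, , drop = FALSE]
    .checkChromLengths(stats::setNames(as.numeric(df[[2L]]),
                                       as.character(df[[1L]])))
}

#' Read a gene x tissue median-TPM matrix in GCT format
#'
#' GCT dialect: line 1 a version tag, line 2 `"nGenes nTissues"`, line 3 a
#' header `Name`, `Description`, then one column per tissue. Dimensions are
#' checked against the declaration; genes with any missing tissue value are
#' dropped (logged); duplicate gene identifiers are resolved by keeping the
#' row with the higher mean (logged); negative values are an error.
#'
#' @param path Path to the GCT file.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `tpm`,
#'   genes as rows and tissues as columns.
#' @export
readExpressionGct <- function(path) {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L) stop("truncated GCT file")
    dims <- suppressWarnings(as.integer(strsplit(trimws(hdr[2L]), "[ \t]+")[[1L]]))
    if (length(dims) < 2L || any(is.na(dims[1:2])))
        stop("GCT line 2 must declare 'nGenes nTissues'")
    df <- read.delim(path, skip = 2L, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("GCT table needs Name, Description and tissues")
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
        stop("GCT declared dimensions (", dims[1L], " x ", dims[2L],
             ") disagree with parsed table (", nrow(df), " x ",
             ncol(df) - 2L, ")")
    mat <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- df[[1L]]
    miss <- apply(mat, 1L, anyNA)
    if (any(miss)) {
        message(sum(miss), " gene(s) with missing tissue values dropped")
        mat <- mat[!miss, , drop = FALSE]
        df <- df[!miss, , drop = FALSE]
    }
    if (any(mat < 0)) stop("negative TPM value in GCT input")
    if (anyDuplicated(rownames(mat))) {
        rm <- rowMeans(mat)
        ord <- order(rownames(mat), -rm)
        mat <- mat[ord, , drop = FALSE]; df <- df[ord, , drop = FALSE]
        dup <- duplicated(rownames(mat))
        message(sum(dup), " duplicate gene id(s): kept the higher-mean row")
        mat <- mat[!dup, , drop = FALSE]; df <- df[!dup, , drop = FALSE]
    }
    SummarizedExperiment(
        assays = list(tpm = mat),
        rowData = S4Vectors::DataFrame(description = df[[2L]],
                                       row.names = rownames(mat)),
        colData = S4Vectors::DataFrame(tissue = colnames(mat),
                                       row.names = colnames(mat)))
}

#' Write a gene x tissue matrix as GCT
#'
#' @param mat Numeric matrix (genes x tissues) with dimnames, or a
#'   `SummarizedExperiment` with a `tpm` assay.
#' @param path Output path.
#' @param description Optional per-gene description column.
#' @return The path, invisibly.
#' @export
writeGct <- function(mat, path, description = NULL) {
    if (is(mat, "SummarizedExperiment")) mat <- assay(mat, "tpm")
    if (is.null(description)) description <- rownames(mat)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
    df <- data.frame(Name = rownames(mat), Description = description,
                     mat, check.names = FALSE)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
    invisible(path)
}

# UCSC web-BLAT score of one PSL row.
.pslScore <- function(matches, repMatches, misMatches, qNumInsert, tNumInsert) {
    matches + repMatches - misMatches - qNumInsert - tNumInsert
}

.blatFromScores <- function(query, score) {
    o <- order(query, -score)
    query <- query[o]; score <- score[o]
    grp <- split(score, factor(query, levels = unique(query)))
    top <- vapply(grp, `[`, numeric(1), 1L)
    second <- vapply(grp, function(s) if (length(s) >= 2L) s[2L] else NA_real_, numeric(1))
    ratio <- ifelse(is.na(second) | top <= 0, 0, second / top)
    S4Vectors::DataFrame(query = names(grp), n_hits = lengths(grp),
                         top_score = unname(top), second_score = unname(second),
                         ratio = unname(ratio))
}

#' Read BLAT results from PSL and compute uniqueness ratios
#'
#' Per alignment the documented UCSC web-BLAT score
#' `matches + repMatches - misMatches - qNumInsert - tNumInsert` is
#' computed; per query, hit scores are sorted descending and the uniqueness
#' ratio is the second score divided by the top score (0 when a query has a
#' single hit). A ratio near 1 means the query has a near-identical match
#' elsewhere in the genome.
#'
#' @param path Path to a PSL file (21 columns, headerless or with the
#'   5-line `psLayout` header).
#' @return A `DataFrame` with columns `query`, `n_hits`, `top_score`,
#'   `second_score`, `ratio`.
#' @export
readPsl <- function(path) {
    lines <- readLines(path)
    if (length(lines) > 0L && grepl("^psLayout", lines[1L])) {
        if (length(lines) < 6L) stop("truncated PSL header")
        lines <- lines[-(1:5)]
    }
    lineNo <- seq_along(lines)
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]; lineNo <- lineNo[keep]
    if (length(lines) == 0L)
        return(S4Vectors::DataFrame(query = character(0), n_hits = integer(0),
                                    top_score = numeric(0),
                                    second_score = numeric(0),
                                    ratio = numeric(0)))
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 21L))
        stop("PSL line ", lineNo[which(nf < 21L)[1L]], ": fewer than 21 columns")
    num <- function(i) as.numeric(vapply(fields, `[`, character(1), i))
    score <- .pslScore(num(1L), num(3L), num(2L), num(5L), num(7L))
    query <- vapply(fields, `[`, character(1), 10L)
    .blatFromScores(query, score)
}

#' Read BLAT results from a plain score table
#'
#' Alternative to [readPsl()] for users supplying their own scorer: a
#' tab-separated table with header columns `query_id` and `score`, one row
#' per hit. Ratios are computed exactly as for PSL input.
#'
#' @param path Path to the score table.
#' @return A `DataFrame`, as [readPsl()].
#' @export
readBlatScores <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("query_id", "score") %in% names(df)))
        stop("score table must have columns query_id and score")
    if (any(is.na(df$score)) || any(df$score < 0))
        stop("scores must be non-negative numbers")
    .blatFromScores(as.character(df$query_id), as.numeric(df$score))
}

#' Write a score table as minimal PSL
#'
#' Emits one 21-column PSL line per hit with the score in the `matches`
#' field and zero mismatches/inserts, so [readPsl()] recovers the same
#' scores. Used by the synthetic-data generator to exercise the PSL path.
#'
#' @param scoreTable `data.frame` with columns `query_id` and `score`.
#' @param path Output path.
#' @param header Write the 5-line `psLayout` header.
#' @return The path, invisibly.
#' @export
writePsl <- function(scoreTable, path, header = TRUE) {
    s <- as.integer(round(scoreTable$score))
    row <- paste(s, 0L, 0L, 0L, 0L, 0L, 0L, 0L, "+",
                 scoreTable$query_id, 11000L, 0L, s,
                 "chrT", 10000000L, 0L, s, 1L,
                 paste0(s, ","), "0,", "0,", sep = "\t")
    if (header)
        row <- c("psLayout version 3", "",
                 "match\tmis-\trep.\tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\tQ\tQ\tQ\tQ\tT\tT\tT\tT\tblock\tblockSizes\tqStarts\ttStarts",
                 "\tmatch\tmatch\t\tcount\tbases\tcount\tbases\t\tname\tsize\tstart\tend\tname\tsize\tstart\tend\tcount",
                 paste(rep("-", 80), collapse = ""), row)
    writeLines(row, path)
    invisible(path)
}

#' Read per-tissue A/B compartment calls
#'
#' Tab-separated with header columns `tissue`, `chrom`, `bin_start`,
#' `bin_end`, `label` (`A`, `B` or `missing`). Bins must lie on the 1-Mb
#' grid (`bin_start` congruent to 1 modulo the bin size) and, when
#' chromosome lengths are supplied, only the last bin of a chromosome may
#' be shorter than the grid. Duplicate (tissue, bin) calls with conflicting
#' labels are an error.
#'
#' @param path Path to the call table.
#' @param chromLengths Optional chromosome-length map.
#' @param binSize Grid size in bp (default 1 Mb).
#' @return A [CompartmentCalls-class] object.
#' @export
readCompartmentCalls <- function(path, chromLengths = NULL, binSize = 1e6) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("tissue", "chrom", "bin_start", "bin_end", "label")
    if (!all(need %in% names(df)))
        stop("compartment table must have columns: ",
             paste(need, collapse = ", "))
    if (any((df$bin_start - 1) %% binSize != 0))
        stop("bin_start values must lie on the ", binSize, " bp grid")
    full <- df$bin_end - df$bin_start + 1 == binSize
    if (!is.null(chromLengths)) {
        chromLengths <- .checkChromLengths(chromLengths)
        lastOk <- df$bin_end == chromLengths[df$chrom]
        if (any(!full & !lastOk, na.rm = TRUE))
            stop("short bin that is not the last bin of its chromosome")
    }
    df$label[df$label == "missing"] <- NA_character_
    if (!all(df$label %in% c("A", "B") | is.na(df$label)))
        stop("labels must be A, B or missing")
    key <- paste(df$chrom, df$bin_start, df$bin_end, sep = ":")
    tk <- paste(df$tissue, key, sep = "|")
    if (anyDuplicated(tk)) {
        lab <- split(df$label, tk)
        bad <- vapply(lab, function(l) length(unique(l)) > 1L, logical(1))
        if (any(bad))
            stop("conflicting duplicate calls for ", names(lab)[bad][1L])
        keep <- !duplicated(tk)
        df <- df[keep, , drop = FALSE]
        key <- key[keep]
    }
    ubin <- unique(df[, c("chrom", "bin_start", "bin_end")])
    ubin <- ubin[order(ubin$chrom, ubin$bin_start), , drop = FALSE]
    bins <- GRanges(ubin$chrom, IRanges(ubin$bin_start, ubin$bin_end))
    if (!is.null(chromLengths)) bins <- .conformToMap(bins, chromLengths,
                                                      what = "bins")
    tissues <- sort(unique(df$tissue))
    lab <- matrix(NA_character_, length(bins), length(tissues),
                  dimnames = list(NULL, tissues))
    ukey <- paste(ubin$chrom, ubin$bin_start, ubin$bin_end, sep = ":")
    lab[cbind(match(key, ukey), match(df$tissue, tissues))] <- df$label
    CompartmentCalls(bins, lab, binSize = binSize)
}

#' Write compartment calls as the long-format TSV read by
#' [readCompartmentCalls()]
#'
#' @param calls A [CompartmentCalls-class] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCompartmentCalls <- function(calls, path) {
    bins <- compartmentBins(calls)
    lab <- compartmentLabels(calls)
    df <- data.frame(
        tissue = rep(colnames(lab), each = length(bins)),
        chrom = rep(as.character(seqnames(bins)), ncol(lab)),
        bin_start = rep(start(bins), ncol(lab)),
        bin_end = rep(end(bins), ncol(lab)),
        label = as.vector(lab))
    df$label[is.na(df$label)] <- "missing"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
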