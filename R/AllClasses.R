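#' @title Container classes
#' @description S4 classes holding the annotation tracks, the exclusion
#'   policy, per-tissue compartment calls and a pipeline run.
#' @name gshscreen-classes
NULL

.TRACK_CLASSES <- c("ucr", "dnase", "gene_tx", "tss", "cancer_gene",
                    "mirna", "lncrna", "tad_border")

#' AnnotationSet: named feature tracks over a fixed chromosome map
#'
#' Holds one [GenomicRanges::GRanges] per feature track (ultra-conserved
#' regions, DNase clusters, gene transcription units, transcription start
#' sites, cancer genes, miRNAs, lncRNAs, TAD borders) together with the
#' chromosome lengths that anchor every downstream interval operation.
#' Features on chromosomes absent from the map are dropped with a message;
#' features running past a chromosome end are an error.
#'
#' @slot tracks A [S4Vectors::SimpleList] of `GRanges`, one per track class.
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with one entry per chromosome.
#' @export
setClass("AnnotationSet",
         slots = c(tracks = "SimpleList", seqinfo = "Seqinfo"))

setValidity("AnnotationSet", function(object) {
    trk <- object@tracks
    if (!all(names(trk) %in% .TRACK_CLASSES))
        return(paste("unknown track class:",
                     paste(setdiff(names(trk), .TRACK_CLASSES), collapse = ", ")))
    if (!all(vapply(trk, is, logical(1), "GRanges")))
        return("all tracks must be GRanges")
    sl <- GenomeInfoDb::seqlengths(object@seqinfo)
    for (nm in names(trk)) {
        gr <- trk[[nm]]
        if (length(gr) == 0L) next
        chrom <- as.character(seqnames(gr))
        if (!all(chrom %in% names(sl)))
            return(paste0("track '", nm, "' has chromosomes outside the map"))
        if (any(start(gr) < 1L))
            return(paste0("track '", nm, "' has starts < 1"))
        if (any(end(gr) > sl[chrom]))
            return(paste0("track '", nm, "' runs past a chromosome end"))
    }
    TRUE
})

#' Build an AnnotationSet
#'
#' @param chromLengths Named vector of chromosome lengths in bp.
#' @param ucr,dnase,geneTx,tss,cancerGene,mirna,lncrna,tadBorder `GRanges`
#'   feature tracks (1-based closed coordinates). Any may be empty.
#' @return An [AnnotationSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000))
#' ann <- AnnotationSet(c(chr1 = 1e6), dnase = gr)
#' trackNames(ann)
#' @export
AnnotationSet <- function(chromLengths,
                          ucr = GRanges(), dnase = GRanges(),
                          geneTx = GRanges(), tss = GRanges(),
                          cancerGene = GRanges(), mirna = GRanges(),
                          lncrna = GRanges(), tadBorder = GRanges()) {
    chromLengths <- .checkChromLengths(chromLengths)
    trk <- S4Vectors::SimpleList(
        ucr = ucr, dnase = dnase, gene_tx = geneTx, tss = tss,
        cancer_gene = cancerGene, mirna = mirna, lncrna = lncrna,
        tad_border = tadBorder)
    trk <- S4Vectors::endoapply(trk, .conformToMap, chromLengths)
    new("AnnotationSet", tracks = trk, seqinfo = .asSeqinfo(chromLengths))
}

#' ExclusionPolicy: per-track buffer widths for the safety filter
#'
#' The buffer is the "more than N bp away" distance of each criterion: the
#' buffered exclusion zone of a feature is the feature body extended by the
#' buffer on both sides, inclusive, so a base exactly N bp from a feature is
#' still excluded (strict "more than N away").
#'
#' @slot buffers Named non-negative numeric, one entry per excluded class.
#' @export
setClass("ExclusionPolicy", slots = c(buffers = "numeric"))

setValidity("ExclusionPolicy", function(object) {
    need <- c("ucr", "dnase", "tss", "gene_tx", "cancer_gene", "mirna", "lncrna")
    if (!identical(sort(names(object@buffers)), sort(need)))
        return("buffers must name exactly the seven excluded classes")
    if (any(object@buffers < 0) || any(is.na(object@buffers)))
        return("buffers must be non-negative")
    TRUE
})

#' Default exclusion-zone policy
#'
#' Defaults encode the screen's criteria: ultra-conserved regions and gene
#' transcription units excluded as-is (buffer 0), DNase clusters +/- 2 kb,
#' transcription start sites +/- 50 kb, cancer genes and miRNAs +/- 300 kb,
#' lncRNAs +/- 100 kb.
#'
#' @param ucr,dnase,tss,geneTx,cancerGene,mirna,lncrna Buffer widths in bp.
#' @return An [ExclusionPolicy-class] object.
#' @examples
#' buffers(exclusionPolicy())
#' @export
exclusionPolicy <- function(ucr = 0, dnase = 2000, tss = 50000, geneTx = 0,
                            cancerGene = 300000, mirna = 300000,
                            lncrna = 100000) {
    new("ExclusionPolicy", buffers = c(
        ucr = unname(ucr), dnase = unname(dnase), tss = unname(tss),
        gene_tx = unname(geneTx), cancer_gene = unname(cancerGene),
        mirna = unname(mirna), lncrna = unname(lncrna)))
}

#' CompartmentCalls: per-tissue A/B labels over the 1-Mb genome grid
#'
#' @slot bins `GRanges` of grid-aligned 1-Mb bins (start congruent to 1
#'   modulo the bin size; the last bin of a chromosome may be truncated).
#' @slot labels Character matrix, bins x tissues, entries "A", "B" or `NA`
#'   (no call in that tissue).
#' @slot binSize Bin width in bp.
#' @export
setClass("CompartmentCalls",
         slots = c(bins = "GRanges", labels = "matrix", binSize = "numeric"))

setValidity("CompartmentCalls", function(object) {
    if (nrow(object@labels) != length(object@bins))
        return("label matrix rows must match the number of bins")
    if (is.null(colnames(object@labels)))
        return("label matrix must carry tissue names")
    bad <- !(object@labels %in% c("A", "B") | is.na(object@labels))
    if (any(bad))
        return("labels must be 'A', 'B' or NA")
    if (any((start(object@bins) - 1) %% object@binSize != 0))
        return("bin starts must lie on the grid")
    TRUE
})

#' Construct CompartmentCalls from bins and a label matrix
#'
#' @param bins Grid-aligned `GRanges` bins.
#' @param labels Character matrix (bins x tissues) of "A"/"B"/`NA` calls.
#' @param binSize Grid size in bp (default 1 Mb).
#' @return A [CompartmentCalls-class] object.
#' @export
CompartmentCalls <- function(bins, labels, binSize = 1e6) {
    labels[labels %in% "missing"] <- NA_character_
    new("CompartmentCalls", bins = granges(bins), labels = labels,
        binSize = binSize)
}

#' GshResult: one full run of the screening funnel
#'
#' @slot safeSites `GRanges` of safe intervals (safety filter output).
#' @slot geneStats `DataFrame` of per-gene expression statistics.
#' @slot housekeeping Character vector of selected housekeeping gene ids.
#' @slot activeRegions `GRanges` of consistently active 1-Mb bins carrying
#'   at least one housekeeping gene.
#' @slot candidates `GRanges` of candidate sites with BLAT and TAD metadata.
#' @slot table The final candidate table (`data.frame`).
#' @slot funnel Named integer vector of per-stage counts.
#' @slot params The thresholds used for the run.
#' @export
setClass("GshResult",
         slots = c(safeSites = "GRanges", geneStats = "DFrame",
                   housekeeping = "character", activeRegions = "GRanges",
                   candidates = "GRanges", table = "data.frame",
                   funnel = "integer", params = "list"))
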