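#' Run the full GSH screening funnel
#'
#' Chains the four stages: (1) safety filtering into genome-wide safe
#' sites, (2) housekeeping-gene selection from the expression matrix,
#' (3) consistently active 1-Mb bins overlapping a housekeeping gene,
#' (4) safe-by-active intersection, BLAT uniqueness filtering and the
#' TAD-border report. Per-stage counts are logged and kept in the result,
#' mirroring the safe sites -> active regions -> overlaps -> final
#' shortlist funnel.
#'
#' @param annotations An [AnnotationSet-class].
#' @param expression `SummarizedExperiment` (assay `tpm`) or genes x
#'   tissues matrix.
#' @param compartments A [CompartmentCalls-class].
#' @param blatResults BLAT results (see [uniquenessFilter()]); `NULL`
#'   skips the uniqueness filter with a message.
#' @param policy [ExclusionPolicy-class] for the safety filter.
#' @param span Lowess span for the variance trend.
#' @param fdrMin,meanTpmMin,requireVarBelowTrend Housekeeping thresholds
#'   (see [selectHousekeeping()]).
#' @param minActive,proportional Compartment-consistency rule (see
#'   [consistentActive()]).
#' @param blatThreshold Uniqueness-ratio pass threshold (default 0.5).
#' @param dropFailedBlat Drop candidates failing the uniqueness filter
#'   from the final table (default TRUE; they remain, flagged, in
#'   `candidates(result)`).
#' @param intersectMode `"clip"` or `"within"` (see
#'   [intersectSafeActive()]).
#' @param geneLocations Optional `GRanges` of gene bodies with `gene_id`;
#'   defaults to the annotation set's `gene_tx` track.
#' @param quiet Suppress progress messages.
#' @return A [GshResult-class].
#' @export
runGshPipeline <- function(annotations, expression, compartments,
                           blatResults = NULL, policy = exclusionPolicy(),
                           span = 0.3, fdrMin = 0.9, meanTpmMin = 5,
                           requireVarBelowTrend = TRUE, minActive = NULL,
                           proportional = FALSE, blatThreshold = 0.5,
                           dropFailedBlat = TRUE,
                           intersectMode = c("clip", "within"),
                           geneLocations = NULL, quiet = FALSE) {
    intersectMode <- match.arg(intersectMode)
    if (is.null(geneLocations)) geneLocations <- getTrack(annotations, "gene_tx")

    safe <- findSafeSites(annotations, policy, quiet = quiet)

    hk <- screenHousekeeping(expression, span = span, fdrMin = fdrMin,
                             meanTpmMin = meanTpmMin,
                             requireVarBelowTrend = requireVarBelowTrend)

    active <- consistentActive(compartments, minActive = minActive,
                               proportional = proportional)
    activeHk <- attachHousekeeping(active, hk$genes, geneLocations)

    cand <- intersectSafeActive(safe, activeHk, mode = intersectMode)
    if (!is.null(blatResults)) {
        cand <- uniquenessFilter(cand, blatResults, threshold = blatThreshold)
    } else {
        if (!quiet) message("no BLAT results supplied: uniqueness filter skipped")
        cand$blat_ratio <- rep(NA_real_, length(cand))
        cand$passed_blat <- rep(NA, length(cand))
    }
    tad <- getTrack(annotations, "tad_border")
    if (length(tad) > 0L) cand <- tadBorderCheck(cand, tad)

    final <- if (dropFailedBlat && !is.null(blatResults))
        cand[cand$passed_blat] else cand
    tab <- emitCandidateTable(final,
                              chromOrder = names(chromLengths(annotations)))

    funnel <- c(safe_sites = length(safe),
                housekeeping_genes = length(hk$genes),
                active_bins = length(active),
                active_hk_regions = length(activeHk),
                safe_active_overlaps = length(cand),
                final_candidates = length(final))
    if (!quiet)
        message("funnel: ", paste(sprintf("%s=%d", names(funnel), funnel),
                                  collapse = " -> "))
    new("GshResult", safeSites = safe, geneStats = hk$stats,
        housekeeping = hk$genes, activeRegions = activeHk,
        candidates = cand, table = tab, funnel = funnel,
        params = list(policy = buffers(policy), span = span, fdrMin = fdrMin,
                      meanTpmMin = meanTpmMin, minActive = minActive,
                      proportional = proportional,
                      blatThreshold = blatThreshold,
                      intersectMode = intersectMode))
}

#' The bundled 25-candidate GRCh38 reference shortlist
#'
#' Loads the reference table of 25 putative GSH loci on GRCh38 shipped
#' with the package: per candidate its coordinates, width, associated
#' active 1-Mb region and housekeeping gene, BLAT uniqueness ratio, and
#' whether it was shortlisted for in-vitro validation. Used in examples
#' and as a fixed arithmetic check of the table-emission conventions
#' (width = end - start + 1; ratio threshold 0.5).
#'
#' @return A `data.frame` with 25 rows.
#' @examples
#' ref <- referenceCandidates()
#' all(ref$width == ref$end - ref$start + 1)
#' @export
referenceCandidates <- function() {
    path <- system.file("extdata", "gsh_candidates_grch38.tsv",
                        package = "gshscreen", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE,
               colClasses = c(chrom = "character"))
}

#' Read pipeline thresholds from a YAML/JSON config file
#'
#' Recognised keys: the seven buffer names under `buffers`, plus `span`,
#' `fdr_min`, `mean_tpm_min`, `min_active`, `proportional`,
#' `blat_threshold`, `intersect_mode`, `strip_chr_prefix`. Missing keys
#' fall back to package defaults.
#'
#' @param path Path to a YAML (or JSON) config file.
#' @return A list with elements `policy` (an [ExclusionPolicy-class]) and
#'   the remaining thresholds.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
           else yaml::read_yaml(path)
    b <- cfg$buffers
    pol <- exclusionPolicy(
        ucr = b$ucr %||% 0, dnase = b$dnase %||% 2000,
        tss = b$tss %||% 50000, geneTx = b$gene_tx %||% 0,
        cancerGene = b$cancer_gene %||% 300000, mirna = b$mirna %||% 300000,
        lncrna = b$lncrna %||% 100000)
    list(policy = pol,
         span = cfg$span %||% 0.3,
         fdrMin = cfg$fdr_min %||% 0.9,
         meanTpmMin = cfg$mean_tpm_min %||% 5,
         minActive = cfg$min_active,
         proportional = isTRUE(cfg$proportional),
         blatThreshold = cfg$blat_threshold %||% 0.5,
         intersectMode = cfg$intersect_mode %||% "clip",
         stripChrPrefix = isTRUE(cfg$strip_chr_prefix))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest
#'
#' Records the thresholds, per-stage funnel counts and optional seed of a
#' pipeline run for provenance.
#'
#' @param result A [GshResult-class].
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return The path, invisibly.
#' @export
writeRunManifest <- function(result, path, seed = NULL) {
    jsonlite::write_json(
        list(params = result@params, funnel = as.list(result@funnel),
             seed = seed),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    invisible(path)
}
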