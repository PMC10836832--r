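#' Configuration for the synthetic-data generator
#'
#' Defines a toy genome with planted ground truth: safe-and-active GSH
#' intervals that pass every default exclusion buffer, housekeeping genes
#' with low cross-tissue variance, mostly-A compartment bins, and a
#' controllable fraction of candidates with a near-duplicate BLAT hit.
#' The same seed always reproduces byte-identical outputs.
#'
#' @param nChromosomes Number of chromosomes (default 2).
#' @param chromLength Chromosome length in bp (default 10 Mb).
#' @param nPlantedGsh Number of planted unique GSH loci (default 3).
#' @param nGenes Number of protein-coding genes in the expression matrix
#'   (default 1000).
#' @param nTissues Number of tissues (default 21, the compartment panel).
#' @param hkFraction Fraction of genes that are housekeeping (default
#'   0.05, i.e. 50 of 1000).
#' @param compartmentNoise Probability that a planted-A bin is mislabelled
#'   B in a given tissue (default 0.02).
#' @param dupFraction Fraction of planted candidates carrying a
#'   near-duplicate second BLAT hit (ratio in (0.5, 1); default 0.25).
#' @param featureDensity Background features per Mb for the `ucr`,
#'   `dnase`, `cancer_gene`, `mirna`, `lncrna` tracks.
#' @param hkMeanRange Range of housekeeping mean TPM (default c(5, 50)).
#' @param plantedHkMeanMin Lower mean-TPM bound for the housekeeping genes
#'   sitting in planted bins, kept away from the 5-TPM selection boundary
#'   so the planted truth is never boundary-ambiguous (default 8).
#' @param hkCv Coefficient of variation of housekeeping expression across
#'   tissues (default 0.05).
#' @param varBreadthRange Range of expression breadth for tissue-variable
#'   genes: each is expressed in `k` tissues, `k` uniform over this range
#'   (default c(1, 17) of 21). Varying breadth at a narrow on-level makes
#'   the variable class trace a smooth mean-variance relation; the upper
#'   bound stays clear of the tissue count because a gene on in all but
#'   one tissue is, by construction, nearly housekeeping.
#' @param varOnLevelRange Range of the on-tissue expression level of
#'   variable genes in TPM (default c(95, 105)): a narrow common level
#'   concentrates the variable class's variability statistic well away
#'   from the housekeeping class, so the planted contrast is separable.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A `list` of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nChromosomes = 2L, chromLength = 1e7,
                            nPlantedGsh = 3L, nGenes = 1000L, nTissues = 21L,
                            hkFraction = 0.05, compartmentNoise = 0.02,
                            dupFraction = 0.25,
                            featureDensity = c(ucr = 1, dnase = 2,
                                               cancer_gene = 0.2,
                                               mirna = 0.3, lncrna = 0.5),
                            hkMeanRange = c(5, 50), plantedHkMeanMin = 8,
                            hkCv = 0.05, varBreadthRange = c(1L, 17L),
                            varOnLevelRange = c(95, 105), seed = 1L) {
    frac <- c(hkFraction, compartmentNoise, dupFraction)
    if (any(frac < 0) || any(frac > 1))
        stop("fractions must lie in [0, 1]")
    if (any(featureDensity < 0)) stop("densities must be non-negative")
    if (nTissues < 3L) stop("need at least 3 tissues")
    structure(list(nChromosomes = as.integer(nChromosomes),
                   chromLength = chromLength, nPlantedGsh = as.integer(nPlantedGsh),
                   nGenes = as.integer(nGenes), nTissues = as.integer(nTissues),
                   hkFraction = hkFraction, compartmentNoise = compartmentNoise,
                   dupFraction = dupFraction, featureDensity = featureDensity,
                   hkMeanRange = hkMeanRange, plantedHkMeanMin = plantedHkMeanMin,
                   hkCv = hkCv,
                   varBreadthRange = as.integer(varBreadthRange),
                   varOnLevelRange = varOnLevelRange,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

# GRanges anchored to the full chromosome map (shared Seqinfo keeps every
# downstream combination and overlap warning-free).
.grOnMap <- function(chrom, start, end, chromLengths) {
    GRanges(factor(chrom, levels = names(chromLengths)),
            IRanges(start, end), seqinfo = .asSeqinfo(chromLengths))
}

# Place n intervals uniformly, rejecting any whose class-buffered zone
# would intrude into a planted GSH interval. Vectorised rejection sampling.
.placeAvoiding <- function(n, widths, chromLengths, avoid, buffer,
                           maxTries = 60L) {
    if (n == 0L)
        return(GRanges(seqinfo = .asSeqinfo(chromLengths)))
    widths <- rep_len(widths, n)
    chroms <- names(chromLengths)
    prob <- chromLengths / sum(chromLengths)
    avoidBuf <- if (length(avoid))
        .grOnMap(as.character(seqnames(avoid)),
                 pmax(1, start(avoid) - buffer),
                 pmin(chromLengths[as.character(seqnames(avoid))],
                      end(avoid) + buffer), chromLengths)
        else NULL
    chrom <- character(n); s <- numeric(n)
    need <- seq_len(n)
    for (try in seq_len(maxTries)) {
        chrom[need] <- sample(chroms, length(need), replace = TRUE,
                              prob = prob)
        maxStart <- chromLengths[chrom[need]] - widths[need] + 1
        s[need] <- floor(stats::runif(length(need)) * pmax(maxStart, 1)) + 1
        bad <- maxStart < 1
        if (!is.null(avoidBuf)) {
            cand <- .grOnMap(chrom[need], s[need],
                             s[need] + widths[need] - 1, chromLengths)
            bad <- bad | countOverlaps(cand, avoidBuf,
                                       ignore.strand = TRUE) > 0L
        }
        need <- need[bad]
        if (length(need) == 0L) break
    }
    if (length(need))
        stop("could not place ", length(need), " feature(s) away from the ",
             "planted GSH; the configuration is too dense for the planted sites")
    sort(.grOnMap(chrom, s, s + widths - 1, chromLengths),
         ignore.strand = TRUE)
}

#' Generate a synthetic genome, expression matrix, compartment calls and
#' BLAT scores with a planted-truth manifest
#'
#' The construction guarantees, not merely encourages, the planted truth:
#'
#' * each planted candidate sits in its own interior 1-Mb bin, flanked by
#'   DNase "filler" clusters whose 2-kb buffers end exactly at the
#'   candidate's edges, so the bin's safe set is exactly the planted
#'   interval;
#' * a housekeeping gene occupies the same bin, 50 kb clear of the
#'   candidate;
#' * background features are rejection-sampled so no buffered exclusion
#'   zone intrudes into a planted interval;
#' * planted bins are labelled A in each tissue with probability
#'   `1 - compartmentNoise`; all other bins are A with probability 0.3;
#' * a `dupFraction` share of planted candidates ("decoys") receive a
#'   second BLAT hit with ratio in (0.5, 1) and must be removed by the
#'   uniqueness filter; the remaining candidates get ratios between 0 and
#'   0.3.
#'
#' All randomness flows from `config$seed` through per-section sub-seeds
#' (drawn once up front), so each section is reproducible independently.
#'
#' @param config A [syntheticConfig()] list.
#' @return A list with elements `annotations` ([AnnotationSet-class]),
#'   `expression` (`SummarizedExperiment`), `compartments`
#'   ([CompartmentCalls-class]), `blatScores` (`data.frame` of
#'   `query_id`/`score` rows), `geneTable` (`data.frame`), `manifest`
#'   (planted truth: `planted_gsh`, `planted_hk_genes`,
#'   `planted_active_bins`, `planted_nonunique_candidates`) and `config`.
#' @examples
#' syn <- generateSyntheticData(syntheticConfig(seed = 7))
#' syn$manifest$planted_gsh
#' @export
generateSyntheticData <- function(config = syntheticConfig()) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed)
    sectionSeeds <- sample.int(.Machine$integer.max - 1L, 6L)

    chromLengths <- stats::setNames(rep(config$chromLength,
                                        config$nChromosomes),
                                    paste0("chr", seq_len(config$nChromosomes)))
    binSize <- 1e6
    nBinsPerChrom <- floor(config$chromLength / binSize)
    if (nBinsPerChrom < 3L)
        stop("chromLength must cover at least 3 Mb to host interior planted bins")

    nDecoys <- if (config$dupFraction > 0)
        max(1L, round(config$nPlantedGsh * config$dupFraction /
                      (1 - config$dupFraction))) else 0L
    nPlanted <- config$nPlantedGsh + nDecoys

    ## -- planted bins: interior, pairwise >= 2 bins apart on a chromosome
    set.seed(sectionSeeds[1L])
    slots <- expand.grid(chrom = names(chromLengths),
                         k = seq(1L, nBinsPerChrom - 2L, by = 2L),
                         stringsAsFactors = FALSE)
    if (nrow(slots) < nPlanted)
        stop("cannot place ", nPlanted, " planted candidates: only ",
             nrow(slots), " well-separated interior 1-Mb bins available; ",
             "increase chromLength or nChromosomes")
    slots <- slots[sample.int(nrow(slots), nPlanted), , drop = FALSE]
    binStart <- slots$k * binSize + 1
    gshWidth <- sample(250:4500, nPlanted, replace = TRUE)
    gshStart <- binStart + 4e5 - 1
    planted <- .grOnMap(slots$chrom, gshStart, gshStart + gshWidth - 1,
                        chromLengths)
    plantedBins <- .grOnMap(slots$chrom, binStart, binStart + binSize - 1,
                            chromLengths)
    isDecoy <- rep(c(FALSE, TRUE), c(config$nPlantedGsh, nDecoys))

    ## DNase fillers: their +/- 2 kb buffers cover the planted bin except
    ## exactly the planted interval.
    fillerL <- .grOnMap(slots$chrom, pmax(1, binStart - 2000),
                        start(planted) - 2001, chromLengths)
    fillerR <- .grOnMap(slots$chrom, end(planted) + 2001,
                        pmin(config$chromLength,
                             binStart + binSize - 1 + 2000), chromLengths)

    ## -- genes ------------------------------------------------------------
    set.seed(sectionSeeds[2L])
    nHk <- round(config$hkFraction * config$nGenes)
    nVar <- config$nGenes - nHk
    hkIds <- sprintf("HK%04d", seq_len(max(nHk, 0L)))
    varIds <- sprintf("VAR%04d", seq_len(max(nVar, 0L)))
    nPlantedHk <- min(nPlanted, nHk)
    plantedHkGr <- .grOnMap(slots$chrom[seq_len(nPlantedHk)],
                            binStart[seq_len(nPlantedHk)] + 6e5 - 1,
                            binStart[seq_len(nPlantedHk)] + 6e5 - 1 + 39999,
                            chromLengths)
    freeHk <- .placeAvoiding(nHk - nPlantedHk,
                             sample(20000:50000, max(nHk - nPlantedHk, 0L),
                                    replace = TRUE),
                             chromLengths, planted, buffer = 51000)
    varGr <- .placeAvoiding(nVar, sample(5000:50000, max(nVar, 0L),
                                         replace = TRUE),
                            chromLengths, planted, buffer = 51000)
    dens <- config$featureDensity
    genomeMb <- sum(chromLengths) / 1e6
    nMir <- round((dens[["mirna"]] %||% 0) * genomeMb)
    nLnc <- round((dens[["lncrna"]] %||% 0) * genomeMb)
    mirGr <- .placeAvoiding(nMir, 80, chromLengths, planted, buffer = 301000)
    lncGr <- .placeAvoiding(nLnc, sample(200:2000, max(nLnc, 0L), replace = TRUE),
                            chromLengths, planted, buffer = 101000)

    geneGr <- c(plantedHkGr, freeHk, varGr, mirGr, lncGr)
    geneTable <- data.frame(
        chrom = as.character(seqnames(geneGr)),
        start = start(geneGr), end = end(geneGr),
        strand = sample(c("+", "-"), length(geneGr), replace = TRUE),
        gene_id = c(hkIds[seq_len(nPlantedHk)],
                    hkIds[setdiff(seq_len(nHk), seq_len(nPlantedHk))],
                    varIds,
                    sprintf("MIR%03d", seq_len(nMir)),
                    sprintf("LNC%03d", seq_len(nLnc))),
        biotype = c(rep("protein_coding", nHk + nVar),
                    rep("miRNA", nMir), rep("lncRNA", nLnc)))
    ## planted housekeeping genes are plus-strand so the TSS (gene start)
    ## sits 50 kb clear of the planted interval by construction
    geneTable$strand[seq_len(nPlantedHk)] <- "+"

    ## -- background exclusion features ------------------------------------
    set.seed(sectionSeeds[3L])
    nUcr <- round((dens[["ucr"]] %||% 0) * genomeMb)
    nDnase <- round((dens[["dnase"]] %||% 0) * genomeMb)
    nCancer <- round((dens[["cancer_gene"]] %||% 0) * genomeMb)
    ucrGr <- .placeAvoiding(nUcr, sample(200:400, max(nUcr, 0L), replace = TRUE),
                            chromLengths, planted, buffer = 1000)
    dnaseBg <- .placeAvoiding(nDnase, sample(150:1000, max(nDnase, 0L),
                                             replace = TRUE),
                              chromLengths, planted, buffer = 3000)
    cancerGr <- .placeAvoiding(nCancer, sample(20000:100000, max(nCancer, 0L),
                                               replace = TRUE),
                               chromLengths, planted, buffer = 301000)
    dnaseGr <- sort(c(granges(fillerL), granges(fillerR), granges(dnaseBg)),
                    ignore.strand = TRUE)
    tadPos <- lapply(names(chromLengths), function(chrom)
        seq(2e6, chromLengths[[chrom]] - 1e6, by = 2e6))
    tadGr <- .grOnMap(rep(names(chromLengths), lengths(tadPos)),
                      unlist(tadPos), unlist(tadPos), chromLengths)

    ## -- assemble annotation set ------------------------------------------
    tracks <- local({
        g <- GRanges(geneTable$chrom, IRanges(geneTable$start, geneTable$end),
                     strand = geneTable$strand, name = geneTable$gene_id,
                     feature_class = "gene_tx", gene_id = geneTable$gene_id,
                     biotype = geneTable$biotype)
        tss <- promoters(g, upstream = 0L, downstream = 1L)
        tss$feature_class <- "tss"
        list(gene_tx = g, tss = tss,
             mirna = g[g$biotype == "miRNA"],
             lncrna = g[g$biotype == "lncRNA"])
    })
    annotations <- AnnotationSet(chromLengths,
                                 ucr = ucrGr, dnase = dnaseGr,
                                 geneTx = tracks$gene_tx, tss = tracks$tss,
                                 cancerGene = cancerGr,
                                 mirna = tracks$mirna, lncrna = tracks$lncrna,
                                 tadBorder = tadGr)

    ## -- expression matrix -------------------------------------------------
    set.seed(sectionSeeds[4L])
    tissues <- sprintf("tissue%02d", seq_len(config$nTissues))
    mat <- matrix(0, nrow = nHk + nVar, ncol = config$nTissues,
                  dimnames = list(c(hkIds, varIds), tissues))
    if (nHk > 0L) {
        mu <- stats::runif(nHk, config$hkMeanRange[1L], config$hkMeanRange[2L])
        if (nPlantedHk > 0L) {
            lo <- min(max(config$plantedHkMeanMin, config$hkMeanRange[1L]),
                      config$hkMeanRange[2L])
            mu[seq_len(nPlantedHk)] <- stats::runif(nPlantedHk, lo,
                                                    config$hkMeanRange[2L])
        }
        mat[seq_len(nHk), ] <- pmax(0, mu + stats::rnorm(
            nHk * config$nTissues, sd = config$hkCv * mu))
    }
    if (nVar > 0L) {
        br <- config$varBreadthRange
        for (i in seq_len(nVar)) {
            k <- sample(br[1L]:br[2L], 1L)
            on <- sample.int(config$nTissues, k)
            lev <- stats::runif(1L, config$varOnLevelRange[1L],
                                config$varOnLevelRange[2L])
            row <- stats::runif(config$nTissues, 0, 0.3)
            row[on] <- pmax(0, lev * (1 + stats::rnorm(k, sd = 0.05)))
            mat[nHk + i, ] <- row
        }
    }
    expression <- SummarizedExperiment(
        assays = list(tpm = mat),
        rowData = S4Vectors::DataFrame(description = rownames(mat),
                                       row.names = rownames(mat)),
        colData = S4Vectors::DataFrame(tissue = tissues, row.names = tissues))

    ## -- compartment calls -------------------------------------------------
    set.seed(sectionSeeds[5L])
    bins <- binGenome(chromLengths, binSize)
    plantedBinIdx <- subjectHits(findOverlaps(plantedBins, bins,
                                              type = "equal"))
    pA <- rep(0.3, length(bins))
    pA[plantedBinIdx] <- 1 - config$compartmentNoise
    lab <- matrix(ifelse(stats::runif(length(bins) * config$nTissues) <
                         rep(pA, config$nTissues), "A", "B"),
                  nrow = length(bins), dimnames = list(NULL, tissues))
    compartments <- CompartmentCalls(bins, lab, binSize = binSize)

    ## -- BLAT scores --------------------------------------------------------
    set.seed(sectionSeeds[6L])
    qids <- .queryIds(planted)
    ratio <- ifelse(isDecoy, stats::runif(nPlanted, 0.52, 0.98),
                    stats::runif(nPlanted, 0, 0.3))
    blatScores <- data.frame(
        query_id = rep(qids, each = 2L),
        score = as.vector(rbind(1000, round(1000 * ratio))))

    manifest <- list(
        planted_gsh = planted[!isDecoy],
        planted_decoys = planted[isDecoy],
        planted_hk_genes = hkIds,
        planted_active_bins = plantedBins,
        planted_nonunique_candidates = qids[isDecoy])

    list(annotations = annotations, expression = expression,
         compartments = compartments, blatScores = blatScores,
         geneTable = geneTable, chromLengths = chromLengths,
         manifest = manifest, config = config)
}

#' Write a synthetic data set in the formats the pipeline reads
#'
#' Emits BED tracks (`ucr.bed`, `dnase.bed`, `cancer_genes.bed`,
#' `tad_borders.bed`), the gene table (`genes.tsv`), chromosome lengths
#' (`chrom_lengths.tsv`), the expression matrix (`expression.gct`),
#' compartment calls (`compartments.tsv`), BLAT scores as both a score
#' table (`blat_scores.tsv`) and PSL (`blat.psl`), and the planted-truth
#' manifest (`manifest.json`).
#'
#' @param syn Output of [generateSyntheticData()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSyntheticData <- function(syn, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    ann <- syn$annotations
    writeBed(getTrack(ann, "ucr"), p("ucr.bed"))
    writeBed(getTrack(ann, "dnase"), p("dnase.bed"))
    writeBed(getTrack(ann, "cancer_gene"), p("cancer_genes.bed"))
    writeBed(getTrack(ann, "tad_border"), p("tad_borders.bed"))
    write.table(syn$geneTable, p("genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(chrom = names(syn$chromLengths),
                           length = as.integer(syn$chromLengths)),
                p("chrom_lengths.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeGct(syn$expression, p("expression.gct"))
    writeCompartmentCalls(syn$compartments, p("compartments.tsv"))
    write.table(syn$blatScores, p("blat_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writePsl(syn$blatScores, p("blat.psl"))
    m <- syn$manifest
    jsonlite::write_json(list(
        planted_gsh = .queryIds(m$planted_gsh),
        planted_decoys = .queryIds(m$planted_decoys),
        planted_hk_genes = m$planted_hk_genes,
        planted_active_bins = .queryIds(m$planted_active_bins),
        planted_nonunique_candidates = m$planted_nonunique_candidates,
        seed = syn$config$seed), p("manifest.json"), pretty = TRUE)
    invisible(dir)
}

#' Score a pipeline run against the planted truth
#'
#' Recall is the fraction of planted GSH intervals recovered exactly
#' (same chromosome, start and end) among the final candidates; precision
#' is the fraction of final candidates that are planted intervals.
#'
#' @param result A [GshResult-class] or candidate `GRanges`.
#' @param manifest The `manifest` element of [generateSyntheticData()].
#' @return Named numeric: `recall`, `precision`, `n_recovered`,
#'   `n_candidates`, `n_planted`.
#' @export
evaluateRecovery <- function(result, manifest) {
    cand <- if (is(result, "GshResult")) {
        tab <- candidateTable(result)
        sprintf("%s:%d-%d", tab$chrom, tab$start, tab$end)
    } else .queryIds(result)
    truth <- .queryIds(manifest$planted_gsh)
    c(recall = if (length(truth)) mean(truth %in% cand) else NA_real_,
      precision = if (length(cand)) mean(cand %in% truth) else NA_real_,
      n_recovered = sum(truth %in% cand),
      n_candidates = length(cand),
      n_planted = length(truth))
}
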