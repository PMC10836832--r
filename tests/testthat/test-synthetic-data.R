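test_that("the same seed reproduces identical synthetic data", {
    a <- suppressWarnings(generateSyntheticData(syntheticConfig(seed = 61)))
    b <- suppressWarnings(generateSyntheticData(syntheticConfig(seed = 61)))
    expect_identical(SummarizedExperiment::assay(a$expression),
                     SummarizedExperiment::assay(b$expression))
    expect_identical(compartmentLabels(a$compartments),
                     compartmentLabels(b$compartments))
    expect_identical(a$blatScores, b$blatScores)
    expect_true(grEqual(a$manifest$planted_gsh, b$manifest$planted_gsh))
    for (trk in trackNames(a$annotations))
        expect_true(grEqual(getTrack(a$annotations, trk),
                            getTrack(b$annotations, trk)))

    d1 <- tempfile(); d2 <- tempfile()
    writeSyntheticData(a, d1); writeSyntheticData(b, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("generated files load back through the readers without warnings", {
    syn <- suppressWarnings(generateSyntheticData(syntheticConfig(seed = 62)))
    dir <- tempfile()
    writeSyntheticData(syn, dir)
    p <- function(f) file.path(dir, f)
    cl <- readChromLengths(p("chrom_lengths.tsv"))
    expect_equal(cl, syn$chromLengths)
    expect_no_warning({
        ucr <- readBed(p("ucr.bed"), "ucr", chromLengths = cl)
        dnase <- readBed(p("dnase.bed"), "dnase", chromLengths = cl)
        genes <- readGeneTable(p("genes.tsv"), chromLengths = cl)
        se <- readExpressionGct(p("expression.gct"))
        cc <- readCompartmentCalls(p("compartments.tsv"), chromLengths = cl)
        blat <- readBlatScores(p("blat_scores.tsv"))
        psl <- readPsl(p("blat.psl"))
    })
    expect_true(grEqual(ucr, getTrack(syn$annotations, "ucr")))
    expect_true(grEqual(genes$gene_tx, getTrack(syn$annotations, "gene_tx")))
    expect_equal(SummarizedExperiment::assay(se),
                 SummarizedExperiment::assay(syn$expression),
                 tolerance = 1e-4)
    expect_identical(compartmentLabels(cc), {
        m <- compartmentLabels(syn$compartments); rownames(m) <- NULL; m
    })
    # the PSL path and the score-table path agree on every ratio
    expect_equal(setNames(psl$ratio, psl$query),
                 setNames(blat$ratio, blat$query)[psl$query])
})

test_that("a zero-noise genome is recovered exactly, end to end", {
    syn <- suppressWarnings(generateSyntheticData(
        syntheticConfig(seed = 63, compartmentNoise = 0, dupFraction = 0)))
    res <- suppressMessages(suppressWarnings(runGshPipeline(
        syn$annotations, syn$expression, syn$compartments, syn$blatScores,
        quiet = TRUE)))
    rec <- evaluateRecovery(res, syn$manifest)
    expect_equal(unname(rec["recall"]), 1)
    expect_equal(unname(rec["precision"]), 1)
    # planted safe sites pass every buffer by construction: they are among
    # the safety-filter output verbatim
    expect_true(all(gshscreen:::.queryIds(syn$manifest$planted_gsh) %in%
                    gshscreen:::.queryIds(safeSites(res))))
})

test_that("decoy candidates with near-duplicate hits are removed by the
           uniqueness filter but recorded in the run", {
    syn <- suppressWarnings(generateSyntheticData(
        syntheticConfig(seed = 64, compartmentNoise = 0, dupFraction = 0.25)))
    expect_gte(length(syn$manifest$planted_nonunique_candidates), 1L)
    res <- suppressMessages(suppressWarnings(runGshPipeline(
        syn$annotations, syn$expression, syn$compartments, syn$blatScores,
        quiet = TRUE)))
    cand <- candidates(res)
    decoys <- syn$manifest$planted_nonunique_candidates
    expect_true(all(decoys %in% cand$query_id))
    expect_true(all(!cand$passed_blat[cand$query_id %in% decoys]))
    tab <- candidateTable(res)
    expect_false(any(sprintf("%s:%d-%d", tab$chrom, tab$start, tab$end)
                     %in% decoys))
})

test_that("without housekeeping genes no active region can attach and the
           pipeline returns zero candidates", {
    syn <- suppressWarnings(generateSyntheticData(
        syntheticConfig(seed = 65, hkFraction = 0, compartmentNoise = 0)))
    res <- suppressMessages(suppressWarnings(runGshPipeline(
        syn$annotations, syn$expression, syn$compartments, syn$blatScores,
        quiet = TRUE)))
    expect_equal(nrow(candidateTable(res)), 0L)
})

test_that("an infeasible planted configuration fails with an explanation", {
    expect_error(suppressWarnings(generateSyntheticData(
        syntheticConfig(seed = 66, nPlantedGsh = 50))),
        "cannot place")
    expect_error(syntheticConfig(hkFraction = 1.5), "fractions")
})

test_that("planted-bin recovery under compartment noise matches the exact
           binomial law", {
    noise <- 0.05
    pKeep <- pbinom(19, size = 21, prob = 1 - noise, lower.tail = FALSE)
    kept <- 0L; total <- 0L
    for (s in 1:20) {
        syn <- suppressWarnings(generateSyntheticData(
            syntheticConfig(seed = 700 + s, compartmentNoise = noise)))
        act <- consistentActive(syn$compartments)
        planted <- syn$manifest$planted_active_bins
        hits <- findOverlaps(planted, act, type = "equal")
        kept <- kept + length(hits)
        total <- total + length(planted)
    }
    emp <- kept / total
    margin <- 4 * sqrt(pKeep * (1 - pKeep) / total)
    expect_lt(abs(emp - pKeep), margin)
})
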