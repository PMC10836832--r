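test_that("BED coordinates convert to 1-based closed and back losslessly", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t99\t200\tsite1\t0\t+", "chr1\t0\t1"), bed)
    gr <- readBed(bed, "dnase")
    expect_equal(start(gr), c(100L, 1L))
    expect_equal(end(gr), c(200L, 1L))
    expect_equal(width(gr), c(101L, 1L))
    expect_equal(as.character(strand(gr)), c("+", "*"))
    expect_true(all(gr$feature_class == "dnase"))

    set.seed(11)
    rnd <- randomIntervals(1000, c(chrA = 50000, chrB = 80000))
    rnd$name <- sprintf("f%04d", seq_along(rnd))
    out <- tempfile(fileext = ".bed")
    writeBed(rnd, out)
    back <- readBed(out, "ucr")
    expect_true(grEqual(sort(rnd), sort(back)))
    expect_equal(sort(back$name), sort(rnd$name))
})

test_that("malformed BED lines fail with their line number", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t20", "chr1\t50\t40"), bed)
    expect_error(readBed(bed, "ucr"), "line 2")
    writeLines(c("# comment", "chr1\t-5\t20"), bed)
    expect_error(readBed(bed, "ucr"), "line 2")
    expect_error(readBed(tempfile(), "ucr"), "no such file")
})

test_that("intervals past the chromosome end are a located load error", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t2000", bed)
    expect_error(readBed(bed, "ucr", chromLengths = c(chr1 = 1500)),
                 "exceeds chromosome length")
    expect_silent(readBed(bed, "ucr", chromLengths = c(chr1 = 2000)))
})

test_that("gene table derives strand-aware TSS and biotype tracks", {
    tab <- tempfile(fileext = ".tsv")
    writeLines(c("chrom\tstart\tend\tstrand\tgene_id\tbiotype",
                 "chr1\t1000\t2000\t+\tG1\tprotein_coding",
                 "chr1\t1000\t2000\t-\tG2\tprotein_coding",
                 "chr2\t500\t600\t+\tM1\tmiRNA",
                 "chr2\t900\t1400\t-\tL1\tlncRNA"), tab)
    trk <- readGeneTable(tab)
    expect_equal(length(trk$gene_tx), 4L)
    tss <- trk$tss
    expect_true(all(width(tss) == 1L))
    expect_equal(start(tss[tss$gene_id == "G1"]), 1000L)
    expect_equal(start(tss[tss$gene_id == "G2"]), 2000L)
    # miRNA rows appear on both the transcription-unit and miRNA tracks
    expect_true("M1" %in% trk$gene_tx$gene_id)
    expect_equal(trk$mirna$gene_id, "M1")
    expect_equal(trk$lncrna$gene_id, "L1")

    writeLines(c("chrom\tstart\tend\tstrand\tgene_id\tbiotype",
                 "chr1\t1000\t2000\t.\tGX\tprotein_coding"), tab)
    expect_error(readGeneTable(tab), "GX")
})

test_that("GCT loads with dimension checks, duplicate resolution and
           non-negativity", {
    gct <- tempfile(fileext = ".gct")
    writeLines(c("#1.2", "2\t3",
                 "Name\tDescription\tliver\theart\tbrain",
                 "G1\tg one\t1\t2\t3",
                 "G2\tg two\t4\t5\t6"), gct)
    se <- readExpressionGct(gct)
    expect_equal(dim(se), c(2L, 3L))
    expect_equal(unname(SummarizedExperiment::assay(se, "tpm")["G2", "heart"]), 5)

    writeLines(c("#1.2", "3\t3",
                 "Name\tDescription\tliver\theart\tbrain",
                 "G1\tlow\t1\t1\t1",
                 "G1\thigh\t9\t9\t9",
                 "G2\tok\t4\t5\t6"), gct)
    expect_message(se <- readExpressionGct(gct), "duplicate")
    expect_equal(nrow(se), 2L)
    expect_equal(unname(SummarizedExperiment::assay(se)["G1", "liver"]), 9)

    writeLines(c("#1.2", "1\t3",
                 "Name\tDescription\tliver\theart\tbrain",
                 "G1\tbad\t1\t-1\t1"), gct)
    expect_error(readExpressionGct(gct), "negative")

    writeLines(c("#1.2", "5\t3",
                 "Name\tDescription\tliver\theart\tbrain",
                 "G1\tok\t1\t2\t3"), gct)
    expect_error(readExpressionGct(gct), "disagree")
})

test_that("PSL uniqueness ratios follow second-over-top semantics", {
    psl <- tempfile(fileext = ".psl")
    writePsl(data.frame(query_id = c("q1", "q1", "q2", "q3", "q3"),
                        score = c(100, 27, 80, 50, 50)), psl)
    res <- readPsl(psl)
    r <- setNames(res$ratio, res$query)
    expect_equal(unname(r["q1"]), 0.27)
    expect_equal(unname(r["q2"]), 0)    # single hit
    expect_equal(unname(r["q3"]), 1.0)  # tied top hits
    expect_true(all(res$ratio >= 0 & res$ratio <= 1))
})

test_that("PSL ratios match a brute-force recomputation on random input", {
    set.seed(5)
    for (rep in 1:20) {
        n <- sample(2:30, 1)
        tab <- data.frame(
            query_id = sample(paste0("q", 1:6), n, replace = TRUE),
            score = sample(0:500, n, replace = TRUE))
        psl <- tempfile(fileext = ".psl")
        writePsl(tab, psl, header = rep %% 2 == 0)
        res <- readPsl(psl)
        brute <- vapply(split(tab$score, tab$query_id), function(s) {
            s <- sort(s, decreasing = TRUE)
            if (length(s) < 2 || s[1] <= 0) 0 else s[2] / s[1]
        }, numeric(1))
        expect_equal(setNames(res$ratio, res$query), brute[res$query])
        # the plain score-table reader agrees with the PSL path
        tsv <- tempfile(fileext = ".tsv")
        write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
        res2 <- readBlatScores(tsv)
        expect_equal(res2$ratio, res$ratio[match(res2$query, res$query)])
    }
})

test_that("truncated PSL data lines are a located parse error", {
    psl <- tempfile(fileext = ".psl")
    writeLines(c(paste(rep("0", 21), collapse = "\t"), "1\t2\t3"), psl)
    expect_error(readPsl(psl), "line 2")
})

test_that("compartment calls load on the 1-Mb grid with conflict detection", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("tissue\tchrom\tbin_start\tbin_end\tlabel",
                 "t1\tchr1\t1\t1000000\tA",
                 "t1\tchr1\t1000001\t2000000\tB",
                 "t2\tchr1\t1\t1000000\tmissing"), tsv)
    cc <- readCompartmentCalls(tsv)
    expect_s4_class(cc, "CompartmentCalls")
    expect_equal(length(compartmentBins(cc)), 2L)
    expect_equal(tissueNames(cc), c("t1", "t2"))
    expect_true(is.na(compartmentLabels(cc)[1, "t2"]))

    writeLines(c("tissue\tchrom\tbin_start\tbin_end\tlabel",
                 "t1\tchr1\t5\t1000000\tA"), tsv)
    expect_error(readCompartmentCalls(tsv), "grid")

    writeLines(c("tissue\tchrom\tbin_start\tbin_end\tlabel",
                 "t1\tchr1\t1\t1000000\tA",
                 "t1\tchr1\t1\t1000000\tB"), tsv)
    expect_error(readCompartmentCalls(tsv), "conflicting")
})

test_that("chromosome-length tables load with or without a header", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("chr1\t1000000", "chr2\t500000"), tsv)
    expect_equal(readChromLengths(tsv), c(chr1 = 1e6, chr2 = 5e5))
    writeLines(c("chrom\tlength", "chr1\t1000000"), tsv)
    expect_equal(readChromLengths(tsv), c(chr1 = 1e6))
})
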