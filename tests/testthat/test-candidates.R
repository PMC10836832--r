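test_that("safe-by-active intersection clips to bins and matches a per-base
           AND oracle", {
    active <- GRanges("chr1", IRanges(1e6 + 1, 2e6))
    active$housekeeping_genes <- IRanges::CharacterList("HK1")
    inside <- GRanges("chr1", IRanges(1289036, 1289342))
    cand <- intersectSafeActive(inside, active)
    expect_equal(c(start(cand), end(cand)), c(1289036L, 1289342L))
    expect_equal(cand$active_start, 1e6 + 1)
    expect_equal(as.list(cand$housekeeping_genes), list("HK1"))

    spanning <- GRanges("chr1", IRanges(999000, 1002000))
    clipped <- intersectSafeActive(spanning, active)
    expect_equal(c(start(clipped), end(clipped)), c(1e6 + 1, 1002000))

    set.seed(51)
    toy <- c(cT = 50000)
    for (i in 1:15) {
        safe <- randomIntervals(sample(1:15, 1), toy, 4000)
        bins <- randomIntervals(sample(1:6, 1), toy, 8000)
        bins <- mergeIntervals(bins)  # disjoint "active" regions
        got <- suppressMessages(intersectSafeActive(safe, bins))
        andMask <- mapply(`&`, maskFromIntervals(safe, toy),
                          maskFromIntervals(bins, toy), SIMPLIFY = FALSE)
        expect_equal(sum(width(reduce(got, ignore.strand = TRUE))),
                     sum(andMask$cT))
    }
})

test_that("intersection in containment mode keeps only fully nested sites", {
    active <- GRanges("chr1", IRanges(1e6 + 1, 2e6))
    gr <- GRanges("chr1", IRanges(c(999000, 1500000), c(1002000, 1500100)))
    within <- intersectSafeActive(gr, active, mode = "within")
    expect_equal(start(within), 1500000L)
})

test_that("query splitting respects the 25-kb limit and the 9-11 kb band", {
    one <- splitQuery(20000)
    expect_equal(one, data.frame(offset = 0, length = 20000))

    s3 <- splitQuery(30000)
    expect_true(all(s3$length >= 9000 & s3$length <= 11000))
    expect_equal(s3$offset[1], 0)
    expect_equal(s3$offset[nrow(s3)] + s3$length[1], 30000)

    set.seed(52)
    lens <- c(25001, 26000, 33000, 44000, 199999, 200000,
              sample(25001:200000, 60))
    for (L in lens) {
        seg <- splitQuery(L)
        expect_true(all(seg$length >= 9000 & seg$length <= 11000),
                    label = paste("bounds at", L))
        expect_true(all(diff(seg$offset) > 0))
        # union covers [0, L) and consecutive segments overlap >= 1 bp
        ends <- seg$offset + seg$length
        expect_equal(seg$offset[1], 0)
        expect_equal(ends[nrow(seg)], L)
        expect_true(all(seg$offset[-1] < ends[-nrow(seg)]),
                    label = paste("overlap at", L))
    }
    expect_error(splitQuery(30000, segMin = 500, segMax = 400), "infeasible")
})

test_that("uniqueness filtering is strict above 0.5 and aggregates segments
           by their worst ratio", {
    cand <- GRanges("chr1", IRanges(c(100, 300, 500), width = 50))
    cand$query_id <- c("a", "b", "c")
    res <- S4Vectors::DataFrame(query = c("a", "b", "c/seg1", "c/seg2"),
                                ratio = c(0.47, 0.51, 0.1, 0.6))
    out <- uniquenessFilter(cand, res)
    expect_equal(out$passed_blat, c(TRUE, FALSE, FALSE))
    expect_equal(out$blat_ratio, c(0.47, 0.51, 0.6))
    # exactly at the threshold passes ("over 0.5" is filtered)
    res$ratio[2] <- 0.5
    expect_true(uniquenessFilter(cand, res)$passed_blat[2])

    expect_error(uniquenessFilter(cand, res[1:2, ]), "no BLAT result.*c")

    # raising the threshold never removes candidates
    set.seed(53)
    res$ratio <- runif(4)
    passed <- sapply(seq(0, 1, by = 0.1), function(th)
        sum(uniquenessFilter(cand, res, threshold = th)$passed_blat))
    expect_true(all(diff(passed) >= 0))

    # enumeration over segment ratio sets: aggregate is always the max
    for (i in 1:20) {
        rs <- runif(sample(2:5, 1))
        res2 <- S4Vectors::DataFrame(
            query = paste0("c/seg", seq_along(rs)), ratio = rs)
        one <- uniquenessFilter(cand[3], res2)
        expect_equal(one$blat_ratio, max(rs))
    }
})

test_that("TAD-border distances are report-only with strict more-than
           semantics", {
    border <- GRanges("chr1", IRanges(500000, 500000))
    cand <- GRanges("chr1", IRanges(c(600000, 499990, 580000),
                                    c(600100, 500010, 580100)))
    out <- tadBorderCheck(cand, border)
    expect_equal(length(out), 3L)           # nothing dropped
    expect_equal(out$tad_border_distance[1], 100000)  # 100 kb away
    expect_equal(out$tad_border_distance[2], 0)      # overlapping
    expect_equal(out$tad_clear[2], FALSE)
    # exactly 80,000 bp away fails the strict check
    at80k <- tadBorderCheck(GRanges("chr1", IRanges(580000, 580100)), border)
    expect_equal(at80k$tad_border_distance, 80000)
    expect_false(at80k$tad_clear)
    noBorder <- tadBorderCheck(GRanges("chr2", IRanges(1, 10)), border)
    expect_equal(noBorder$tad_border_distance, Inf)
    expect_true(noBorder$tad_clear)
})

test_that("validation-candidate drawing is deterministic, exhaustive and
           carries the rounding endpoint artefact", {
    expect_setequal(pickValidationCandidates(5, 5, seed = 1), 1:5)
    expect_identical(pickValidationCandidates(7, 25, seed = 99),
                     pickValidationCandidates(7, 25, seed = 99))
    expect_error(pickValidationCandidates(8, 7), "distinct")

    set.seed(54)
    draws <- as.integer(round(runif(1e5, 1, 25)))
    freq <- tabulate(draws, 25) / 1e5
    interior <- 1 / 24
    expect_equal(mean(freq[2:24]), interior, tolerance = 0.02)
    expect_equal(freq[1], interior / 2, tolerance = 0.15)
    expect_equal(freq[25], interior / 2, tolerance = 0.15)
    expect_true(max(abs(freq[2:24] - interior)) < 0.005)
})

test_that("the emitted table recomputes widths and sorts by map order", {
    cand <- GRanges(c("chr2", "chr1", "chr1"),
                    IRanges(c(100, 56339813, 7), c(100, 56340245, 7)))
    tab <- emitCandidateTable(cand, chromOrder = c("chr1", "chr2"))
    expect_equal(tab$width, c(1L, 56340245L - 56339813L + 1L, 1L))
    expect_equal(tab$chrom, c("chr1", "chr1", "chr2"))
    expect_equal(tab$width[2], 433L)
})
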