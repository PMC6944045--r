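# fixtures in 1-based closed coordinates; e.g. the half-open pair
# [0,10) and [5,15) is written 1-10 and 6-15

test_that("unionRegions merges bases present in any sample", {
    a <- dfGr(data.frame(start = 1, end = 10))
    b <- dfGr(data.frame(start = 6, end = 15))
    u <- unionRegions(list(a, b))
    expect_s4_class(u, "RegionSet")
    expect_identical(setLabel(u), "UUMR")
    expect_same_regions(regions(u), data.frame(start = 1, end = 15))

    # one sample: identity
    one <- unionRegions(list(UMRSet("s1", a)))
    expect_same_regions(regions(one), grDf(a))
    expect_identical(provenance(one), "s1")

    expect_error(unionRegions(list()), "at least one")
})

test_that("commonRegions is the base-level intersection across samples", {
    a <- dfGr(data.frame(start = c(1, 21), end = c(10, 30)))
    b <- dfGr(data.frame(start = 6, end = 25))
    cm <- commonRegions(list(a, b))
    expect_same_regions(regions(cm),
                        data.frame(start = c(6, 21), end = c(10, 25)))

    # identical sets: the set itself
    expect_same_regions(regions(commonRegions(list(a, a))), grDf(a))

    # disjoint sets: empty
    d1 <- dfGr(data.frame(start = 1, end = 10))
    d2 <- dfGr(data.frame(start = 21, end = 30))
    expect_length(regions(commonRegions(list(d1, d2))), 0L)

    expect_error(commonRegions(list()), "at least one")
})

test_that("anchor mode keeps first-sample UMRs touching every other sample", {
    a <- dfGr(data.frame(start = c(1, 100), end = c(10, 120)))
    b <- dfGr(data.frame(start = 5, end = 105))
    cm <- commonRegions(list(a, b), mode = "anchor")
    # both anchor UMRs share a base with b's single UMR: kept whole
    expect_same_regions(regions(cm),
                        data.frame(start = c(1, 100), end = c(10, 120)))
})

test_that("union and intersection match per-base oracles on random cohorts", {
    set.seed(108)
    for (i in 1:200) {
        len <- sample(100:5000, 1)
        nSets <- sample(2:5, 1)
        sets <- lapply(seq_len(nSets), function(j) {
            raw <- randomIntervalDf(sample(1:8, 1), len)
            maxRuns(covVec(raw$start, raw$end, len), TRUE)
        })
        grs <- lapply(sets, dfGr)
        expect_same_regions(regions(unionRegions(grs)),
                            oracleUnion(sets, len))
        expect_same_regions(regions(commonRegions(grs)),
                            oracleIntersect(sets, len))
    }
})

test_that("complement of the union equals intersection of complements", {
    set.seed(109)
    len <- 2000L
    for (i in 1:20) {
        sets <- lapply(1:3, function(j) {
            raw <- randomIntervalDf(sample(1:6, 1), len)
            maxRuns(covVec(raw$start, raw$end, len), TRUE)
        })
        compl <- lapply(sets, function(s)
            maxRuns(covVec(s$start, s$end, len), FALSE))
        lhs <- oracleUnion(sets, len)
        rhsCompl <- regions(commonRegions(lapply(compl, dfGr)))
        # union(sets) and intersect(complements) tile [1,len] disjointly
        expect_equal(sum(lhs$end - lhs$start + 1) +
                         sum(GenomicRanges::width(rhsCompl)), len)
        expect_equal(oracleOverlapCount(lhs, grDf(rhsCompl)), 0L)
    }
})

test_that("overlapWithBreakpoints counts each region at most once", {
    regs <- dfGr(data.frame(start = c(1, 101), end = c(50, 200)))
    expect_equal(overlapWithBreakpoints(regs, GenomicRanges::GRanges()), 0L)
    # one break point strictly inside one UMR
    bp <- dfGr(data.frame(start = 120, end = 120))
    expect_equal(overlapWithBreakpoints(regs, bp), 1L)
    # two break points in the same region still count it once
    bp2 <- dfGr(data.frame(start = c(120, 150), end = c(121, 151)))
    expect_equal(overlapWithBreakpoints(regs, bp2), 1L)
    expect_equal(overlapWithBreakpoints(regs, bp2, count = "breakpoints"),
                 2L)
})

test_that("overlapWithBreakpoints agrees with the all-pairs scan", {
    set.seed(110)
    for (i in 1:200) {
        len <- sample(100:5000, 1)
        regsRaw <- randomIntervalDf(sample(1:10, 1), len)
        regs <- maxRuns(covVec(regsRaw$start, regsRaw$end, len), TRUE)
        bps <- randomIntervalDf(sample(0:10, 1), len)
        got <- overlapWithBreakpoints(dfGr(regs), dfGr(bps))
        expect_equal(got, oracleOverlapCount(regs, bps))
        expect_lte(got, nrow(regs))
    }
})

test_that("cumulative overlap curve grows with the union and is reproducible", {
    set.seed(111)
    len <- 5000L
    sets <- lapply(1:6, function(j) {
        raw <- randomIntervalDf(sample(3:8, 1), len)
        dfGr(maxRuns(covVec(raw$start, raw$end, len), TRUE))
    })
    bps <- dfGr(randomIntervalDf(8, len))
    cv <- cumulativeOverlapCurve(sets, bps)
    expect_equal(cv$k, 1:6)
    expect_true(all(diff(cv$unionBp) >= 0))
    expect_true(all(diff(cv$breakpointsTouched) >= 0))
    expect_true(all(cv$overlappedCount <= cv$unionCount))
    expect_equal(cv$overlappedCount[1],
                 overlapWithBreakpoints(sets[[1]], bps))
    expect_equal(cv$unionCount[6],
                 length(regions(unionRegions(sets))))
    # input order is deterministic; shuffling is seed-reproducible
    expect_identical(cumulativeOverlapCurve(sets, bps), cv)
    s1 <- cumulativeOverlapCurve(sets, bps, shuffleSeed = 7)
    s2 <- cumulativeOverlapCurve(sets, bps, shuffleSeed = 7)
    expect_identical(s1, s2)
})

test_that("prefix unions are monotone and intersections anti-monotone", {
    set.seed(112)
    len <- 3000L
    for (rep in 1:20) {
        sets <- lapply(1:5, function(j) {
            raw <- randomIntervalDf(sample(2:6, 1), len)
            dfGr(maxRuns(covVec(raw$start, raw$end, len), TRUE))
        })
        ub <- cb <- numeric(5)
        for (k in 1:5) {
            ub[k] <- sum(GenomicRanges::width(
                regions(unionRegions(sets[1:k]))))
            cb[k] <- sum(GenomicRanges::width(
                regions(commonRegions(sets[1:k]))))
        }
        expect_true(all(diff(ub) >= 0))
        expect_true(all(diff(cb) <= 0))
        # common(S) is contained in union(S)
        cm <- regions(commonRegions(sets))
        un <- regions(unionRegions(sets))
        if (length(cm))
            expect_true(all(IRanges::overlapsAny(cm, un)))
        expect_lte(sum(GenomicRanges::width(cm)),
                   sum(GenomicRanges::width(un)))
    }
})

test_that("cumrRatio reproduces the cohort percentages with half-up rounding", {
    expect_equal(cumrRatio(1577, 47793), 3.3)
    expect_equal(cumrRatio(440, 24291), 1.8)
    expect_equal(cumrRatio(0, 1000), 0)
    expect_error(cumrRatio(10, 0), "positive")
    expect_error(cumrRatio(10, -5), "positive")
    # halves round up, unlike round()'s round-to-even
    expect_equal(roundHalfUp(2.25, 1), 2.3)
    expect_equal(roundHalfUp(-2.25, 1), -2.3)
    expect_equal(cumrRatio(25, 1000), 2.5)
})

test_that("loadBreakpoints accepts BED intervals and chrom/pos points", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200", "chr1\t150\t300"), bed)
    gr <- loadBreakpoints(bed)
    expect_length(gr, 2L)          # break points may overlap each other
    expect_equal(GenomicRanges::start(gr), c(101L, 151L))

    pts <- tempfile(fileext = ".txt")
    writeLines(c("1\t500", "2\t700"), pts)
    gp <- loadBreakpoints(pts)
    expect_equal(GenomicRanges::width(gp), c(1L, 1L))
    expect_equal(GenomicRanges::start(gp), c(500L, 700L))
})

test_that("break-point comparison bridges chr-prefixed and bare naming", {
    umrs <- dfGr(data.frame(start = 100, end = 200), "chr1")
    bps <- dfGr(data.frame(start = 150, end = 160), "1")
    expect_equal(overlapWithBreakpoints(umrs, bps), 1L)
    expect_equal(overlapWithBreakpoints(umrs, bps, "breakpoints"), 1L)
    cv <- cumulativeOverlapCurve(list(umrs), bps)
    expect_equal(cv$overlappedCount, 1L)
})
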