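oneDeletion <- function(start = 10000L, end = 12000L, sample = "S1",
                        zygosity = "hom") {
    data.frame(sample = sample, chrom = "chr1", start = start, end = end,
               tag = "shared", zygosity = zygosity)
}

test_that("simulateSample is byte-deterministic under a fixed seed", {
    cfg <- simulationConfig(genome = c(chr1 = 60000), readLength = 100L,
                            depth = 30, deletions = oneDeletion(),
                            seed = 11L)
    f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
    writeSam(simulateSample(cfg, "S1")$records, cfg@genome, f1)
    writeSam(simulateSample(cfg, "S1")$records, cfg@genome, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    # a different seed changes the placement
    cfg2 <- simulationConfig(genome = c(chr1 = 60000), readLength = 100L,
                             depth = 30, deletions = oneDeletion(),
                             seed = 12L)
    expect_false(identical(simulateSample(cfg, "S1")$records,
                           simulateSample(cfg2, "S1")$records))
})

test_that("realized depth stays within 10% of the request on >= 50 kb", {
    cfg <- simulationConfig(genome = c(chr1 = 50000), readLength = 101L,
                            depth = 30, seed = 21L)
    sim <- simulateSample(cfg, "S1")
    realized <- nrow(sim$records) * 101 / 50000
    expect_lt(abs(realized - 30) / 30, 0.1)
})

test_that("without deletions, 30x coverage leaves almost no gap bases", {
    cfg <- simulationConfig(genome = c(chr1 = 100000), readLength = 100L,
                            depth = 30, seed = 31L)
    sim <- simulateSample(cfg, "S1")
    u <- detectUmrsFromAlignments(sim$records, sampleId = "S1")
    expect_lt(sum(GenomicRanges::width(umrRanges(u))), 0.01 * 100000)
    # cross-check the gap bases against the per-base coverage oracle
    df <- data.frame(start = sim$records$pos,
                     end = sim$records$pos + 99L)
    expect_same_regions(umrRanges(u), oracleGaps(df$start, df$end))
})

test_that("a planted homozygous deletion surfaces as one matching UMR", {
    cfg <- simulationConfig(genome = c(chr1 = 100000), readLength = 100L,
                            depth = 30,
                            deletions = oneDeletion(10000L, 12000L),
                            seed = 41L)
    sim <- simulateSample(cfg, "S1")
    u <- detectUmrsFromAlignments(sim$records, sampleId = "S1")
    hits <- umrRanges(u)[IRanges::overlapsAny(umrRanges(u), sim$truth)]
    expect_length(hits, 1L)
    # gap edges shift by at most one read length on either side
    symdiff <- sum(GenomicRanges::width(GenomicRanges::union(
        hits, sim$truth))) -
        sum(GenomicRanges::width(GenomicRanges::intersect(
            hits, sim$truth)))
    expect_lte(symdiff, 2 * 100)
})

test_that("reads never cross planted deletion junctions", {
    cfg <- simulationConfig(genome = c(chr1 = 60000), readLength = 100L,
                            depth = 30, deletions = oneDeletion(),
                            seed = 51L)
    sim <- simulateSample(cfg, "S1")
    reads <- dfGr(data.frame(start = sim$records$pos,
                             end = sim$records$pos + 99L))
    expect_false(any(IRanges::overlapsAny(reads, sim$truth)))
})

test_that("heterozygous deletions keep reduced but nonzero coverage", {
    cfg <- simulationConfig(genome = c(chr1 = 60000), readLength = 100L,
                            depth = 30,
                            deletions = oneDeletion(zygosity = "het"),
                            seed = 61L)
    sim <- simulateSample(cfg, "S1")
    reads <- dfGr(data.frame(start = sim$records$pos,
                             end = sim$records$pos + 99L))
    inDel <- sum(IRanges::overlapsAny(reads, sim$truth))
    expect_gt(inDel, 0)     # the intact haplotype still contributes
    # so the zero-coverage detector stays blind to it
    u <- detectUmrsFromAlignments(sim$records, sampleId = "S1")
    expect_false(any(IRanges::overlapsAny(umrRanges(u), sim$truth)))
})

test_that("infeasible placements and out-of-bounds deletions are refused", {
    expect_error(simulationConfig(genome = c(chr1 = 5000),
                                  deletions = oneDeletion(100L, 6000L)),
                 "beyond")
    cfg <- simulationConfig(genome = c(chr1 = 300), readLength = 150L,
                            depth = 5,
                            deletions = data.frame(
                                sample = "S1", chrom = "chr1",
                                start = 100L, end = 250L,
                                tag = "private", zygosity = "hom"))
    expect_error(simulateSample(cfg, "S1"), "infeasible")
})

test_that("plantCohortDeletions builds the requested shared/private design", {
    genome <- c(chr1 = 300000, chr2 = 300000)
    d <- plantCohortDeletions(paste0("S", 1:5), genome, nShared = 3,
                              nPrivate = 2, seed = 5L)
    expect_equal(nrow(d), 5 * (3 + 2))
    expect_equal(sum(d$tag == "shared"), 15)
    # shared deletions identical across samples
    sh <- unique(d[d$tag == "shared", c("chrom", "start", "end")])
    expect_equal(nrow(sh), 3)
    expect_true(all(d$end - d$start >= 500 & d$end - d$start <= 5000))
    cfg <- simulationConfig(genome = genome, deletions = d)  # validity
    expect_s4_class(cfg, "SimulationConfig")
})

test_that("simulateCohort pools the truth into a break-point catalogue", {
    genome <- c(chr1 = 400000)
    d <- plantCohortDeletions(paste0("S", 1:5), genome, nShared = 3,
                              nPrivate = 2, seed = 6L)
    cfg <- simulationConfig(genome = genome, readLength = 100L,
                            depth = 8, deletions = d, seed = 7L)
    out <- tempfile()
    sim <- simulateCohort(cfg, outDir = out)
    expect_length(sim$breakpoints, 3 + 5 * 2)
    expect_setequal(names(sim$samples), paste0("S", 1:5))
    for (f in c("S1.sam", "S1.truth.bed", "breakpoints.bed",
                "manifest.json"))
        expect_true(file.exists(file.path(out, f)))
    # the pooled break points are exactly the union of per-sample truths
    all <- do.call(c, unname(lapply(sim$samples, function(s)
        GenomicRanges::granges(s$truth))))
    expect_same_regions(sort(sim$breakpoints), grDf(sort(unique(all))))
})

test_that("shared deletions are recovered in the cohort CUMR set", {
    genome <- c(chr1 = 200000)
    d <- plantCohortDeletions(paste0("S", 1:3), genome, nShared = 2,
                              nPrivate = 1, seed = 8L)
    cfg <- simulationConfig(genome = genome, readLength = 100L,
                            depth = 30, deletions = d, seed = 9L)
    sim <- simulateCohort(cfg)
    umrSets <- lapply(names(sim$samples), function(sId)
        detectUmrsFromAlignments(sim$samples[[sId]]$records,
                                 sampleId = sId))
    cumr <- commonRegions(umrSets)
    sh <- unique(d[d$tag == "shared", c("chrom", "start", "end")])
    shared <- grFromBed(sh$chrom, sh$start, sh$end)
    expect_true(all(IRanges::overlapsAny(shared, regions(cumr))))
    # and the cumulative curve against the truth is non-decreasing,
    # ending at or above the shared-deletion count
    cv <- cumulativeOverlapCurve(umrSets, sim$breakpoints)
    expect_true(all(diff(cv$overlappedCount) >= 0))
    expect_gte(cv$overlappedCount[nrow(cv)], 2)
})
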