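.asRegionGRanges <- function(x) {
    if (is(x, "UMRSet")) return(umrRanges(x))
    if (is(x, "RegionSet")) return(regions(x))
    if (is(x, "GRanges")) return(x)
    stop("expected UMRSet, RegionSet or GRanges, got ", class(x)[1L])
}

# endpoint-counting sweep on plain integer vectors: given interval
# starts/ends (1-based closed, one chromosome), return the maximal
# intervals whose per-base multiplicity is >= minCount. Events are +1
# at each start and -1 just past each end; cumulating them over the
# sorted event positions yields the depth of every constant segment.
.sweepRuns <- function(s, e, minCount) {
    if (!length(s)) return(list(start = integer(0), end = integer(0)))
    pos <- c(s, e + 1L)
    delta <- rep(c(1L, -1L), c(length(s), length(e)))
    o <- order(pos)
    pos <- pos[o]
    depth <- cumsum(delta[o])
    last <- c(pos[-1L] != pos[-length(pos)], TRUE)
    p <- pos[last]                # segment i spans [p[i], p[i+1] - 1]
    ok <- depth[last] >= minCount
    runStart <- ok & !c(FALSE, ok[-length(ok)])
    runEnd <- ok & !c(ok[-1L], FALSE)
    list(start = p[runStart], end = p[which(runEnd) + 1L] - 1L)
}

# base-level coverage sweep across a list of interval sets (GRanges):
# maximal intervals covered by >= minCount of the sets. When
# perSetBinary = TRUE each set is first collapsed to its covered bases,
# so multiplicity counts sets rather than raw intervals (required for
# intersection; irrelevant for union). All arithmetic happens on plain
# integer vectors; a single GRanges is built at the end.
.coverageRuns <- function(grl, minCount, perSetBinary = FALSE) {
    chrs <- lapply(grl, function(g) as.character(GenomicRanges::seqnames(g)))
    ss <- lapply(grl, GenomicRanges::start)
    ee <- lapply(grl, GenomicRanges::end)
    chroms <- unique(unlist(chrs))
    if (!length(chroms)) return(GenomicRanges::GRanges())
    outChrom <- character(0); outStart <- integer(0); outEnd <- integer(0)
    for (ch in chroms) {
        s <- integer(0); e <- integer(0)
        for (j in seq_along(grl)) {
            sel <- chrs[[j]] == ch
            sj <- ss[[j]][sel]; ej <- ee[[j]][sel]
            if (perSetBinary && length(sj)) {
                r <- .sweepRuns(sj, ej, 1L)
                sj <- r$start; ej <- r$end
            }
            s <- c(s, sj); e <- c(e, ej)
        }
        r <- .sweepRuns(s, e, minCount)
        outChrom <- c(outChrom, rep(ch, length(r$start)))
        outStart <- c(outStart, r$start)
        outEnd <- c(outEnd, r$end)
    }
    GenomicRanges::GRanges(factor(outChrom, levels = chroms),
                           IRanges::IRanges(outStart, outEnd))
}

.setIds <- function(sets) {
    vapply(seq_along(sets), function(i) {
        s <- sets[[i]]
        if (is(s, "UMRSet")) sampleId(s)
        else if (is(s, "RegionSet") && length(provenance(s)))
            paste(provenance(s), collapse = "+")
        else paste0("set", i)
    }, character(1))
}

#' Union of UMR sets (UUMRs)
#'
#' The merged maximal intervals covering every base that is unmapped in
#' at least one sample of the cohort. The count of a UUMR set is the
#' number of merged intervals, not the multiset of contributing
#' per-sample UMRs.
#'
#' @param sets list of [UMRSet-class], [RegionSet-class] or `GRanges`.
#' @return a [RegionSet-class] labelled `"UUMR"`.
#' @export
unionRegions <- function(sets) {
    if (is(sets, "UMRSet") || is(sets, "RegionSet") || is(sets, "GRanges"))
        sets <- list(sets)
    if (!length(sets)) stop("need at least one input set")
    grl <- lapply(sets, .asRegionGRanges)
    RegionSet("UUMR", .coverageRuns(grl, 1L), provenance = .setIds(sets))
}

#' Common UMRs across a cohort (CUMRs)
#'
#' Base-level intersection: the maximal intervals of bases that are
#' unmapped in *every* sample, counted as maximal disjoint intervals.
#' This reading is symmetric in sample order. The alternative
#' `"anchor"` mode instead keeps each first-sample UMR that shares at
#' least one base with some UMR of every other sample (an asymmetric
#' reading that depends on which sample anchors); it is provided for
#' comparison only.
#'
#' @param sets list of [UMRSet-class], [RegionSet-class] or `GRanges`.
#' @param mode `"base"` (default) or `"anchor"`.
#' @return a [RegionSet-class] labelled `"CUMR"`.
#' @export
commonRegions <- function(sets, mode = c("base", "anchor")) {
    mode <- match.arg(mode)
    if (is(sets, "UMRSet") || is(sets, "RegionSet") || is(sets, "GRanges"))
        sets <- list(sets)
    if (!length(sets)) stop("need at least one input set")
    grl <- lapply(sets, .asRegionGRanges)
    if (mode == "base") {
        # per-set binary: multiplicity counts samples, not raw intervals
        common <- .coverageRuns(grl, length(grl), perSetBinary = TRUE)
    } else {
        grl <- lapply(grl, function(g) .coverageRuns(list(g), 1L))
        anchor <- grl[[1L]]
        keep <- rep(TRUE, length(anchor))
        for (other in grl[-1L])
            keep <- keep & IRanges::overlapsAny(anchor, other,
                                                minoverlap = 1L)
        common <- anchor[keep]
    }
    RegionSet("CUMR", common, provenance = .setIds(sets))
}

#' Count regions overlapping known deletion break points
#'
#' Compares a region set (per-sample UMRs or cohort UUMRs) 1:1 against a
#' catalogue of deletion break-point spans (e.g. the 1000 Genomes
#' structural-variation deletions): a region counts when it shares at
#' least one base with at least one break-point interval, and each
#' region is counted at most once. `count = "breakpoints"` reports the
#' dual count (break points touched by at least one region).
#'
#' @param regs a [RegionSet-class], [UMRSet-class] or `GRanges`.
#' @param bps `GRanges` of break-point spans (a point break is a
#'   length-1 interval).
#' @param count `"regions"` (default) or `"breakpoints"`.
#' @return integer count.
#' @export
overlapWithBreakpoints <- function(regs, bps,
                                   count = c("regions", "breakpoints")) {
    count <- match.arg(count)
    gr <- .asRegionGRanges(regs)
    bps <- .asRegionGRanges(bps)
    if (!length(gr) || !length(bps)) return(0L)
    # harmonize "chr1" vs "1" style naming before comparing, else the
    # overlap test silently finds nothing across providers
    la <- GenomeInfoDb::seqlevels(gr)
    lb <- GenomeInfoDb::seqlevels(bps)
    if (!all(unique(as.character(GenomicRanges::seqnames(bps))) %in% la) ||
        !all(unique(as.character(GenomicRanges::seqnames(gr))) %in% lb)) {
        gr <- .normalizeSeqnames(gr)
        bps <- .normalizeSeqnames(bps)
    }
    if (count == "regions")
        sum(suppressWarnings(
            IRanges::overlapsAny(gr, bps, minoverlap = 1L)))
    else
        sum(suppressWarnings(
            IRanges::overlapsAny(bps, gr, minoverlap = 1L)))
}

#' Cumulative break-point overlap curve
#'
#' For k = 1..N samples (in input order, or permuted reproducibly with
#' `shuffleSeed`), unions the first k UMR sets and counts how many of
#' the resulting UUMRs overlap the break-point catalogue
#' (`overlappedCount`), plus the dual `breakpointsTouched`. As samples
#' accumulate the union's covered bases only grow, so
#' `breakpointsTouched` and `unionBp` are non-decreasing by
#' construction; `overlappedCount` (and `unionCount`) typically grow
#' too but can dip when a new sample merges two previously distinct
#' overlapping regions into one.
#'
#' @param sets ordered list of [UMRSet-class]/[RegionSet-class]/`GRanges`.
#' @param bps `GRanges` of break-point spans.
#' @param shuffleSeed optional seed to permute the sample order
#'   reproducibly.
#' @return data.frame with columns `k`, `unionCount`, `unionBp`,
#'   `overlappedCount`, `breakpointsTouched`.
#' @export
cumulativeOverlapCurve <- function(sets, bps, shuffleSeed = NULL) {
    if (is(sets, "UMRSet") || is(sets, "RegionSet") || is(sets, "GRanges"))
        sets <- list(sets)
    if (!length(sets)) stop("need at least one input set")
    if (!is.null(shuffleSeed)) {
        ord <- local({
            old <- if (exists(".Random.seed", globalenv()))
                get(".Random.seed", globalenv()) else NULL
            on.exit(if (!is.null(old))
                assign(".Random.seed", old, globalenv()))
            set.seed(as.integer(shuffleSeed))
            sample.int(length(sets))
        })
        sets <- sets[ord]
    }
    acc <- GenomicRanges::GRanges()
    out <- vector("list", length(sets))
    for (k in seq_along(sets)) {
        acc <- .coverageRuns(list(acc, .asRegionGRanges(sets[[k]])), 1L)
        out[[k]] <- data.frame(
            k = k, unionCount = length(acc),
            unionBp = sum(GenomicRanges::width(acc)),
            overlappedCount = overlapWithBreakpoints(acc, bps),
            breakpointsTouched = overlapWithBreakpoints(acc, bps,
                                                        "breakpoints"))
    }
    do.call(rbind, out)
}

#' CUMR-to-UMR percentage
#'
#' The share of a cohort's common UMRs relative to the average
#' per-sample UMR count, `100 * cumrCount / meanUmrCount`, rounded
#' half-up to one decimal (so 1,577 CUMRs over an average of 47,793
#' UMRs gives 3.3).
#'
#' @param cumrCount number of CUMRs.
#' @param meanUmrCount average per-sample UMR count (> 0).
#' @return percentage rounded to one decimal place.
#' @examples
#' cumrRatio(1577, 47793)
#' @export
cumrRatio <- function(cumrCount, meanUmrCount) {
    if (any(meanUmrCount <= 0))
        stop("meanUmrCount must be positive")
    roundHalfUp(100 * cumrCount / meanUmrCount, 1L)
}

#' Load deletion break points
#'
#' Accepts a BED interval file or a two-column (chrom, pos) points file;
#' points are expanded to length-1 intervals. Break points may overlap
#' each other.
#'
#' @param path BED or chrom/pos TSV.
#' @param alias optional chromosome alias map.
#' @return `GRanges` of break-point spans.
#' @export
loadBreakpoints <- function(path, alias = NULL) {
    stopifnot(file.exists(path))
    firstLine <- readLines(path, n = 1L, warn = FALSE)
    if (!length(firstLine)) return(GenomicRanges::GRanges())
    nf <- length(strsplit(firstLine, "\t", fixed = TRUE)[[1L]])
    if (nf >= 3L) {
        gr <- GenomicRanges::granges(rtracklayer::import(path,
                                                         format = "BED"))
    } else {
        tab <- utils::read.table(path, sep = "\t", header = FALSE,
                                 col.names = c("chrom", "pos"),
                                 colClasses = c("character", "integer"))
        gr <- GenomicRanges::GRanges(tab$chrom,
            IRanges::IRanges(tab$pos, width = 1L))
    }
    .normalizeSeqnames(gr, alias)
}

#' Plot a cumulative overlap curve
#'
#' @param curve data.frame from [cumulativeOverlapCurve].
#' @param ... passed to [graphics::plot].
#' @return the curve, invisibly.
#' @export
plotCumulativeCurve <- function(curve, ...) {
    stopifnot(all(c("k", "unionCount", "overlappedCount") %in% names(curve)))
    graphics::plot(curve$k, curve$unionCount, type = "b", pch = 16,
                   xlab = "number of samples (k)", ylab = "regions",
                   ylim = c(0, max(curve$unionCount)), ...)
    graphics::lines(curve$k, curve$overlappedCount, type = "b", pch = 1,
                    lty = 2)
    graphics::legend("bottomright",
                     legend = c("UUMRs", "UUMRs overlapping break points"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
    invisible(curve)
}
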