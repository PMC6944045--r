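#' Detect unmapped regions on one chromosome
#'
#' Given the mapped reference intervals of one chromosome, returns the
#' maximal intervals covered by no read (the UMRs). The detector sorts
#' by (start, end) and sweeps with a running maximum end point `E`:
#' whenever the next interval starts beyond `E`, the uncovered stretch
#' between them is emitted if it is at least `minGap` bp long. Nested
#' and contained reads are therefore handled correctly; the literal
#' consecutive-pair comparison (each read's end against the next read's
#' start) is available via `legacyPairwise` in the policy and emits
#' false gaps in the presence of nested reads.
#'
#' @param intervals `GRanges` of mapped intervals, all on one
#'   chromosome.
#' @param policy a [DetectorPolicy-class].
#' @return `GRanges` of UMRs, sorted, disjoint, non-adjacent. With
#'   `includeEdges`, uncovered chromosome ends are included; an empty
#'   input then yields every chromosome in the policy's `chromLengths`
#'   whole.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 201), c(100, 300)))
#' detectUmrs(gr)   # one 100 bp gap
#' @export
detectUmrs <- function(intervals, policy = detectorPolicy()) {
    stopifnot(is(intervals, "GRanges"), is(policy, "DetectorPolicy"))
    chroms <- unique(as.character(GenomicRanges::seqnames(intervals)))
    if (length(chroms) > 1L)
        stop("intervals span multiple chromosomes: ",
             paste(chroms, collapse = ", "))
    chrom <- if (length(chroms)) chroms else NA_character_
    chromLen <- if (!is.na(chrom) && chrom %in% names(policy@chromLengths))
        policy@chromLengths[[chrom]] else NA_integer_

    if (!length(intervals)) {
        # nothing mapped: with edges requested, every known chromosome
        # is uncovered end to end (the input cannot name one itself)
        if (policy@includeEdges && length(policy@chromLengths)) {
            cl <- policy@chromLengths[policy@chromLengths >= policy@minGap]
            return(GenomicRanges::GRanges(names(cl),
                IRanges::IRanges(rep(1L, length(cl)), cl)))
        }
        return(GenomicRanges::GRanges())
    }

    s <- GenomicRanges::start(intervals)
    e <- GenomicRanges::end(intervals)
    o <- order(s, e)
    s <- s[o]; e <- e[o]

    if (policy@legacyPairwise) {
        # literal rule: compare each read's end with the NEXT read's start
        prevEnd <- e[-length(e)]
        nextStart <- s[-1L]
    } else {
        runMax <- cummax(e)
        prevEnd <- runMax[-length(runMax)]
        nextStart <- s[-1L]
    }
    gapStart <- prevEnd + 1L
    gapEnd <- nextStart - 1L
    keep <- (gapEnd - gapStart + 1L) >= policy@minGap
    gaps <- GenomicRanges::GRanges(rep(chrom, sum(keep)),
        IRanges::IRanges(gapStart[keep], gapEnd[keep]))

    if (policy@includeEdges && !is.na(chromLen)) {
        edges <- GenomicRanges::GRanges()
        if (min(s) > 1L && (min(s) - 1L) >= policy@minGap)
            edges <- c(edges, GenomicRanges::GRanges(chrom,
                IRanges::IRanges(1L, min(s) - 1L)))
        lastCov <- max(e)
        if (lastCov < chromLen && (chromLen - lastCov) >= policy@minGap)
            edges <- c(edges, GenomicRanges::GRanges(chrom,
                IRanges::IRanges(lastCov + 1L, chromLen)))
        gaps <- sort(c(edges, gaps))
    } else if (policy@includeEdges && is.na(chromLen)) {
        stop("includeEdges requires a chromosome length for ", chrom)
    }
    gaps
}

#' Detect unmapped regions from an alignment stream
#'
#' Runs the full per-sample detection: read records (from a SAM/BAM file
#' or an in-memory record data.frame), apply the read filter, convert
#' passing records to mapped intervals, and sweep each chromosome for
#' zero-coverage gaps. Input must be coordinate-sorted within each
#' chromosome; a start that goes backwards is reported with its
#' position.
#'
#' @param x path to a coordinate-sorted SAM/BAM file, or a data.frame
#'   with columns `chrom`, `pos`, `cigar` and optionally `flag`, `mapq`.
#' @param filterPolicy a [FilterPolicy-class].
#' @param detectorPolicy a [DetectorPolicy-class].
#' @param sampleId sample identifier recorded in the result (defaults to
#'   the file base name or `"sample"`).
#' @return a [UMRSet-class].
#' @export
detectUmrsFromAlignments <- function(x,
                                     filterPolicy = umrscan::filterPolicy(),
                                     detectorPolicy = umrscan::detectorPolicy(),
                                     sampleId = NULL) {
    if (is.character(x)) {
        if (is.null(sampleId))
            sampleId <- sub("\\.(sam|bam)$", "", basename(x),
                            ignore.case = TRUE)
        records <- readAlignments(x)
    } else {
        records <- x
        if (is.null(sampleId)) sampleId <- "sample"
    }
    stopifnot(is.data.frame(records))
    nTotal <- nrow(records)

    pass <- if (nTotal) passesFilters(records, filterPolicy) else logical(0)
    # also drop records that cannot be placed at all
    mapped <- pass & records$cigar != "*" & !is.na(records$pos)
    rec <- records[mapped, , drop = FALSE]

    # coordinate-sortedness within each chromosome, in stream order
    if (nrow(rec) > 1L) {
        byChrom <- split(seq_len(nrow(rec)), rec$chrom)
        for (idx in byChrom) {
            p <- rec$pos[idx]
            bad <- which(diff(p) < 0L)
            if (length(bad))
                stop(sprintf(
                    "input not coordinate-sorted: %s:%d follows %s:%d",
                    rec$chrom[idx[bad[1L] + 1L]], p[bad[1L] + 1L],
                    rec$chrom[idx[bad[1L]]], p[bad[1L]]))
        }
    }

    gr <- mappedIntervals(rec)
    perChrom <- split(gr, as.character(GenomicRanges::seqnames(gr)))
    gaps <- lapply(perChrom, detectUmrs, policy = detectorPolicy)
    umrs <- if (length(gaps)) sort(do.call(c, unname(gaps)))
            else GenomicRanges::GRanges()

    readLen <- if (nrow(rec)) as.integer(round(mean(referenceSpan(rec$cigar))))
               else NA_integer_
    UMRSet(sampleId, umrs, metadata = list(
        nRecords = nTotal, nUsed = nrow(rec),
        readLength = readLen,
        filterPolicy = filterPolicy, detectorPolicy = detectorPolicy))
}

#' Per-chromosome UMR summary
#'
#' @param x a [UMRSet-class].
#' @return data.frame with columns `sample`, `chrom`, `n`, `totalBp`,
#'   `meanLength`.
#' @export
umrSummary <- function(x) {
    stopifnot(is(x, "UMRSet"))
    gr <- umrRanges(x)
    if (!length(gr))
        return(data.frame(sample = character(0), chrom = character(0),
                          n = integer(0), totalBp = integer(0),
                          meanLength = numeric(0)))
    w <- split(GenomicRanges::width(gr),
               as.character(GenomicRanges::seqnames(gr)))
    data.frame(sample = sampleId(x), chrom = names(w),
               n = vapply(w, length, integer(1)),
               totalBp = vapply(w, sum, numeric(1)),
               meanLength = vapply(w, mean, numeric(1)),
               row.names = NULL)
}

#' Write/read UMRs as BED6
#'
#' BED6 with `name = UMR_<i>`, `score = length in bp`, `strand = "."`.
#'
#' @param x a [UMRSet-class] or `GRanges`.
#' @param path output BED path.
#' @return `writeUmrBed`: the path, invisibly. `readRegionBed`: a
#'   `GRanges`.
#' @export
writeUmrBed <- function(x, path) {
    gr <- if (is(x, "UMRSet")) umrRanges(x) else x
    gr <- GenomicRanges::granges(gr)
    if (length(gr)) {
        S4Vectors::mcols(gr)$name <- paste0("UMR_", seq_along(gr))
        S4Vectors::mcols(gr)$score <- GenomicRanges::width(gr)
    }
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' @rdname writeUmrBed
#' @export
readRegionBed <- function(path) {
    stopifnot(file.exists(path))
    GenomicRanges::granges(rtracklayer::import(path, format = "BED"))
}
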