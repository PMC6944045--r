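#' Reference span of a CIGAR string
#'
#' Number of reference bases consumed by an alignment: the sum of the
#' lengths of the reference-consuming operations M, D, N, = and X.
#' Insertions (I), soft/hard clips (S/H) and padding (P) consume no
#' reference. A read's mapping end point is its start plus this span;
#' for a plain `"<L>M"` alignment the span is simply the read length,
#' but real CIGARs carry indels and clips, so the general SAM rule is
#' applied.
#'
#' @param cigar character vector of CIGAR strings (not `"*"`).
#' @return integer vector of reference spans (bp).
#' @examples
#' referenceSpan(c("100M", "10S90M", "50M10D40M5I5M"))
#' @export
referenceSpan <- function(cigar) {
    cigar <- as.character(cigar)
    out <- integer(length(cigar))
    if (!length(cigar)) return(out)
    if (any(is.na(cigar)))
        stop("NA CIGAR string")
    if (any(cigar == "*"))
        stop("CIGAR '*' signals an unmapped record; no reference span")
    bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
    if (any(bad)) {
        tok <- sub("^(?:[0-9]+[MIDNSHP=X])*", "", cigar[bad][1L], perl = TRUE)
        stop(sprintf("malformed CIGAR '%s' (at '%s')", cigar[bad][1L],
                     if (nzchar(tok)) tok else cigar[bad][1L]))
    }
    lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
    vapply(seq_along(cigar), function(i) {
        n <- as.integer(lens[[i]])
        sum(n[ops[[i]] %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
}

#' Mapped reference intervals of alignment records
#'
#' Converts the SAM start coordinate (column 4) and CIGAR string
#' (column 6) of each mapped record into the reference interval the read
#' covers: 1-based positions `[pos, pos + referenceSpan(cigar) - 1]`.
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based
#'   leftmost mapping position), `cigar`, and optionally `flag`, `mapq`.
#' @return `GRanges`, one range per record, in input order.
#' @examples
#' mappedIntervals(data.frame(chrom = "1", pos = 100, cigar = "50M"))
#' @export
mappedIntervals <- function(records) {
    stopifnot(is.data.frame(records),
              all(c("chrom", "pos", "cigar") %in% names(records)))
    if (!nrow(records)) return(GenomicRanges::GRanges())
    if (!is.null(records$flag) && any(bitwAnd(records$flag, 4L) != 0L))
        stop("unmapped record (flag 0x4 set) has no mapped interval")
    if (any(records$cigar == "*"))
        stop("unmapped record (CIGAR '*') has no mapped interval")
    if (any(records$pos < 1L))
        stop("mapped records must have pos >= 1")
    span <- referenceSpan(records$cigar)
    GenomicRanges::GRanges(records$chrom,
        IRanges::IRanges(start = records$pos,
                         width = span))
}

#' Apply a read-filtering policy
#'
#' A record passes when none of the policy's excluded flag bits is set,
#' its mapping quality reaches `minMapq`, and (if soft-clipped reads are
#' excluded) its CIGAR contains no S operation. Missing MAPQ (255 is
#' kept as-is; `NA` treated as 0).
#'
#' @param records data.frame with columns `flag`, `mapq` and `cigar`.
#' @param policy a [FilterPolicy-class] (default policy if omitted).
#' @return logical vector, `TRUE` for records that pass.
#' @export
passesFilters <- function(records, policy = filterPolicy()) {
    stopifnot(is(policy, "FilterPolicy"))
    flag <- if (is.null(records$flag)) rep(0L, nrow(records))
            else as.integer(records$flag)
    mapq <- if (is.null(records$mapq)) rep(255L, nrow(records))
            else as.integer(records$mapq)
    mapq[is.na(mapq)] <- 0L
    ok <- bitwAnd(flag, policy@excludeFlags) == 0L &
        mapq >= policy@minMapq
    if (!policy@includeSoftClipped)
        ok <- ok & !grepl("S", records$cigar, fixed = TRUE)
    ok
}

#' Read alignments from a SAM or BAM file
#'
#' Loads the fields the UMR pipeline needs (chromosome, position, CIGAR,
#' flag, MAPQ) from a coordinate-sorted SAM or BAM file. SAM input is
#' converted to BAM on the fly (via Rsamtools); unmapped records are
#' kept so the filtering policy can account for them.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return data.frame with columns `chrom`, `pos`, `cigar`, `flag`,
#'   `mapq`, in file order.
#' @export
readAlignments <- function(path) {
    stopifnot(file.exists(path))
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- suppressMessages(
            Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE))
    }
    res <- Rsamtools::scanBam(bam,
        param = Rsamtools::ScanBamParam(
            what = c("rname", "pos", "cigar", "flag", "mapq")))[[1L]]
    data.frame(chrom = as.character(res$rname),
               pos = res$pos,
               cigar = ifelse(is.na(res$cigar), "*", res$cigar),
               flag = res$flag,
               mapq = res$mapq,
               stringsAsFactors = FALSE)
}
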