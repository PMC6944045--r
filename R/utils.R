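#' Half-up rounding
#'
#' Rounds halves away from zero at the given number of decimals (R's
#' `round()` rounds halves to even). A small epsilon guards against
#' binary representations of exact decimal halves landing just below
#' 0.5.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0L) {
    scale <- 10^digits
    sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' Convenience converter for BED-convention coordinates.
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends (must exceed `start`).
#' @return `GRanges` (1-based closed, the internal convention).
#' @export
grFromBed <- function(chrom, start, end) {
    stopifnot(all(end > start), all(start >= 0))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}
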