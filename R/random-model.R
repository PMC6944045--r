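#' Coverage depth
#'
#' Average fold coverage of a reference of length G by R reads of
#' length L: `D = R * L / G`.
#'
#' @param nReads number of reads (R).
#' @param readLength read length in bp (L).
#' @param genomeLength reference length in bp (G).
#' @return coverage depth (fold).
#' @examples
#' coverageDepth(1000, 100, 100000)   # 1x
#' @export
coverageDepth <- function(nReads, readLength, genomeLength) {
    if (any(c(nReads, readLength, genomeLength) <= 0))
        stop("nReads, readLength and genomeLength must all be positive")
    nReads * readLength / genomeLength
}

#' Construct random-mapping model parameters
#'
#' @param nReads number of mapped reads (R).
#' @param readLength read length in bp (L).
#' @param genomeLength reference length in bp (G).
#' @param avgUmrLength average UMR length in bp (m), e.g. computed from
#'   a detected [UMRSet-class] via [avgUmrLength].
#' @param alphaMode how the chance-start probability alpha is read:
#'   `"literal"` (alpha = D/G, the printed form) or `"per-read"`
#'   (alpha = R/G, the probability that some read starts at a given
#'   position).
#' @param depth coverage depth; derived as R*L/G when omitted.
#' @return a [RandomMappingParams-class].
#' @export
randomMappingParams <- function(nReads, readLength, genomeLength,
                                avgUmrLength,
                                alphaMode = c("literal", "per-read"),
                                depth = NULL) {
    alphaMode <- match.arg(alphaMode)
    if (is.null(depth))
        depth <- coverageDepth(nReads, readLength, genomeLength)
    new("RandomMappingParams", nReads = as.numeric(nReads),
        readLength = as.numeric(readLength),
        genomeLength = as.numeric(genomeLength),
        avgUmrLength = as.numeric(avgUmrLength),
        depth = as.numeric(depth), alphaMode = alphaMode)
}

#' Chance-start probability alpha
#'
#' Probability that mapping starts at a given reference position by
#' chance. Two readings are supported and the one used is attached to
#' the result: `"literal"` gives `alpha = D / G`; `"per-read"` gives
#' `alpha = R / G` (the chance that one of R uniformly placed reads
#' starts at a fixed position). Both lie in [0, 1] for any admissible
#' input, and the mode can be overridden per call.
#'
#' @param params a [RandomMappingParams-class].
#' @param mode optional override of the params' `alphaMode`.
#' @return alpha, with attribute `"mode"`.
#' @export
startProbability <- function(params, mode = NULL) {
    stopifnot(is(params, "RandomMappingParams"))
    mode <- if (is.null(mode)) params@alphaMode
            else match.arg(mode, c("literal", "per-read"))
    alpha <- switch(mode,
        "literal" = params@depth / params@genomeLength,
        "per-read" = params@nReads / params@genomeLength)
    if (is.na(alpha) || alpha < 0 || alpha > 1)
        stop("alpha = ", alpha, " outside [0, 1]; check R, L, G")
    structure(alpha, mode = mode)
}

#' Probability that a UMR arises under random read placement
#'
#' Under an independent chance-start process with per-position
#' probability alpha, a position initiates a "gap event" when a read
#' starts there and no further read starts within the following
#' `L + m - 1` positions — i.e. the read (length L) is followed by a
#' zero-coverage run of at least the average UMR length m. The default
#' form
#' \deqn{P = \alpha (1-\alpha)^{L+m-1} \cdot G/(L+m)}
#' is the expected number of such events per `(L+m)`-sized unit of the
#' genome: `G * alpha * (1-alpha)^(L+m-1)` events are expected in total,
#' scaled by `1/(L+m)`. Both the exponent and the scale factor are
#' configurable because the model admits neighbouring readings; the
#' variant used is recorded on the result. P vanishes at alpha = 0 (no
#' chance starts) and alpha = 1 (no start-free run possible).
#'
#' @param params a [RandomMappingParams-class] (uses its `alphaMode`).
#' @param alpha optional explicit alpha (otherwise [startProbability]).
#' @param exponent exponent of the `(1-alpha)` factor; default
#'   `L + m - 1`.
#' @param scaleFactor multiplier; default `G / (L + m)`.
#' @return P, with attributes `"alpha"`, `"exponent"`, `"scaleFactor"`
#'   and `"form"` describing the variant computed.
#' @export
umrProbability <- function(params, alpha = NULL, exponent = NULL,
                           scaleFactor = NULL) {
    stopifnot(is(params, "RandomMappingParams"))
    if (is.null(alpha)) alpha <- as.numeric(startProbability(params))
    if (alpha < 0 || alpha > 1)
        stop("alpha = ", alpha, " outside [0, 1]")
    L <- params@readLength
    m <- params@avgUmrLength
    G <- params@genomeLength
    if (is.null(exponent)) exponent <- L + m - 1
    if (is.null(scaleFactor)) scaleFactor <- G / (L + m)
    p <- alpha * (1 - alpha)^exponent * scaleFactor
    structure(p, alpha = alpha, exponent = exponent,
              scaleFactor = scaleFactor,
              form = "alpha*(1-alpha)^exponent*scaleFactor")
}

#' Whole-sample random-mapping probability
#'
#' Probability that *all* reads of a sample were placed by chance:
#' the per-read UMR probability raised to the sample's exponent
#' (typically the coverage depth, e.g. `0.0272^30 = 1.089e-47`). A
#' vanishingly small value indicates the observed UMRs are not chance
#' artefacts of random placement.
#'
#' @param p per-read UMR probability in [0, 1].
#' @param depthExponent positive exponent (e.g. coverage depth).
#' @return `p ^ depthExponent`.
#' @examples
#' wholeSampleProbability(0.0272, 30)
#' @export
wholeSampleProbability <- function(p, depthExponent) {
    if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
    if (any(depthExponent <= 0)) stop("depthExponent must be positive")
    p^depthExponent
}

#' Average UMR length of a sample
#'
#' @param x a [UMRSet-class] or `GRanges`.
#' @return mean UMR width in bp (NA when empty).
#' @export
avgUmrLength <- function(x) {
    gr <- if (is(x, "UMRSet")) umrRanges(x) else x
    if (!length(gr)) return(NA_real_)
    mean(GenomicRanges::width(gr))
}

#' Random-mapping statistics table
#'
#' Computes D, alpha, P and P^D for a sample in one call, recording the
#' formula variants used (the `umrscan stats` entry point).
#'
#' @param nReads,readLength,genomeLength,avgUmrLength model inputs; see
#'   [randomMappingParams].
#' @param alphaMode `"literal"` or `"per-read"`.
#' @param depthExponent exponent for the whole-sample probability;
#'   defaults to the coverage depth.
#' @return one-row data.frame with columns `R`, `L`, `G`, `m`, `depth`,
#'   `alphaMode`, `alpha`, `umrProbability`, `depthExponent`,
#'   `wholeSampleProbability`.
#' @export
randomMappingStats <- function(nReads, readLength, genomeLength,
                               avgUmrLength,
                               alphaMode = c("literal", "per-read"),
                               depthExponent = NULL) {
    alphaMode <- match.arg(alphaMode)
    params <- randomMappingParams(nReads, readLength, genomeLength,
                                  avgUmrLength, alphaMode)
    alpha <- startProbability(params)
    p <- umrProbability(params)
    if (is.null(depthExponent)) depthExponent <- params@depth
    data.frame(R = nReads, L = readLength, G = genomeLength,
               m = avgUmrLength, depth = params@depth,
               alphaMode = alphaMode, alpha = as.numeric(alpha),
               umrProbability = as.numeric(p),
               depthExponent = depthExponent,
               wholeSampleProbability =
                   wholeSampleProbability(as.numeric(p), depthExponent))
}
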