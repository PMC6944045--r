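#' @import methods
#' @importFrom GenomicRanges GRanges granges reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

.isNormalizedGRanges <- function(gr) {
    # sorted, pairwise disjoint and non-adjacent per chromosome, i.e.
    # the interval set is its own reduce(): chromosomes grouped in
    # seqlevels order, and each same-chromosome neighbour separated by
    # at least one uncovered base.
    n <- length(gr)
    if (n < 2L) return(TRUE)
    f <- as.integer(GenomicRanges::seqnames(gr))
    if (is.unsorted(f)) return(FALSE)
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    same <- f[-1L] == f[-n]
    all(s[-1L][same] > e[-n][same] + 1L)
}

#' Read-filtering policy
#'
#' Controls which alignment records contribute mapped intervals.
#' Secondary (0x100), supplementary (0x800), duplicate (0x400) and
#' unmapped (0x4) records are excluded by default; multiply-mapped reads
#' are therefore not double counted, and duplicate removal performed
#' upstream (e.g. by Picard MarkDuplicates) is replicated for inputs
#' where it was not.
#'
#' @slot minMapq minimum mapping quality (default 0: no MAPQ threshold).
#' @slot excludeFlags SAM flag mask; any record with a set bit in common
#'   with the mask is dropped.
#' @slot includeSoftClipped if `FALSE`, reads whose CIGAR contains a
#'   soft clip (S) are dropped entirely.
#' @exportClass FilterPolicy
setClass("FilterPolicy",
    representation(minMapq = "integer", excludeFlags = "integer",
                   includeSoftClipped = "logical"),
    prototype(minMapq = 0L,
              excludeFlags = bitwOr(bitwOr(4L, 256L), bitwOr(1024L, 2048L)),
              includeSoftClipped = TRUE))

setValidity("FilterPolicy", function(object) {
    if (length(object@minMapq) != 1L || is.na(object@minMapq) ||
        object@minMapq < 0L)
        return("minMapq must be a single non-negative integer")
    if (length(object@excludeFlags) != 1L || object@excludeFlags < 0L)
        return("excludeFlags must be a single non-negative integer")
    TRUE
})

#' Construct a FilterPolicy
#'
#' @param minMapq minimum mapping quality to keep a record.
#' @param excludeFlags SAM flag mask of records to drop (default:
#'   unmapped, secondary, duplicate, supplementary).
#' @param includeSoftClipped keep soft-clipped reads (default `TRUE`).
#' @return a [FilterPolicy-class] object.
#' @examples
#' filterPolicy(minMapq = 20)
#' @export
filterPolicy <- function(minMapq = 0L,
                         excludeFlags = bitwOr(bitwOr(4L, 256L),
                                               bitwOr(1024L, 2048L)),
                         includeSoftClipped = TRUE) {
    new("FilterPolicy", minMapq = as.integer(minMapq),
        excludeFlags = as.integer(excludeFlags),
        includeSoftClipped = isTRUE(includeSoftClipped))
}

#' Gap-detection policy
#'
#' @slot minGap minimum gap length (bp) for a zero-coverage interval to
#'   be reported as a UMR. Default 1: every gap is reported and length
#'   selection is left to downstream consumers.
#' @slot includeEdges whether the uncovered region before the first read
#'   and after the last read on a chromosome counts as a UMR; requires
#'   `chromLengths`.
#' @slot chromLengths named integer vector of chromosome lengths (bp);
#'   required when `includeEdges` is `TRUE`.
#' @slot legacyPairwise use the literal consecutive-pair comparison
#'   (sort by start, compare each read's end to the next read's start)
#'   instead of the running-maximum sweep. With nested reads the
#'   pairwise variant emits false gaps; it is retained only for method
#'   comparison.
#' @exportClass DetectorPolicy
setClass("DetectorPolicy",
    representation(minGap = "integer", includeEdges = "logical",
                   chromLengths = "integer", legacyPairwise = "logical"),
    prototype(minGap = 1L, includeEdges = FALSE,
              chromLengths = integer(0), legacyPairwise = FALSE))

setValidity("DetectorPolicy", function(object) {
    if (length(object@minGap) != 1L || is.na(object@minGap) ||
        object@minGap < 1L)
        return("minGap must be a single integer >= 1")
    if (isTRUE(object@includeEdges) && length(object@chromLengths) == 0L)
        return("includeEdges=TRUE requires chromLengths")
    if (length(object@chromLengths) &&
        is.null(names(object@chromLengths)))
        return("chromLengths must be named by chromosome")
    TRUE
})

#' Construct a DetectorPolicy
#'
#' @param minGap minimum UMR length in bp (>= 1).
#' @param includeEdges count chromosome edges as UMRs.
#' @param chromLengths named vector of chromosome lengths (needed for
#'   `includeEdges`).
#' @param legacyPairwise use the consecutive-pair gap rule instead of the
#'   running-maximum sweep (see [DetectorPolicy-class]).
#' @return a [DetectorPolicy-class] object.
#' @export
detectorPolicy <- function(minGap = 1L, includeEdges = FALSE,
                           chromLengths = integer(0),
                           legacyPairwise = FALSE) {
    cl <- as.integer(chromLengths)
    names(cl) <- names(chromLengths)
    new("DetectorPolicy", minGap = as.integer(minGap),
        includeEdges = isTRUE(includeEdges), chromLengths = cl,
        legacyPairwise = isTRUE(legacyPairwise))
}

#' Per-sample set of unmapped regions
#'
#' Holds the UMRs (maximal zero-coverage reference intervals) detected in
#' one sample, as a sorted, disjoint, non-adjacent `GRanges`, plus
#' provenance metadata (policies used, read counts, gene-filter
#' bookkeeping).
#'
#' @slot sampleId sample identifier.
#' @slot umrs `GRanges` of UMRs, normalized (sorted, disjoint,
#'   non-bookended per chromosome).
#' @slot metadata free-form provenance list (read length, mean depth,
#'   policies, counts before/after gene filtering, ...).
#' @exportClass UMRSet
setClass("UMRSet",
    representation(sampleId = "character", umrs = "GRanges",
                   metadata = "list"))

setValidity("UMRSet", function(object) {
    if (length(object@sampleId) != 1L)
        return("sampleId must be a single string")
    if (!.isNormalizedGRanges(object@umrs))
        return("umrs must be sorted, disjoint and non-adjacent per chromosome")
    TRUE
})

#' Construct a UMRSet
#'
#' @param sampleId sample identifier.
#' @param umrs `GRanges` of unmapped regions (normalized internally with
#'   `reduce()`; supplying overlapping or adjacent ranges is an error).
#' @param metadata named list of provenance metadata.
#' @return a [UMRSet-class] object.
#' @export
UMRSet <- function(sampleId, umrs = GenomicRanges::GRanges(),
                   metadata = list()) {
    new("UMRSet", sampleId = as.character(sampleId),
        umrs = umrs, metadata = metadata)
}

#' Cohort-level region set (UUMRs or CUMRs)
#'
#' A merged, normalized interval set produced by cohort set algebra:
#' the union (UUMR) or base-level intersection (CUMR) of per-sample UMR
#' sets.
#'
#' @slot label what the set is (e.g. "UUMR", "CUMR").
#' @slot regions normalized `GRanges`.
#' @slot provenance sample identifiers that contributed.
#' @exportClass RegionSet
setClass("RegionSet",
    representation(label = "character", regions = "GRanges",
                   provenance = "character"))

setValidity("RegionSet", function(object) {
    if (length(object@label) != 1L)
        return("label must be a single string")
    if (!.isNormalizedGRanges(object@regions))
        return("regions must be sorted, disjoint and non-adjacent")
    TRUE
})

#' Construct a RegionSet
#' @param label descriptive label.
#' @param regions normalized `GRanges`.
#' @param provenance character vector of contributing sample ids.
#' @return a [RegionSet-class] object.
#' @export
RegionSet <- function(label, regions = GenomicRanges::GRanges(),
                      provenance = character(0)) {
    new("RegionSet", label = as.character(label), regions = regions,
        provenance = as.character(provenance))
}

#' Gene annotation index
#'
#' Gene locations used to discard UMRs that fall in genic regions
#' (genes rich in repeats are hard to map and produce spurious UMRs).
#'
#' @slot genes `GRanges` with a `gene` metadata column of gene names.
#' @exportClass GeneAnnotation
setClass("GeneAnnotation", representation(genes = "GRanges"))

setValidity("GeneAnnotation", function(object) {
    if (length(object@genes) && !"gene" %in% colnames(mcols(object@genes)))
        return("genes must carry a 'gene' metadata column")
    if (length(object@genes) && any(GenomicRanges::width(object@genes) < 1L))
        return("gene intervals must have width >= 1")
    TRUE
})

#' Construct a GeneAnnotation
#' @param genes `GRanges` with a `gene` metadata column (added as
#'   `gene_<i>` when absent).
#' @return a [GeneAnnotation-class] object.
#' @export
GeneAnnotation <- function(genes = GenomicRanges::GRanges()) {
    if (length(genes) && !"gene" %in% colnames(mcols(genes)))
        mcols(genes)$gene <- paste0("gene_", seq_along(genes))
    new("GeneAnnotation", genes = genes)
}

#' Parameters of the random-mapping probability model
#'
#' Houses the quantities of the chance-mapping model: R reads of length
#' L bp on a reference of G bp give coverage depth D = R*L/G; alpha is
#' the probability that a read starts at a given reference position by
#' chance; m is the average UMR length observed in the sample.
#'
#' @slot nReads number of mapped reads (R).
#' @slot readLength read length in bp (L).
#' @slot genomeLength reference genome length in bp (G).
#' @slot avgUmrLength average UMR length in bp (m).
#' @slot depth coverage depth (D = R*L/G unless supplied).
#' @slot alphaMode `"literal"` (alpha = D/G) or `"per-read"`
#'   (alpha = R/G).
#' @exportClass RandomMappingParams
setClass("RandomMappingParams",
    representation(nReads = "numeric", readLength = "numeric",
                   genomeLength = "numeric", avgUmrLength = "numeric",
                   depth = "numeric", alphaMode = "character"))

setValidity("RandomMappingParams", function(object) {
    for (s in c("nReads", "readLength", "genomeLength", "avgUmrLength",
                "depth")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v <= 0)
            return(sprintf("%s must be a single positive number", s))
    }
    if (!object@alphaMode %in% c("literal", "per-read"))
        return("alphaMode must be 'literal' or 'per-read'")
    TRUE
})

#' Simulation configuration
#'
#' Describes a synthetic short-read cohort: a reference genome, uniform
#' read placement at a target depth, and per-sample planted deletions
#' (shared across the cohort or private to a sample). Stands in for
#' whole-genome sequencing cohorts such as 101 bp / 30x or
#' 150 bp / 45x Illumina data.
#'
#' @slot genome named numeric vector: chromosome lengths in bp.
#' @slot readLength read length in bp.
#' @slot depth target fold coverage over the donor genome.
#' @slot deletions data.frame with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open, BED convention), `tag`
#'   (`"shared"`/`"private"`) and `zygosity` (`"hom"`/`"het"`).
#' @slot genes optional planted gene annotation (`GRanges`).
#' @slot seed RNG seed for the whole cohort.
#' @slot paired metadata flag only; reads are emitted unpaired.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(genome = "numeric", readLength = "integer",
                   depth = "numeric", deletions = "data.frame",
                   genes = "GRanges", seed = "integer",
                   paired = "logical"))

setValidity("SimulationConfig", function(object) {
    if (length(object@genome) == 0L || is.null(names(object@genome)))
        return("genome must be a named vector of chromosome lengths")
    if (any(object@genome < 1))
        return("chromosome lengths must be >= 1")
    if (object@readLength < 1L) return("readLength must be >= 1")
    if (object@depth <= 0) return("depth must be > 0")
    d <- object@deletions
    need <- c("sample", "chrom", "start", "end", "tag", "zygosity")
    if (nrow(d)) {
        if (!all(need %in% names(d)))
            return(paste("deletions needs columns:",
                         paste(need, collapse = ", ")))
        if (any(!d$chrom %in% names(object@genome)))
            return("deletion chromosome not in genome")
        if (any(d$start < 0) || any(d$end <= d$start))
            return("deletions must satisfy 0 <= start < end")
        if (any(d$end > object@genome[d$chrom]))
            return("deletion extends beyond its chromosome")
        # pairwise non-overlapping within each sample
        for (s in unique(d$sample)) {
            ds <- d[d$sample == s, , drop = FALSE]
            ds <- ds[order(ds$chrom, ds$start), , drop = FALSE]
            same <- ds$chrom[-1] == ds$chrom[-nrow(ds)]
            if (nrow(ds) > 1 && any(same & ds$start[-1] < ds$end[-nrow(ds)]))
                return(sprintf("overlapping deletions within sample %s", s))
        }
    }
    TRUE
})
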