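#' @name accessors
#' @title Accessors for umrscan classes
#' @description Slot accessors for [UMRSet-class], [RegionSet-class] and
#'   [GeneAnnotation-class]; use these rather than `@`.
#' @param x an object.
#' @return `sampleId`: the sample identifier; `umrRanges`, `regions`,
#'   `geneRanges`: a `GRanges`; `setLabel`: the label string;
#'   `provenance`: contributing sample ids; `umrMetadata`: the
#'   provenance metadata list.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "UMRSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("umrRanges", function(x) standardGeneric("umrRanges"))
#' @rdname accessors
#' @export
setMethod("umrRanges", "UMRSet", function(x) x@umrs)

#' @rdname accessors
#' @export
setGeneric("umrMetadata", function(x) standardGeneric("umrMetadata"))
#' @rdname accessors
#' @export
setMethod("umrMetadata", "UMRSet", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))
#' @rdname accessors
#' @export
setMethod("setLabel", "RegionSet", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "RegionSet", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setMethod("geneRanges", "GeneAnnotation", function(x) x@genes)

setMethod("show", "UMRSet", function(object) {
    gr <- object@umrs
    cat("UMRSet for sample", object@sampleId, "\n")
    cat("  ", length(gr), " UMRs on ",
        length(unique(as.character(GenomicRanges::seqnames(gr)))),
        " chromosome(s), ", sum(GenomicRanges::width(gr)),
        " bp total\n", sep = "")
    if (!is.null(object@metadata$nRemovedByGeneFilter))
        cat("  gene filter removed:",
            object@metadata$nRemovedByGeneFilter, "UMRs\n")
})

setMethod("show", "RegionSet", function(object) {
    cat("RegionSet <", object@label, ">: ", length(object@regions),
        " regions, ", sum(GenomicRanges::width(object@regions)),
        " bp, from ", length(object@provenance), " sample(s)\n", sep = "")
})

setMethod("show", "GeneAnnotation", function(object) {
    cat("GeneAnnotation:", length(object@genes), "gene intervals\n")
})

setMethod("show", "RandomMappingParams", function(object) {
    cat("RandomMappingParams: R=", object@nReads, " L=", object@readLength,
        " G=", object@genomeLength, " m=", object@avgUmrLength,
        " D=", signif(object@depth, 4),
        " alphaMode=", object@alphaMode, "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", length(object@genome), "chromosome(s),",
        sum(object@genome), "bp; readLength", object@readLength,
        "; depth", object@depth, "x;", nrow(object@deletions),
        "planted deletion(s); seed", object@seed, "\n")
})
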