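.log <- function(level, ..., logLevel = "INFO") {
    levels <- c(DEBUG = 1L, INFO = 2L, QUIET = 3L)
    if (levels[[level]] >= levels[[logLevel]] && logLevel != "QUIET")
        message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the full UMR pipeline
#'
#' Executes the stages detect -> gene-filter -> union/common ->
#' break-point comparison -> cumulative curve over a set of alignment
#' files, writing per-stage BED/TSV outputs and a JSON manifest to
#' `outDir`. Every stage is also available as a standalone function
#' ([detectUmrsFromAlignments], [filterUmrs], [unionRegions],
#' [commonRegions], [overlapWithBreakpoints], [cumulativeOverlapCurve]),
#' and running them by hand with the same parameters yields the same
#' outputs. Both the unfiltered and the gene-filtered UMR sets are kept
#' throughout.
#'
#' @param alignments character vector of SAM/BAM paths (one per sample).
#' @param outDir output directory.
#' @param genes optional gene annotation path.
#' @param geneDialect `"bed"` or `"ncbi"` (see [loadGeneAnnotation]).
#' @param breakpoints optional break-point BED/TSV path.
#' @param filterPolicy a [FilterPolicy-class].
#' @param detectorPolicy a [DetectorPolicy-class].
#' @param sampleIds sample names (default: file base names).
#' @param logLevel `"DEBUG"`, `"INFO"` or `"QUIET"`.
#' @return invisibly, a list with the per-sample [UMRSet-class]s
#'   (`umrs`, after gene filtering when an annotation was given),
#'   `uumr`/`cumr` [RegionSet-class]s, `curve` data.frame (when break
#'   points were given) and `files` (paths written).
#' @export
runPipeline <- function(alignments, outDir, genes = NULL,
                        geneDialect = "bed", breakpoints = NULL,
                        filterPolicy = umrscan::filterPolicy(),
                        detectorPolicy = umrscan::detectorPolicy(),
                        sampleIds = NULL, logLevel = "INFO") {
    if (!length(alignments)) stop("no alignment files given")
    missingIn <- alignments[!file.exists(alignments)]
    for (p in c(genes, breakpoints))
        if (!is.null(p) && !file.exists(p)) missingIn <- c(missingIn, p)
    if (length(missingIn))
        stop("missing input file(s): ", paste(missingIn, collapse = ", "))
    if (is.null(sampleIds))
        sampleIds <- sub("\\.(sam|bam)$", "", basename(alignments),
                         ignore.case = TRUE)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- list()

    # stage: detect
    umrSets <- vector("list", length(alignments))
    for (i in seq_along(alignments)) {
        u <- tryCatch(
            detectUmrsFromAlignments(alignments[i], filterPolicy,
                                     detectorPolicy, sampleIds[i]),
            error = function(e) stop("stage 'detect' failed on ",
                                     alignments[i], ": ",
                                     conditionMessage(e)))
        .log("INFO", sprintf("detect: %s -> %d UMRs", sampleIds[i],
                             length(umrRanges(u))), logLevel = logLevel)
        p <- file.path(outDir, paste0(sampleIds[i], ".umr.bed"))
        writeUmrBed(u, p)
        files[[basename(p)]] <- p
        umrSets[[i]] <- u
    }
    names(umrSets) <- sampleIds

    # stage: gene filter
    if (!is.null(genes)) {
        ann <- loadGeneAnnotation(genes, dialect = geneDialect)
        umrSets <- lapply(umrSets, function(u) {
            f <- filterUmrs(u, ann)
            .log("INFO", sprintf("filter: %s removed %d of %d UMRs",
                                 sampleId(u),
                                 umrMetadata(f)$nRemovedByGeneFilter,
                                 umrMetadata(f)$nBeforeGeneFilter),
                 logLevel = logLevel)
            p <- file.path(outDir, paste0(sampleId(u), ".umr.filtered.bed"))
            writeUmrBed(f, p)
            files[[basename(p)]] <<- p
            rem <- umrMetadata(f)$removedByGeneFilter
            pr <- file.path(outDir, paste0(sampleId(u), ".umr.removed.bed"))
            if (length(rem)) {
                gg <- GenomicRanges::granges(rem)
                S4Vectors::mcols(gg)$name <- S4Vectors::mcols(rem)$gene
            } else gg <- rem
            rtracklayer::export(gg, pr, format = "BED")
            files[[basename(pr)]] <<- pr
            f
        })
    }

    # stage: union / common
    uumr <- unionRegions(umrSets)
    cumr <- commonRegions(umrSets)
    .log("INFO", sprintf("cohort: %d UUMRs, %d CUMRs",
                         length(regions(uumr)), length(regions(cumr))),
         logLevel = logLevel)
    pu <- file.path(outDir, "uumr.bed"); writeUmrBed(regions(uumr), pu)
    pc <- file.path(outDir, "cumr.bed"); writeUmrBed(regions(cumr), pc)
    files[["uumr.bed"]] <- pu; files[["cumr.bed"]] <- pc

    meanUmr <- mean(vapply(umrSets, function(u) length(umrRanges(u)),
                           numeric(1)))
    ratioTab <- data.frame(
        nSamples = length(umrSets),
        cumrCount = length(regions(cumr)),
        meanUmrCount = meanUmr,
        cumrToUmrPct = if (meanUmr > 0)
            cumrRatio(length(regions(cumr)), meanUmr) else NA_real_)
    pt <- file.path(outDir, "cumr_ratio.tsv")
    utils::write.table(ratioTab, pt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[["cumr_ratio.tsv"]] <- pt

    # stage: break-point comparison + curve
    curve <- NULL
    if (!is.null(breakpoints)) {
        bps <- loadBreakpoints(breakpoints)
        curve <- cumulativeOverlapCurve(umrSets, bps)
        .log("INFO", sprintf("compare: %d of %d UUMRs overlap break points",
                             curve$overlappedCount[nrow(curve)],
                             curve$unionCount[nrow(curve)]),
             logLevel = logLevel)
        pk <- file.path(outDir, "curve.tsv")
        utils::write.table(curve, pk, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files[["curve.tsv"]] <- pk
    }

    manifest <- list(
        subcommand = "pipeline",
        parameters = list(
            minMapq = filterPolicy@minMapq,
            excludeFlags = filterPolicy@excludeFlags,
            minGap = detectorPolicy@minGap,
            legacyPairwise = detectorPolicy@legacyPairwise,
            genes = if (is.null(genes)) NA else genes,
            breakpoints = if (is.null(breakpoints)) NA else breakpoints),
        inputs = as.list(structure(
            unname(tools::md5sum(alignments)), names = basename(alignments))),
        samples = as.list(sampleIds),
        version = as.character(utils::packageVersion("umrscan")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    pm <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE)
    files[["manifest.json"]] <- pm

    invisible(list(umrs = umrSets, uumr = uumr, cumr = cumr,
                   curve = curve, files = files))
}
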