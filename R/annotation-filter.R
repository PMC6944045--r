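#' Normalize chromosome names
#'
#' Unifies UCSC-style (`"chr6"`) and NCBI/Ensembl-style (`"6"`) names so
#' that annotation and alignment inputs from different providers
#' overlap. Default: strip a leading `"chr"`. An explicit alias map
#' (named character vector, `c(chrMT = "MT")`) is applied first.
#'
#' @param chrom character vector of chromosome names.
#' @param alias optional named character vector mapping input names to
#'   canonical names.
#' @return character vector of normalized names.
#' @export
normalizeChrom <- function(chrom, alias = NULL) {
    chrom <- as.character(chrom)
    if (!is.null(alias)) {
        hit <- chrom %in% names(alias)
        chrom[hit] <- alias[chrom[hit]]
    }
    sub("^chr", "", chrom)
}

.normalizeSeqnames <- function(gr, alias = NULL) {
    old <- GenomeInfoDb::seqlevels(gr)
    new <- normalizeChrom(old, alias)
    GenomeInfoDb::seqlevels(gr) <- make.unique(new)
    gr
}

#' Load a gene annotation
#'
#' Two dialects are supported: `"bed"` (0-based half-open; name in
#' column 4) and `"ncbi"` — a tab-delimited table of
#' (chrom, start, end, name) with 1-based fully-closed coordinates as
#' printed by NCBI gene reports (e.g. HLA-A at 6:29,942,469-29,945,883).
#' NCBI rows are converted to the package's internal convention at the
#' boundary. Chromosome names are normalized (see [normalizeChrom]).
#'
#' @param path annotation file.
#' @param dialect `"bed"` or `"ncbi"`.
#' @param alias optional chromosome alias map.
#' @return a [GeneAnnotation-class].
#' @export
loadGeneAnnotation <- function(path, dialect = c("bed", "ncbi"),
                               alias = NULL) {
    dialect <- match.arg(dialect)
    stopifnot(file.exists(path))
    if (dialect == "bed") {
        if (file.size(path) == 0L ||
            !length(readLines(path, n = 1L, warn = FALSE)))
            return(GeneAnnotation())
        gr <- rtracklayer::import(path, format = "BED")
        nm <- S4Vectors::mcols(gr)$name
        gr <- GenomicRanges::granges(gr)
        S4Vectors::mcols(gr)$gene <- if (is.null(nm))
            paste0("gene_", seq_along(gr)) else nm
    } else {
        tab <- tryCatch(
            utils::read.table(path, sep = "\t", header = FALSE,
                              col.names = c("chrom", "start", "end", "name"),
                              colClasses = c("character", "integer",
                                             "integer", "character"),
                              comment.char = "#", quote = ""),
            error = function(e) stop("cannot parse '", path,
                                     "' as ncbi table: ",
                                     conditionMessage(e)))
        if (!nrow(tab)) return(GeneAnnotation())
        bad <- which(is.na(tab$start) | is.na(tab$end) |
                     tab$start < 1L | tab$end < tab$start)
        if (length(bad))
            stop(sprintf("invalid gene interval at line %d of %s",
                         bad[1L], path))
        # 1-based fully-closed in, GRanges 1-based closed: identical span
        gr <- GenomicRanges::GRanges(tab$chrom,
            IRanges::IRanges(tab$start, tab$end))
        S4Vectors::mcols(gr)$gene <- tab$name
    }
    GeneAnnotation(.normalizeSeqnames(gr, alias))
}

#' Remove UMRs overlapping gene locations
#'
#' Drops every UMR that shares at least one base with any gene interval;
#' UMRs are removed whole, never truncated. Essential genes rich in
#' repeats are hard to map and would otherwise masquerade as deletion
#' candidates; the canonical example is a UMR inside the HLA-A locus.
#' The result's metadata records counts before and after and the removed
#' UMRs with the first offending gene, so both the filtered and
#' unfiltered views of a sample can always be reported.
#'
#' @param umrs a [UMRSet-class].
#' @param genes a [GeneAnnotation-class].
#' @param alias optional chromosome alias map applied to both sides.
#' @return a [UMRSet-class] with the surviving UMRs; metadata gains
#'   `nBeforeGeneFilter`, `nRemovedByGeneFilter` and `removedByGeneFilter`
#'   (a `GRanges` with a `gene` column).
#' @export
filterUmrs <- function(umrs, genes, alias = NULL) {
    stopifnot(is(umrs, "UMRSet"), is(genes, "GeneAnnotation"))
    gr <- umrRanges(umrs)
    # overlap on normalized copies; results keep the caller's naming
    grN <- .normalizeSeqnames(gr, alias)
    gg <- .normalizeSeqnames(geneRanges(genes), alias)
    if (!length(gr) || !length(gg)) {
        hits <- integer(0)
    } else {
        ov <- suppressWarnings(
            GenomicRanges::findOverlaps(grN, gg, minoverlap = 1L))
        hits <- S4Vectors::queryHits(ov)
    }
    removedIdx <- unique(hits)
    removed <- gr[removedIdx]
    if (length(removedIdx)) {
        first <- !duplicated(S4Vectors::queryHits(ov))
        geneOf <- S4Vectors::mcols(gg)$gene[S4Vectors::subjectHits(ov)[first]]
        S4Vectors::mcols(removed)$gene <- geneOf
    }
    kept <- if (length(removedIdx)) gr[-removedIdx] else gr
    meta <- umrMetadata(umrs)
    meta$nBeforeGeneFilter <- length(gr)
    meta$nRemovedByGeneFilter <- length(removedIdx)
    meta$removedByGeneFilter <- removed
    UMRSet(sampleId(umrs), kept, metadata = meta)
}
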