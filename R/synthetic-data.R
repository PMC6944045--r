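.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.sampleSeed <- function(seed, index) {
    as.integer((as.numeric(seed) + 7919 * index) %% (2^31 - 1))
}

#' Construct a simulation configuration
#'
#' Defaults mirror a 101 bp / 30x Illumina whole-genome run (the
#' lower-depth arm of the kind of cohort the detector targets); the
#' genome itself is a single synthetic chromosome sized for desk-scale
#' experiments.
#'
#' @param genome named vector of chromosome lengths in bp.
#' @param readLength read length in bp (default 101).
#' @param depth target fold coverage (default 30).
#' @param deletions data.frame with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `tag`
#'   (`"shared"`/`"private"`, default `"private"`) and `zygosity`
#'   (`"hom"`/`"het"`, default `"hom"`). `NULL` for none.
#' @param genes optional planted gene annotation (`GRanges` with a
#'   `gene` column).
#' @param seed cohort RNG seed.
#' @param paired metadata flag; reads are emitted unpaired either way.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(genome = c(chr1 = 1000000),
                             readLength = 101L, depth = 30,
                             deletions = NULL, genes = NULL,
                             seed = 1L, paired = FALSE) {
    if (is.null(deletions))
        deletions <- data.frame(sample = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                tag = character(0), zygosity = character(0))
    if (is.null(deletions$tag)) deletions$tag <- rep("private",
                                                     nrow(deletions))
    if (is.null(deletions$zygosity)) deletions$zygosity <- rep("hom",
                                                               nrow(deletions))
    if (is.null(genes)) genes <- GenomicRanges::GRanges()
    new("SimulationConfig", genome = structure(as.numeric(genome),
                                               names = names(genome)),
        readLength = as.integer(readLength), depth = as.numeric(depth),
        deletions = deletions, genes = genes, seed = as.integer(seed),
        paired = isTRUE(paired))
}

#' Plant shared and private deletions for a cohort
#'
#' Draws non-overlapping deletion intervals on the configured genome:
#' `nShared` deletions carried by every sample and `nPrivate` per-sample
#' ones, with lengths uniform in `lengthRange`. Intervals are separated
#' by at least `minSpacing` bp so that each planted deletion maps to its
#' own zero-coverage gap.
#'
#' @param sampleIds character vector of sample names.
#' @param genome named vector of chromosome lengths.
#' @param nShared deletions present in all samples.
#' @param nPrivate deletions private to each sample.
#' @param lengthRange deletion length range in bp (default 500-5000,
#'   the long-deletion scale of interest).
#' @param minSpacing minimum distance between planted deletions.
#' @param seed RNG seed.
#' @param zygosity `"hom"` or `"het"` applied to every deletion.
#' @return deletions data.frame suitable for [simulationConfig].
#' @export
plantCohortDeletions <- function(sampleIds, genome, nShared = 2L,
                                 nPrivate = 2L,
                                 lengthRange = c(500L, 5000L),
                                 minSpacing = 2000L, seed = 1L,
                                 zygosity = "hom") {
    nTotal <- nShared + nPrivate * length(sampleIds)
    .withSeed(seed, {
        # lay intervals down left-to-right with random spacing on a
        # randomly chosen chromosome ordering
        lens <- sample(seq(lengthRange[1L], lengthRange[2L]), nTotal,
                       replace = TRUE)
        chroms <- sample(names(genome), nTotal, replace = TRUE)
        out <- vector("list", nTotal)
        cursor <- structure(rep(minSpacing, length(genome)),
                            names = names(genome))
        for (i in seq_len(nTotal)) {
            ch <- chroms[i]
            start <- cursor[[ch]] + sample.int(minSpacing, 1L)
            end <- start + lens[i]
            if (end + minSpacing > genome[[ch]])
                stop("genome too small for the requested deletion load")
            out[[i]] <- data.frame(chrom = ch, start = start, end = end)
            cursor[[ch]] <- end + minSpacing
        }
        dels <- do.call(rbind, out)
        shared <- if (nShared) dels[seq_len(nShared), , drop = FALSE]
                  else dels[0, ]
        res <- list()
        for (s in seq_along(sampleIds)) {
            if (nShared)
                res[[length(res) + 1L]] <- data.frame(
                    sample = sampleIds[s], shared, tag = "shared")
            if (nPrivate) {
                idx <- nShared + (s - 1L) * nPrivate + seq_len(nPrivate)
                res[[length(res) + 1L]] <- data.frame(
                    sample = sampleIds[s], dels[idx, , drop = FALSE],
                    tag = "private")
            }
        }
        d <- do.call(rbind, res)
        d$zygosity <- zygosity
        rownames(d) <- NULL
        d
    })
}

.retainedSegments <- function(chromLen, chrom, dels) {
    whole <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, chromLen))
    if (!length(dels)) return(whole)
    GenomicRanges::setdiff(whole, dels)
}

.placeReads <- function(genome, delGr, readLength, depth) {
    segs <- do.call(c, unname(lapply(names(genome), function(ch) {
        .retainedSegments(as.integer(genome[[ch]]), ch,
            delGr[as.character(GenomicRanges::seqnames(delGr)) == ch])
    })))
    w <- GenomicRanges::width(segs)
    valid <- pmax(w - readLength + 1L, 0L)
    if (sum(valid) == 0L)
        stop("infeasible placement: no retained segment is at least ",
             readLength, " bp")
    donorLen <- sum(w)
    nReads <- as.integer(round(depth * donorLen / readLength))
    idx <- sample.int(length(segs), nReads, replace = TRUE,
                      prob = valid / sum(valid))
    offset <- floor(stats::runif(nReads) * valid[idx])
    data.frame(chrom = as.character(GenomicRanges::seqnames(segs))[idx],
               pos = GenomicRanges::start(segs)[idx] + as.integer(offset),
               stringsAsFactors = FALSE)
}

#' Simulate one sample's alignments
#'
#' Places reads of the configured length uniformly at random on the
#' sample's donor genome (the reference minus that sample's planted
#' deletions) at a count giving the requested depth over the donor.
#' Reads always lie entirely within one retained segment — a read that
#' would span a deletion junction is, in effect, re-drawn, because real
#' junction-spanning reads would be soft-clipped or split by an aligner
#' and that signal is exactly what the zero-coverage method does not
#' use. Homozygous deletions receive no reads; heterozygous ones
#' receive reads from the deletion-free haplotype at half depth. Output
#' is deterministic for a fixed config seed and sample index.
#'
#' @param config a [SimulationConfig-class].
#' @param sId sample identifier (must appear in the config's
#'   deletions, or be arbitrary when there are none).
#' @param sampleIndex 1-based index used to derive the per-sample seed;
#'   defaults to the sample's position among the config's samples.
#' @return list with `records` (coordinate-sorted data.frame: `qname`,
#'   `flag`, `chrom`, `pos`, `mapq`, `cigar`) and `truth` (`GRanges` of
#'   the sample's planted deletions with `tag`/`zygosity`).
#' @export
simulateSample <- function(config, sId, sampleIndex = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    d <- config@deletions
    sampleNames <- unique(d$sample)
    if (is.null(sampleIndex))
        sampleIndex <- if (sId %in% sampleNames)
            match(sId, sampleNames) else 1L
    ds <- d[d$sample == sId, , drop = FALSE]
    mkGr <- function(dd) {
        if (!nrow(dd)) {
            gr <- GenomicRanges::GRanges()
        } else {
            gr <- grFromBed(dd$chrom, dd$start, dd$end)
            S4Vectors::mcols(gr)$tag <- dd$tag
            S4Vectors::mcols(gr)$zygosity <- dd$zygosity
        }
        gr
    }
    truth <- mkGr(ds)
    L <- config@readLength
    anyHet <- any(ds$zygosity == "het")
    placed <- .withSeed(.sampleSeed(config@seed, sampleIndex), {
        if (!anyHet) {
            .placeReads(config@genome, GenomicRanges::granges(truth),
                        L, config@depth)
        } else {
            # haplotype 1 carries all deletions, haplotype 2 only the
            # homozygous ones; each contributes half the depth
            hap1 <- GenomicRanges::granges(truth)
            hap2 <- GenomicRanges::granges(
                truth[S4Vectors::mcols(truth)$zygosity == "hom"])
            rbind(.placeReads(config@genome, hap1, L, config@depth / 2),
                  .placeReads(config@genome, hap2, L, config@depth / 2))
        }
    })
    ord <- order(match(placed$chrom, names(config@genome)), placed$pos)
    placed <- placed[ord, , drop = FALSE]
    n <- nrow(placed)
    records <- data.frame(
        qname = sprintf("%s_r%07d", sId, seq_len(n)),
        flag = rep(0L, n),
        chrom = placed$chrom,
        pos = placed$pos,
        mapq = rep(60L, n),
        cigar = rep(sprintf("%dM", L), n),
        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
}

#' Write alignment records as SAM
#'
#' Emits a minimal valid coordinate-sorted SAM: an `@HD`/`@SQ` header
#' and one line per record with placeholder SEQ/QUAL (`*`); only
#' columns 1-9 carry meaning for the pipeline.
#'
#' @param records data.frame as produced by [simulateSample].
#' @param chromLengths named vector of chromosome lengths.
#' @param path output `.sam` path.
#' @return the path, invisibly.
#' @export
writeSam <- function(records, chromLengths, path) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    body <- if (nrow(records)) {
        flag <- if (is.null(records$flag)) rep(0L, nrow(records))
                else records$flag
        mapq <- if (is.null(records$mapq)) rep(60L, nrow(records))
                else records$mapq
        qname <- if (is.null(records$qname))
            sprintf("r%07d", seq_len(nrow(records))) else records$qname
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                qname, as.integer(flag), records$chrom,
                as.integer(records$pos), as.integer(mapq), records$cigar)
    } else character(0)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Simulate a cohort
#'
#' Runs [simulateSample] for every sample named in the config's
#' deletions (or `sampleIds`), and optionally writes one sorted SAM per
#' sample, per-sample truth-deletion BEDs, a pooled break-point BED (the
#' union of all planted deletions — the catalogue a detector's output is
#' compared against), the planted gene annotation BED, and a JSON
#' manifest recording seed and configuration.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory (`NULL`: in-memory only).
#' @param sampleIds sample names; default: those in the config's
#'   deletions (or `"S1"` when there are none).
#' @return list with `samples` (named list of [simulateSample] results),
#'   `breakpoints` (`GRanges`), `genes` (`GRanges`) and, when written,
#'   `files` (named list of paths).
#' @export
simulateCohort <- function(config, outDir = NULL, sampleIds = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    if (is.null(sampleIds)) {
        sampleIds <- unique(config@deletions$sample)
        if (!length(sampleIds)) sampleIds <- "S1"
    }
    sims <- lapply(seq_along(sampleIds), function(i)
        simulateSample(config, sampleIds[i], sampleIndex = i))
    names(sims) <- sampleIds
    truthList <- lapply(sims, function(s) GenomicRanges::granges(s$truth))
    bps <- unique(do.call(c, unname(truthList)))
    out <- list(samples = sims, breakpoints = bps, genes = config@genes)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        files <- list()
        for (sId in sampleIds) {
            samPath <- file.path(outDir, paste0(sId, ".sam"))
            writeSam(sims[[sId]]$records, config@genome, samPath)
            truthPath <- file.path(outDir, paste0(sId, ".truth.bed"))
            writeUmrBed(sims[[sId]]$truth, truthPath)
            files[[paste0(sId, ".sam")]] <- samPath
            files[[paste0(sId, ".truth.bed")]] <- truthPath
        }
        bpPath <- file.path(outDir, "breakpoints.bed")
        writeUmrBed(bps, bpPath)
        files[["breakpoints.bed"]] <- bpPath
        if (length(config@genes)) {
            genePath <- file.path(outDir, "genes.bed")
            gg <- config@genes
            nm <- S4Vectors::mcols(gg)$gene
            gg <- GenomicRanges::granges(gg)
            S4Vectors::mcols(gg)$name <- if (is.null(nm))
                paste0("gene_", seq_along(gg)) else nm
            rtracklayer::export(gg, genePath, format = "BED")
            files[["genes.bed"]] <- genePath
        }
        manifest <- list(seed = config@seed,
                         readLength = config@readLength,
                         depth = config@depth,
                         genome = as.list(config@genome),
                         samples = as.list(sampleIds),
                         nDeletions = nrow(config@deletions))
        manifestPath <- file.path(outDir, "manifest.json")
        jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                             pretty = TRUE)
        files[["manifest.json"]] <- manifestPath
        out$files <- files
    }
    out
}
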