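suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# --- independent brute-force oracles -----------------------------------
# These deliberately avoid the package's code paths (and IRanges): plain
# character walks and per-base logical vectors.

oracleCigarSpan <- function(cigar) {
    chars <- strsplit(cigar, "")[[1L]]
    num <- 0L
    span <- 0L
    for (ch in chars) {
        if (ch >= "0" && ch <= "9") {
            num <- num * 10L + (utf8ToInt(ch) - utf8ToInt("0"))
        } else {
            if (ch %in% c("M", "D", "N", "=", "X")) span <- span + num
            num <- 0L
        }
    }
    span
}

randomCigar <- function() {
    nops <- sample(1:6, 1L)
    ops <- sample(c("M", "I", "D", "N", "S", "=", "X"), nops,
                  replace = TRUE)
    lens <- sample(1:50, nops, replace = TRUE)
    paste0(lens, ops, collapse = "")
}

# per-base coverage of 1-based closed intervals over [1, len]
covVec <- function(starts, ends, len) {
    v <- logical(len)
    for (i in seq_along(starts)) v[starts[i]:ends[i]] <- TRUE
    v
}

# maximal runs of `value` in a logical vector, as 1-based closed intervals
maxRuns <- function(v, value = FALSE) {
    if (!length(v))
        return(data.frame(start = integer(0), end = integer(0)))
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values == value
    data.frame(start = starts[keep], end = ends[keep])
}

# uncovered maximal runs between leftmost and rightmost covered base
oracleGaps <- function(starts, ends, minGap = 1L) {
    if (!length(starts))
        return(data.frame(start = integer(0), end = integer(0)))
    lo <- min(starts); hi <- max(ends)
    v <- covVec(starts, ends, hi)
    runs <- maxRuns(v[lo:hi], FALSE)
    runs$start <- runs$start + lo - 1L
    runs$end <- runs$end + lo - 1L
    runs[runs$end - runs$start + 1L >= minGap, , drop = FALSE]
}

oracleUnion <- function(setList, len) {
    v <- logical(len)
    for (s in setList) if (nrow(s)) v <- v | covVec(s$start, s$end, len)
    maxRuns(v, TRUE)
}

oracleIntersect <- function(setList, len) {
    v <- rep(TRUE, len)
    for (s in setList) {
        w <- if (nrow(s)) covVec(s$start, s$end, len) else logical(len)
        v <- v & w
    }
    maxRuns(v, TRUE)
}

oracleOverlapCount <- function(regs, bps) {
    n <- 0L
    for (i in seq_len(nrow(regs))) {
        hit <- FALSE
        for (j in seq_len(nrow(bps))) {
            if (regs$start[i] <= bps$end[j] && bps$start[j] <= regs$end[i]) {
                hit <- TRUE
                break
            }
        }
        n <- n + hit
    }
    n
}

# circular Bernoulli read-start process: mean rate of gap-initiating
# events (a start followed by >= L+m-1 start-free positions), per
# (L+m)-sized unit
mcGapEventRate <- function(alpha, L, m, G, nrep) {
    span <- L + m
    stat <- numeric(nrep)
    for (i in seq_len(nrep)) {
        k <- stats::rbinom(1L, G, alpha)
        if (k == 0L) next
        posns <- sort(sample.int(G, k))
        d <- diff(c(posns, posns[1L] + G))
        stat[i] <- sum(d >= span) / span
    }
    list(mean = mean(stat), se = stats::sd(stat) / sqrt(nrep))
}

# --- fixture builders ---------------------------------------------------

grDf <- function(gr) {
    data.frame(start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr))
}

dfGr <- function(df, chrom = "chr1") {
    if (!nrow(df)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end))
}

randomIntervalDf <- function(n, chromLen, maxWidth = 200L) {
    s <- sample.int(chromLen - 1L, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    data.frame(start = s, end = pmin(s + w - 1L, chromLen))
}

# records data.frame shorthand for alignment fixtures
rec <- function(chrom, pos, cigar, flag = 0L, mapq = 60L) {
    data.frame(chrom = chrom, pos = pos, cigar = cigar, flag = flag,
               mapq = mapq, stringsAsFactors = FALSE)
}

expect_same_regions <- function(gr, df) {
    expect_equal(length(gr), nrow(df))
    expect_equal(GenomicRanges::start(gr), as.integer(df$start))
    expect_equal(GenomicRanges::end(gr), as.integer(df$end))
}
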