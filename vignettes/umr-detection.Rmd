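---
title: "Detecting long-deletion candidates as unmapped regions"
author: "umrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-deletion candidates as unmapped regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umrscan)
library(GenomicRanges)
```

## The idea

Structural variants longer than ~50 bp are awkward for short-read data:
read-depth, read-pair, split-read and assembly signals all need
substantial machinery and still struggle with long events. `umrscan`
takes the simplest complementary view. After reads are aligned to a
reference, a **homozygous long deletion leaves a hole**: a maximal
reference interval covered by no read at all. We call such an interval
an *unmapped region* (UMR) and treat it as a long-deletion candidate.
The method deliberately uses none of the split-read or insert-size
signal — it only asks where coverage is exactly zero — which makes it
cheap, transparent, and applicable to any coordinate-sorted SAM/BAM.

The per-sample pipeline is:

1. **Mapped intervals.** For each primary, non-duplicate mapped record,
   the reference interval it covers is `[pos, pos + span - 1]`, where
   `span` is the CIGAR reference span — the sum of the M, D, N, `=` and
   X operation lengths. Summing only M would misplace end points for
   any read spanning an indel, so the general SAM rule is used;
   deletions (D) and skips (N) inside a read are counted as covered
   reference, which slightly suppresses very short UMRs relative to an
   M-only reading but reflects that the read does align across them.
2. **Gap sweep.** Intervals are sorted by (start, end) and swept with a
   running maximum end point `E`; whenever the next interval starts at
   `s > E + 1`, the gap `[E + 1, s - 1]` is emitted if it is at least
   `minGap` bp. The running maximum matters: a naive comparison of
   consecutive reads emits false gaps whenever one read nests inside
   another (the naive rule is kept behind `legacyPairwise = TRUE`
   purely for comparison). The sweep provably returns exactly the
   maximal zero-coverage intervals between the leftmost and rightmost
   covered base — the test suite checks it against a per-base coverage
   oracle on thousands of random instances.
3. **Gene filtering.** Genes rich in repeats (HLA-A is the canonical
   example) are hard to map and would masquerade as deletions, so any
   UMR sharing at least one base with a gene location is removed whole.
   Both the filtered and unfiltered sets are always retained.

At the cohort level, per-sample UMR sets are combined two ways:
**UUMRs** (the union — bases unmapped in at least one sample, counted
as merged maximal intervals) and **CUMRs** (the base-level intersection
— bases unmapped in *every* sample). UUMRs are compared against a
catalogue of known deletion break points (e.g. the 1000 Genomes
structural-variant deletions), counting each UUMR at most once if it
shares a base with any break-point span; plotting those counts as
samples accumulate gives the cumulative overlap curve. The union's
covered bases only grow with k, so the number of break points touched
is non-decreasing by construction; the UUMR-count statistics typically
grow too, but can dip when a newly added sample merges two previously
distinct regions into one.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `minMapq` | `filterPolicy()` | 0 | no MAPQ threshold is applied by default; raise it to discard ambiguous placements |
| `excludeFlags` | `filterPolicy()` | 0x4+0x100+0x400+0x800 | unmapped, secondary, duplicate and supplementary records never contribute coverage; multiple mappings of a read are not treated |
| `minGap` | `detectorPolicy()` | 1 bp | every gap is reported; long-deletion selection is a downstream choice, so the detector does not guess a cutoff. If a cutoff tied to read length is wanted, set `minGap = readLength` |
| `includeEdges` | `detectorPolicy()` | `FALSE` | telomeric/unaligned chromosome ends are not gaps *between* reads; enabling it requires chromosome lengths |
| `mode` | `commonRegions()` | `"base"` | base-level intersection is symmetric in sample order; the `"anchor"` reading (first-sample UMRs touching all other samples) is order-dependent and kept only for comparison |

Coordinates are handled as `GRanges` (1-based, closed) throughout —
delegating interval arithmetic to `IRanges` removes the usual off-by-one
risk — and converted to/from 0-based half-open BED only at file
boundaries (by `rtracklayer`). NCBI-style 1-based gene tables are
converted at load time. Chromosome names are normalized (`"chr6"` vs
`"6"`) before any overlap test, because that mismatch is the most
common silent failure of annotation filtering.

## The random-mapping model

To argue observed UMRs are not placement noise, the package models
fully random read placement. With `R` reads of length `L` on a genome
of length `G`, the coverage depth is `D = R*L/G`, and `alpha` is the
probability that a read starts at a given position by chance. A
position initiates a "gap event" when a read starts there and no
further read starts within the next `L + m - 1` positions (`m` = the
sample's average UMR length) — i.e. the read is followed by a
zero-coverage run at least as long as a typical UMR. The default form

$$P = \alpha\,(1-\alpha)^{L+m-1}\,\frac{G}{L+m}$$

is the expected number of such events per `(L+m)`-sized unit of genome,
and `P^D` is reported as the whole-sample probability (e.g.
`0.0272^30 = 1.089e-47` at 30-fold depth — vanishing, so real UMRs are
not random-placement artefacts).

Two genuinely open readings are exposed rather than decided silently:
`alpha` can be taken literally as `D/G` (default) or per-read as `R/G`,
and both the exponent and the `G/(L+m)` factor of `P` are arguments;
every result carries attributes recording the variant used. The test
suite validates the default form against a Monte-Carlo simulation of
the Bernoulli start process on a 2 kb circular toy genome (circularity
removes edge effects so every position is exchangeable), agreeing
within three standard errors at 10^5 replicates.

## What the simulator emulates — and what it does not

`simulateSample()` places reads of fixed length uniformly at random on
a *donor* genome: the reference minus that sample's planted deletions.
Each read lies entirely within one retained segment and is emitted as a
full-match CIGAR at its reference coordinate; a read that would span a
deletion junction is in effect re-drawn. Real aligners would soft-clip
or split such junction reads — exactly the signal this method ignores —
so the simulator models the method's operating assumptions, not an
aligner. Defaults are 101 bp reads at 30-fold depth, the lower-depth
arm of the kind of Illumina cohort the method targets. Deletions are
homozygous by default (zero coverage); `zygosity = "het"` draws half
the depth from each haplotype, demonstrating the method's structural
blindness to heterozygous deletions (the test suite asserts no UMR is
called over a het deletion at 30x).

Consequently, passing tests show that the *interval logic* is exact and
that recovery works under the stated model; they do not show robustness
to sequencing error, GC or mappability bias, soft-clipped junction
reads, repeat-induced multi-mapping, or reference gaps — all of which
affect real data and are the reason the gene filter and downstream
catalogue comparison exist.

Determinism: each sample's RNG stream is derived from the cohort seed
and the sample index, so a cohort is byte-reproducible as a whole and
per sample.

## Numerical and design choices

* **Problem sizes.** The test and acceptance suites use synthetic
  chromosomes of 50–400 kb, cohorts of 3–5 samples, 20 seeds for the
  recovery study, 1,000 random instances per interval-operation oracle
  check and 10^5 Monte-Carlo replicates — sizes at which the brute-force
  per-base oracles remain exact and fast while leaving the statistics
  stable.
* **Rounding.** Reported CUMR/UMR percentages use half-up rounding to
  one decimal (R's `round()` is round-half-to-even, which would turn
  2.25 into 2.2).
* **Ties and degenerate input.** Sorting is by (start, end); the sweep's
  output is provably invariant under input permutation, so equal-start
  ties need no special rule. Empty inputs yield empty outputs (or the
  whole chromosome when edges are requested and the length is known);
  an empty gene annotation makes the filter the identity.
* **Counting convention.** The primary break-point comparison statistic
  is the number of *regions* overlapped (each at most once); the dual
  count of break points touched is available via an argument, since
  either reading of a "1:1 comparison" is defensible.
* **UMR length.** `score` in emitted BED6 is the UMR length in bp, and
  `m` for the random model is the mean width of a sample's UMR set.

## Limitations

Zero-coverage calling is blind to heterozygous deletions and to any
deletion shorter than the typical inter-read gap at the sample's depth;
at 30x, random gaps are rare, but at low depth UMRs are dominated by
sampling noise (the random-mapping model quantifies this). Break-point
concordance against a population catalogue is evidence, not validation:
an overlapping UMR may still be a mappability artefact, and a
non-overlapping one may be a real population-specific deletion.

## A worked example

```{r example}
genome <- c(chr1 = 200000)
dels <- plantCohortDeletions(paste0("S", 1:3), genome,
                             nShared = 2, nPrivate = 1, seed = 4)
cfg <- simulationConfig(genome = genome, readLength = 101L, depth = 30,
                        deletions = dels, seed = 4)
sim <- simulateCohort(cfg)

umrs <- lapply(names(sim$samples), function(s)
    detectUmrsFromAlignments(sim$samples[[s]]$records, sampleId = s))

sapply(umrs, function(u) length(umrRanges(u)))
cumulativeOverlapCurve(umrs, sim$breakpoints)
commonRegions(umrs)
```
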