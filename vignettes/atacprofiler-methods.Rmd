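---
title: "Methods and design notes for atacprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for atacprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters, the
synthetic-data generator, and the numerical decisions behind
`atacprofiler`. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and containers

All internal containers are Bioconductor ranges: fragments, peaks and
features are `GRanges` (1-based, closed intervals), the genome index is a
`Seqinfo`. Every BED-family text format (fragment BED, peak BED, bedGraph,
BED12) is 0-based half-open; conversion happens only in the readers and
writers, so exactly one convention exists on each side of the I/O boundary.

## Fragment input and filtering

A fragment is one sequenced paired-end insert: the span from the leftmost
to the rightmost aligned base of a properly paired read pair, with the
strand of the first mate. Single-end reads are accepted (each read's span
becomes a fragment) for all analyses except those that intrinsically need
inserts: fragment-length statistics, integration-site coverage, and
junction tracks refuse unpaired input.

Organelle filtering drops fragments on contigs matching
`{chrM, MT, Mt, Pt, chrMT, chloroplast}` (case-insensitive exact names;
user-overridable, optionally as regular expressions). Mitochondrial
contamination commonly reaches 20–80% of an ATAC library, which is why the
filter runs before anything else. Duplicates are defined at the fragment
level by identical `(contig, start, end, strand)` — the standard for
paired-end ATAC, where independent inserts essentially never coincide
exactly. Mapping quality is filtered at MAPQ ≥ 10 by default (BAM input
only); the threshold is exposed because no universal value exists.

## Fragment-length periodicity by FFT

Nucleosome-protected DNA yields fragment lengths at integer multiples of
the inter-nucleosome spacing (~190–200 bp in most cells), on top of a
sub-nucleosomal (< 150 bp) mode from nucleosome-free regions. The spacing
is estimated as the dominant period of the 1-bp length histogram:

1. restrict the series to lengths ≥ the search band's lower edge
   (default 100 bp) — the ladder lives above the sub-nucleosomal mode,
   whose broad envelope otherwise leaks through any high-pass detrending
   and dominates the band;
2. subtract a centered moving average (width 51 bp, odd, edge-shrunk) to
   remove the slowly varying envelope;
3. taper with a Hann window. The choice of window is genuinely open in
   descriptions of this analysis; without a taper, leakage from the
   truncation edges biases the band maximum by tens of bp, with it the
   planted-sinusoid oracle is recovered to < 0.1 bp;
4. subtract the mean of the tapered series (so power at f = 0 is exactly
   zero), zero-pad eight-fold to a power of two (fine frequency grid:
   at a 190-bp period the grid spacing is ~4 bp), FFT, and take the
   squared modulus;
5. the period is `1/f*` for the band-maximal frequency, refined by
   parabolic interpolation over the three bins around the maximum.

`has_signal` is FALSE when the maximal band power is below 4x the median
band power. This criterion is conservative for long periods (the spectral
peak is intrinsically broad there, raising the band median); the period
estimate itself is unaffected.

Defaults: `max_length` 1000 bp, search band (100, 400) bp — bracketing
both the ~200 bp textbook spacing and the ~190 bp typically observed —
and `detrend_window` 51 bp.

## Coverage and peak calling

Two coverage modes map to two biological questions. *Full-fragment*
coverage adds 1 over each insert and highlights nucleosome-occupied
regions; *integration-site* coverage adds 1 over a `±25 bp` window around
both Tn5 cut sites of each fragment and defines nucleosome-free accessible
regions. The optional Tn5 +4/−5 offset is available but off by default:
at 50-bp windows it moves nothing that matters, and keeping cut sites at
the observed fragment ends makes the coverage integral exactly
`2 × window × 2 × n_fragments` (up to contig-edge clipping), an invariant
the tests exploit.

The bundled caller is a MACS-like Poisson scan: each position's depth is
tested against `lambda = max(genome-wide rate, local rate in a centered
10-kb window, control rates)`; when a control track is supplied its local
rates at 200 bp, 1 kb and 10 kb windows (scaled to the treatment's total
signal) also enter the max — the small windows are what allow a sharp
control enrichment to cancel a shared artifact. P-values are
Benjamini–Hochberg corrected over all genome positions, significant
positions are merged across gaps ≤ 100 bp, regions shorter than 150 bp are
dropped, and the summit is the leftmost position of maximal depth
(leftmost for determinism). Peak abundance is
`RPKM = count / ((length/1000) × (library/10^6))` with the retained
fragment count as library size.

The caller is deliberately simple — per-position vectors, no model
building, no shifting — and is intended for desk-scale genomes and
self-contained testing; genuinely large genomes should route external
peak calls (any BED) into the downstream modules, which accept them
everywhere.

## Feature sets and enrichment

Eight feature sets derive from the annotation: promoter (strand-aware
1-kb window upstream of the TSS; 1 kb matches the flank used in
profiling, since "promoter" has no canonical numeric definition), gene
body, exon (union over transcripts), intron (gene body minus exons),
5'UTR, CDS, 3'UTR, and IGR (genome complement of gene bodies and
promoters). Features are unions over genes, so a base may belong to
several non-IGR features; enrichment is computed per feature
independently. UTR records absent from the annotation leave the UTR sets
empty (with a warning) rather than inferred.

Enrichment of a peak set in feature *f* is
`log2((S_Pf/S_P)/(S_gf/S_g))` in base pairs, computed by interval
intersection after merging the peaks. Zero-size or zero-overlap features
are reported as *undefined* (NA with a flag), not ±Inf, so the bar chart
stays plottable and downstream arithmetic fails loudly rather than
silently propagating infinities.

## Signal matrices

Gene-scaled rows are `[100 upstream bins][100 scaled body bins]
[100 downstream bins]` by default (flank 1 kb, bin 10 bp), strand-oriented
so upstream is always leftmost; peak-centered rows are a fixed 2-kb window
around the summit. A bin's value is its depth sum normalized like RPKM
(per bin-kb per million contributing units), mirroring the peak abundance
normalization. Heatmap rows are ranked by whole-row mean (whether
TSS-proximal or whole-row ranking is "right" is genuinely open; whole-row
is the simpler and order-stable choice), and the metaplot is the column
mean. Windows running off a contig are clipped; missing bases contribute
zero.

## Junction tracks

One BED12 record per fragment, an arc from start to end (blockCount 2,
1-bp blocks), score = length capped at 1000, colored by length class:
blue `0,0,255` below 150 bp (nucleosome-free), red `255,0,0` at 150 bp and
above (nucleosome-spanning). The boundary length 150 itself is assigned to
the nucleosomal class — the conventional "below 150 / above 150" phrasing
leaves it unassigned, and a fragment spanning one full nucleosome is the
natural reading.

## Differential accessibility

*With replicates.* Candidate regions are the sweep-line partition of the
union of all input peak sets into maximal segments of constant set
membership (the interval equivalent of BEDTools `multiinter`). Abundance
is RPKM per candidate per replicate. The test is Welch's two-sample t-test
on `log2(RPKM + 1)` — Welch avoids the equal-variance assumption and the
log stabilizes variance; the pseudocount of 1 makes zero abundances
well-defined. A region is significant when the raw-mean fold change
(pseudocount 1, larger/smaller) is ≥ 2 **and** p < 0.05. No multiplicity
correction is applied by default (the conventional gate is on raw p);
`fdr = TRUE` switches to BH. Note Welch at n = 3 per group is inherently
conservative (true size ≈ 0.035 at nominal 0.05); the calibration
acceptance band accounts for this.

*Without replicates.* Group-specific peaks are those overlapping no peak
of the other group by even 1 bp. Reproducibility filtering across
replicates is provided as an overlap criterion (reciprocal overlap ≥ 0.5
against every other replicate); full IDR is intentionally not
re-implemented — externally filtered peak sets plug in directly.

*Promoters.* Promoter abundances of two samples, log-transformed, are
modeled with a bivariate Gaussian mixture fitted by our own EM
(full covariances, covariance ridge of `1e-6` times the mean marginal
variance, 10 seeded k-means restarts, component count 1–3 by BIC). A
gene's tail probability is the chi-square(2) survival function at its
squared Mahalanobis distance to its most responsible component; genes
below p = 0.05 are differentially accessible. One guard matters:
components holding < 5% of the data are rejected during model selection.
Without it, a handful of true outliers can be absorbed into their own
component — each then sits at Mahalanobis distance ~0 from "its"
component and escapes detection entirely. This is a standard
regularization for mixture-based outlier detection, and it is why the
procedure stays an outlier test rather than a clustering exercise.

## Overlap testing and expression

The hypergeometric overlap test needs a finite population; the genome is
modeled as `N = floor(S_g / mean peak width over both sets)` bins, A's
peaks mark K of them, and the p-value is the upper hypergeometric tail at
the observed number of A peaks with ≥ 1 bp of B overlap. The bin model is
a package convention (the test itself is standard); `population_bins`
overrides it. Overlap counting is A-sided; the intersection intervals are
exported symmetrically.

For expression, genes are ranked by RPKM (ties broken by gene id for
determinism) and split into 10 near-equal groups (sizes differ by at most
one); a gene is accessible when its body or 1-kb promoter overlaps a peak.
Zero-expression genes stay in the ranking and populate the bottom group.

## The synthetic generator: what a green test establishes

`simulate_dataset()` draws fragment lengths from a mixture of a gamma
sub-nucleosomal mode (mode 60 bp) and Gaussian nucleosome modes at
`k × spacing` (k ≤ 3; sd `0.12 × spacing × sqrt(k)`, widening with k as in
real ladders; weights 0.5/0.25/0.15/0.10). Midpoints are uniform except
inside planted accessible regions (default twenty 500-bp regions at 10x)
and optionally promoter windows; a planted fraction of fragments (default
0.3) lands on a dedicated organelle contig; duplicates are injected at
rate 0.1 by copying earlier fragments. All randomness flows through one
PRNG stream keyed by the seed, and the caller's RNG state is restored
afterwards, so outputs are byte-identical across runs. The truth manifest
records every planted quantity; tests consume truth only through it.

The generator emulates *density* structure, not sequence: no Tn5 sequence
bias, no mappability variation, no chromatin-state autocorrelation, no
GC effects. A green acceptance run therefore establishes that the
estimators recover their own stated world — planted spacing, planted
regions, planted fractions — not that they are robust to every artifact
of real libraries.

## Degenerate inputs and tie-breaks

- Empty fragment sets: histograms warn and stay empty; RPKM is an error
  (undefined), not NaN.
- Peak summit ties break leftmost; expression ranking ties break by gene
  id; both for determinism.
- Zero-variance rows in the t-test: identical means give p = 1,
  different means p = 0.
- GMM input with all points identical is an error ("zero-variance
  input"), as is n < 20.
- Promoters clipped to zero width at contig edges are dropped silently
  (size 0, no error).

## Known limitations

- The Poisson caller materializes per-contig depth vectors; fine to tens
  of Mb, wrong tool at mammalian scale (use external callers there).
- Single-end libraries cannot drive length statistics, integration-site
  coverage or junction tracks.
- The hypergeometric population model treats peaks as equal-width bins;
  heavy width heterogeneity distorts N (override `population_bins`).
- `has_signal` is conservative for periods near the top of the search
  band.
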