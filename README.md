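# atacprofiler

Genome-wide chromatin accessibility profiling from paired-end ATAC-seq
fragments, as an R package built on the Bioconductor ranges stack
(`GenomicRanges`, `Rsamtools`, `rtracklayer`).

ATAC-seq marks open chromatin: the Tn5 transposase inserts preferentially
into nucleosome-free DNA, so sequenced fragment density reports
accessibility. `atacprofiler` takes coordinate-sorted alignments (BAM) or a
fragment BED plus a gene annotation (GTF/GFF3) and provides the standard
desk-to-figure workflow for one or more libraries:

- **QC** — removal of organelle-derived fragments (mitochondrial reads can
  be 20–80% of a library) and PCR duplicates; fragment-size distribution;
  FFT estimation of the nucleosome spacing from the periodicity of the
  length histogram.
- **Accessible regions** — coverage in two modes (full-fragment for
  nucleosome-occupied signal, cut-site windows for nucleosome-free signal)
  and a bundled MACS-like Poisson local-background peak caller with
  RPKM abundances; external peak BEDs are accepted everywhere downstream.
- **Annotation context** — eight genomic feature sets (promoter, gene body,
  exon, intron, 5'UTR, CDS, 3'UTR, IGR) and peak enrichment per feature:

  `log2( (S_Pf / S_P) / (S_gf / S_g) )`

  where `S_P` is total peak bp, `S_g` genome bp, `S_Pf` peak/feature
  overlap bp and `S_gf` feature bp.
- **Profiles** — gene-scaled and peak-centered signal matrices
  (heatmap + metaplot, RPKM-normalized bins) and an IGV junction track
  (BED12 arcs, blue < 150 bp = nucleosome-free, red ≥ 150 bp =
  nucleosome-spanning).
- **Differential accessibility** — multi-set candidate regions (sweep-line
  partition), a ≥ 2-fold + Welch t-test (p < 0.05) gate on log2(RPKM+1)
  with replicates, overlap-based specific peaks without replicates, and a
  bivariate Gaussian-mixture outlier model for differential promoters.
- **Integration** — hypergeometric overlap test against ChIP-seq /
  DNase / MNase peak sets, and accessibility-vs-expression grouping
  (percent accessible genes per expression decile, Venn counts for the
  extreme groups).
- **Synthetic data** — a deterministic generator planting every signal the
  statistics consume (length modes, nucleosome spacing, accessible
  regions, organelle fraction, duplicates), so everything is testable
  offline.

## Worked example

```r
library(atacprofiler)

sim  <- simulate_dataset(simulation_config(seed = 42, promoter_bias = 6))
res  <- filter_organelle_and_duplicates(sim$fragments)
res$report
#> fragment filter: 50000 in, 14969 organelle (29.9%), 3482 duplicates, 31549 retained

est <- estimate_period_fft(length_histogram(res$fragments))
est
#> estimated period: 193.8 bp (band 100-400 bp, signal: yes)

cov   <- make_coverage(res$fragments)
peaks <- peak_abundance(call_peaks(cov), res$fragments)
length(peaks)
#> [1] 116

paths  <- write_simulated_dataset(sim, tempdir())
models <- parse_annotation(paths[["gtf"]], genome = sim$genome)
enr    <- fold_enrichment(peaks, build_feature_set(models, sim$genome))
enr[, c("feature", "S_Pf", "S_gf", "log2_enrichment")]
#>     feature  S_Pf   S_gf log2_enrichment
#> 1  promoter 92768 100000            2.88
#> 2 gene_body  4020 318031           -3.32
#> ...
```

The filter report shows the planted 30% organelle contamination recovered
as 29.9%; the FFT recovers the planted 190-bp nucleosome spacing as
193.8 bp; and because this simulation plants accessibility at promoters
(6x background), peak enrichment is strongly positive at promoters
(+2.9 log2) and negative elsewhere.

## Command line

Every step is also a subcommand (see `?atac_dispatch`):

```sh
Rscript -e 'atacprofiler::atac_dispatch()' simulate --out-dir sim --seed 1
Rscript -e 'atacprofiler::atac_dispatch()' filter \
    --fragments sim/sim_fragments.bed --chrom-sizes sim/sim.chrom.sizes \
    --out-dir filtered
Rscript -e 'atacprofiler::atac_dispatch()' callpeak \
    --fragments filtered/filtered_fragments.bed \
    --chrom-sizes sim/sim.chrom.sizes --out-dir peaks
```

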