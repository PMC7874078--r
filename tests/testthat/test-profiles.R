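test_that("enrichment reproduces proportional and 2x overlap cases", {
  genome <- c(chr1 = 1000)
  peaks <- GRanges("chr1", IRanges(1, 100))            # S_P = 100
  fs <- feature_set(list(f20 = GRanges("chr1", IRanges(81, 280)),
                         f40 = GRanges("chr1", IRanges(61, 260))),
                    genome)
  enr <- fold_enrichment(peaks, fs)
  expect_equal(enr$S_Pf, c(20, 40))
  expect_equal(enr$S_gf, c(200, 200))
  expect_equal(enr$log2_enrichment[1], 0)              # (20/100)/(200/1000)
  expect_equal(enr$log2_enrichment[2], 1)              # doubling S_Pf adds 1
  expect_error(fold_enrichment(peaks[0], fs), "no peaks")
})

test_that("enrichment equals a per-base brute-force oracle on random genomes", {
  for (seed in 1:10) {
    set.seed(seed)
    glen <- sample(5000:20000, 1)
    genome <- c(chr1 = glen)
    rand_intervals <- function(n, maxw) {
      st <- sample.int(glen - maxw, n)
      reduce(GRanges("chr1", IRanges(st, width = sample(50:maxw, n,
                                                        replace = TRUE))))
    }
    peaks <- rand_intervals(sample(3:12, 1), 400)
    feat <- rand_intervals(sample(3:12, 1), 600)
    enr <- fold_enrichment(peaks, feature_set(list(f = feat), genome))
    # brute force: per-base membership over every genomic position
    pmask <- fmask <- logical(glen)
    for (i in seq_along(peaks)) pmask[start(peaks)[i]:end(peaks)[i]] <- TRUE
    for (i in seq_along(feat)) fmask[start(feat)[i]:end(feat)[i]] <- TRUE
    expect_equal(enr$S_P, sum(pmask))
    expect_equal(enr$S_Pf, sum(pmask & fmask))
    if (sum(pmask & fmask) == 0) {
      expect_false(enr$defined)          # undefined, not -Inf
    } else {
      expect_equal(enr$log2_enrichment,
                   log2((sum(pmask & fmask) / sum(pmask)) /
                          (sum(fmask) / glen)),
                   tolerance = 1e-12)
    }
    # permuting peak order changes nothing
    enr2 <- fold_enrichment(rev(peaks), feature_set(list(f = feat), genome))
    expect_equal(enr2$log2_enrichment, enr$log2_enrichment)
  }
})

test_that("zero-overlap and zero-size features are undefined, not infinite", {
  genome <- c(chr1 = 1000)
  peaks <- GRanges("chr1", IRanges(1, 100))
  fs <- feature_set(list(away = GRanges("chr1", IRanges(901, 950)),
                         empty = GRanges()), genome)
  enr <- fold_enrichment(peaks, fs)
  expect_false(any(enr$defined))
  expect_true(all(is.na(enr$log2_enrichment)))
})

test_that("signal matrix layout arithmetic and flat-coverage behavior", {
  genome <- c(chr1 = 20000)
  frags <- make_frags("chr1", 1, 20000, genome)   # depth 1 everywhere
  cov <- make_coverage(frags)
  gtf <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t5001\t8000\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t5001\t8000\t.\t+\t.\tgene_id "g1"; transcript_id "g1.1";'),
    ".gtf")
  models <- parse_annotation(gtf, genome = genome_index(genome))
  sm <- signal_matrix(cov, models, "gene_scaled", flank = 1000,
                      bin_width = 10, body_bins = 100)
  expect_equal(dim(sm$matrix), c(1, 100 + 100 + 100))
  expect_equal(unname(sm$matrix[1, ]), rep(unname(sm$matrix[1, 1]), 300),
               tolerance = 1e-6)
  expect_lt(sd(sm$metaplot), 1e-6 * mean(sm$metaplot))
  expect_error(signal_matrix(cov, models, "gene_scaled", flank = 1000,
                             bin_width = 7), "divide")
})

test_that("unnormalized bin sums conserve fragment-bp (1-bp bins)", {
  genome <- c(chr1 = 5000)
  set.seed(31)
  st <- sample.int(4800, 60)
  frags <- make_frags("chr1", st, st + sample(20:120, 60, replace = TRUE),
                      genome)
  cov <- make_coverage(frags)
  # one gene whose body width equals body_bins so every bin is 1 bp
  gtf <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t2001\t2100\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t2001\t2100\t.\t+\t.\tgene_id "g1"; transcript_id "g1.1";'),
    ".gtf")
  models <- parse_annotation(gtf, genome = genome_index(genome))
  sm <- signal_matrix(cov, models, "gene_scaled", flank = 100, bin_width = 1,
                      body_bins = 100)
  unnorm <- sm$matrix[1, ] * ((1 / 1000) * (cov$total_units / 1e6))
  window <- 1901:2200
  expect_equal(sum(unnorm), sum(as.numeric(cov$cov$chr1)[window]),
               tolerance = 1e-9)
})

test_that("minus-strand rows are upstream-leftmost oriented", {
  genome <- c(chr1 = 20000)
  # coverage only upstream of the minus-strand gene (genomic right side)
  frags <- make_frags("chr1", 8001, 8600, genome)
  cov <- make_coverage(frags)
  gtf <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t5001\t8000\t.\t-\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t5001\t8000\t.\t-\t.\tgene_id "g1"; transcript_id "g1.1";'),
    ".gtf")
  models <- parse_annotation(gtf, genome = genome_index(genome))
  sm <- signal_matrix(cov, models, "gene_scaled", flank = 1000,
                      bin_width = 10, body_bins = 100)
  expect_gt(sum(sm$matrix[1, 1:100]), 0)       # upstream columns
  expect_equal(sum(sm$matrix[1, 201:300]), 0)  # downstream columns
})

test_that("promoter-planted accessibility peaks in the upstream flank", {
  sim <- simulate_dataset(simulation_config(seed = 17, n_fragments = 40000,
                                            promoter_bias = 8,
                                            n_accessible_regions = 0,
                                            organelle_fraction = 0))
  paths <- write_simulated_dataset(sim, tempfile())
  models <- parse_annotation(paths[["gtf"]], genome = sim$genome)
  cov <- make_coverage(sim$fragments)
  sm <- signal_matrix(cov, models, "gene_scaled")
  expect_lte(which.max(sm$metaplot), 100)      # within upstream flank bins
})

test_that("peak-centered matrices are summit-anchored", {
  planted <- GRanges("chr1", IRanges(40001, width = 500))
  frags <- sim_caller_fragments(5, planted = planted)
  cov <- make_coverage(frags)
  peaks <- call_peaks(cov)
  sm <- signal_matrix(cov, peaks, "peak_centered", flank = 1000,
                      bin_width = 10)
  expect_equal(ncol(sm$matrix), 200)
  centre <- sm$metaplot[91:110]
  edges <- c(sm$metaplot[1:10], sm$metaplot[191:200])
  expect_gt(mean(centre), 3 * mean(edges))
})

test_that("junction classes split exactly at the 150-bp boundary", {
  genome <- c(chr1 = 10000)
  frags <- make_frags("chr1", c(1001, 2001, 3001),
                      c(1149, 2150, 3151), genome)   # lengths 149/150/151
  tr <- junction_track(frags)
  expect_equal(tr$cls, c("nfr", "nucleosomal", "nucleosomal"))
  expect_equal(tr$color, c("0,0,255", "255,0,0", "255,0,0"))
  single <- make_frags("chr1", 1001, 1149, genome, paired = FALSE)
  expect_error(junction_track(single), "paired-end")
})

test_that("junction BED12 round trip is lossless and well-formed", {
  genome <- c(chr1 = 10000)
  set.seed(41)
  st <- sample.int(8000, 50)
  frags <- make_frags("chr1", st, st + sample(c(80:220, 1500), 50,
                                              replace = TRUE), genome)
  tr <- junction_track(frags)
  path <- tempfile(fileext = ".bed12")
  write_junction_bed12(tr, path)
  back <- read_junction_bed12(path)
  expect_equal(back, tr, ignore_attr = TRUE)
  raw <- read.table(path, sep = "\t")
  expect_true(all(raw[[5]] <= 1000))                  # score cap
  expect_true(all(raw[[10]] == 2))                    # blockCount
  expect_true(all(raw[[12]] == paste0("0,", tr$length - 1)))
})
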