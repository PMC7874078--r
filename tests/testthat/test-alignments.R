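test_that("BAM pairs load as fragments spanning both mates", {
  genome <- c(chr1 = 10000)
  frags <- make_frags("chr1", 101, 250, genome)   # 0-based [100, 250), 150 bp
  sam <- tempfile(fileext = ".sam")
  write_fragments_sam(frags, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  got <- load_fragments(bam, genome = genome_index(genome))
  expect_length(got, 1)
  expect_equal(start(got), 101)
  expect_equal(end(got), 250)
  expect_equal(width(got), 150)
  expect_true(metadata(got)$paired)
})

test_that("empty BAM yields empty fragments with a valid genome index", {
  genome <- genome_index(c(chr1 = 5000, chr2 = 3000))
  sam <- write_lines_tmp(c("@HD\tVN:1.6",
                           "@SQ\tSN:chr1\tLN:5000",
                           "@SQ\tSN:chr2\tLN:3000"), ".sam")
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  got <- load_fragments(bam)
  expect_length(got, 0)
  expect_equal(seqlengths(got), seqlengths(genome))
})

test_that("simulated BAM reproduces the generator's fragment records", {
  sim <- simulate_dataset(simulation_config(seed = 7, n_fragments = 1000))
  paths <- write_simulated_dataset(sim, tempfile())
  bam <- Rsamtools::asBam(paths[["sam"]], tempfile(), overwrite = TRUE)
  got <- load_fragments(bam, genome = sim$genome)
  expect_length(got, 1000)
  expect_identical(sort(granges(got)), sort(granges(sim$fragments)))
  expect_identical(sort(width(got)), sort(sim$manifest$fragment_lengths))
})

test_that("organelle filtering removes the right contigs and reports counts", {
  genome <- c(chr1 = 10000, chrM = 2000)
  st <- c(1, 101, 201, 301, 401, 501, 601, 1, 101, 201)
  frags <- make_frags(c(rep("chr1", 7), rep("chrM", 3)), st, st + 99, genome)
  res <- filter_organelle_and_duplicates(frags, dedup = FALSE)
  expect_length(res$fragments, 7)
  expect_equal(res$report$n_organelle_removed, 3)
  expect_equal(res$report$organelle_fraction, 0.3)
  expect_false(any(seqnames(res$fragments) == "chrM"))
})

test_that("duplicate fragments collapse to one", {
  genome <- c(chr1 = 10000)
  frags <- make_frags("chr1", c(101, 101), c(200, 200), genome)
  res <- filter_organelle_and_duplicates(frags)
  expect_length(res$fragments, 1)
  expect_equal(res$report$n_duplicates_removed, 1)
  # same span on opposite strands is not a duplicate
  frags2 <- make_frags("chr1", c(101, 101), c(200, 200), genome,
                       strand = c("+", "-"))
  expect_length(filter_organelle_and_duplicates(frags2)$fragments, 2)
})

test_that("filtering everything is an error; report is conserved and idempotent", {
  genome <- c(chrM = 2000)
  frags <- make_frags("chrM", 1, 100, genome)
  expect_error(filter_organelle_and_duplicates(frags), "no nuclear contigs")

  sim <- simulate_dataset(simulation_config(seed = 2, n_fragments = 2000))
  res <- filter_organelle_and_duplicates(sim$fragments)
  r <- res$report
  expect_equal(r$n_input,
               r$n_retained + r$n_organelle_removed + r$n_duplicates_removed)
  res2 <- filter_organelle_and_duplicates(res$fragments)
  expect_identical(granges(res2$fragments), granges(res$fragments))
  expect_equal(res2$report$n_organelle_removed, 0)
  expect_equal(res2$report$n_duplicates_removed, 0)
})

test_that("planted organelle fraction 0.5 is reported within [0.48, 0.52]", {
  sim <- simulate_dataset(simulation_config(seed = 11, n_fragments = 10000,
                                            organelle_fraction = 0.5))
  res <- filter_organelle_and_duplicates(sim$fragments, dedup = FALSE)
  expect_gte(res$report$organelle_fraction, 0.48)
  expect_lte(res$report$organelle_fraction, 0.52)
})

test_that("fragment BED round trip is exact", {
  sim <- simulate_dataset(simulation_config(seed = 4, n_fragments = 500))
  path <- tempfile(fileext = ".bed")
  write_fragments_bed(sim$fragments, path)
  back <- read_fragments_bed(path, genome = sim$genome)
  expect_identical(granges(back), granges(sim$fragments))
  expect_identical(mcols(back)$length, width(sim$fragments))
})

test_that("length selection respects cutoff and side", {
  genome <- c(chr1 = 10000)
  frags <- make_frags("chr1", c(1, 1, 1, 1), c(100, 149, 150, 200), genome)
  expect_equal(width(select_fragments_by_length(frags, 150, "at_most")),
               c(100, 149, 150))
  expect_equal(width(select_fragments_by_length(frags, 150, "above")), 200)
  expect_error(select_fragments_by_length(frags, 0), "positive")
  expect_warning(select_fragments_by_length(frags, 10, "at_most"),
                 "no fragments")
})
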