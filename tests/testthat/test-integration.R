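test_that("overlap test reproduces the closed-form toy case exactly", {
  genome <- c(chr1 = 1000)
  A <- GRanges("chr1", IRanges(1, 100))     # 0-based [0,100)
  B <- GRanges("chr1", IRanges(51, 150))    # 0-based [50,150)
  res <- overlap_test(A, B, genome)
  expect_equal(res$n_shared, 1)
  expect_equal(res$population_bins, 10)     # mean width 100 over 1000 bp
  expect_equal(res$p_value, 0.1, tolerance = 1e-15)
  expect_equal(start(res$shared_intervals), 51)
  expect_equal(end(res$shared_intervals), 100)
})

test_that("disjoint peak sets give p = 1", {
  genome <- c(chr1 = 1000)
  A <- GRanges("chr1", IRanges(1, 100))
  B <- GRanges("chr1", IRanges(501, 600))
  res <- overlap_test(A, B, genome)
  expect_equal(res$n_shared, 0)
  expect_equal(res$p_value, 1)
})

test_that("hypergeometric p matches exhaustive draw enumeration for N <= 12", {
  enumerate_p <- function(N, K, n, x_obs) {
    draws <- utils::combn(N, n)
    mean(apply(draws, 2, function(d) sum(d <= K) >= x_obs))
  }
  cases <- list(c(N = 10, K = 3, n = 4, x = 2),
                c(N = 12, K = 5, n = 6, x = 3),
                c(N = 8, K = 2, n = 5, x = 1),
                c(N = 12, K = 6, n = 3, x = 3))
  for (cs in cases) {
    p_pkg <- phyper(cs["x"] - 1, m = cs["K"], n = cs["N"] - cs["K"],
                    k = cs["n"], lower.tail = FALSE)
    expect_equal(unname(p_pkg),
                 enumerate_p(cs["N"], cs["K"], cs["n"], cs["x"]),
                 tolerance = 1e-12)
  }
  # monotone: more sharing never raises the p-value
  ps <- phyper(0:5 - 1, m = 6, n = 6, k = 6, lower.tail = FALSE)
  expect_true(all(diff(ps) <= 0))
})

test_that("overlap intersections are symmetric; tiny genomes are rejected", {
  genome <- c(chr1 = 1000)
  set.seed(3)
  st <- sample.int(800, 5)
  A <- reduce(GRanges("chr1", IRanges(st, width = 60)))
  B <- reduce(GRanges("chr1", IRanges(st + 30, width = 60)))
  ab <- overlap_test(A, B, genome)$shared_intervals
  ba <- overlap_test(B, A, genome)$shared_intervals
  expect_identical(granges(ab), granges(ba))
  expect_error(overlap_test(A, B, c(chr1 = 100)), "too small")
})

test_that("expression groups and accessibility percentages behave", {
  genome <- c(chr1 = 1e5)
  lines <- unlist(lapply(1:10, function(i) {
    s <- i * 5000
    c(sprintf('chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tgene_id "g%02d";', s, s + 999, i),
      sprintf('chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tgene_id "g%02d"; transcript_id "g%02d.1";',
              s, s + 999, i, i))
  }))
  models <- parse_annotation(write_lines_tmp(lines, ".gtf"),
                             genome = genome_index(genome))
  expr <- data.frame(gene_id = sprintf("g%02d", 1:10), rpkm = 1:10)
  # peaks on the 5 highest-expressed genes only
  peaks <- GRanges("chr1", IRanges((6:10) * 5000, width = 200))
  ea <- expression_accessibility(expr, models, peaks, n_groups = 2)
  expect_equal(ea$percent_accessible, c(0, 100))
  expect_equal(unname(ea$venn["top_accessible"]), 5)
  expect_equal(unname(ea$venn["bottom_accessible"]), 0)
  # all genes accessible
  peaks_all <- GRanges("chr1", IRanges((1:10) * 5000, width = 200))
  ea2 <- expression_accessibility(expr, models, peaks_all, n_groups = 2)
  expect_equal(ea2$percent_accessible, c(100, 100))
  # group sizes near-equal over odd splits
  ea3 <- expression_accessibility(expr, models, peaks_all, n_groups = 3)
  sizes <- table(ea3$genes$group)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 10)
  # unknown genes are excluded with a warning
  expr_bad <- rbind(expr, data.frame(gene_id = "nope", rpkm = 5))
  expect_warning(ea4 <- expression_accessibility(expr_bad, models, peaks_all),
                 "missing from annotation")
  expect_equal(ea4$n_excluded, 1)
})

test_that("rank-linked accessibility rises across expression groups", {
  sim <- simulate_dataset(simulation_config(seed = 17, n_fragments = 100,
                                            contigs = c(chr1 = 8e6),
                                            n_genes = 2000))
  paths <- write_simulated_dataset(sim, tempfile())
  models <- parse_annotation(paths[["gtf"]], genome = sim$genome)
  se <- simulate_expression(models, slope = 0.8, base = 0.05, seed = 17)
  ea <- expression_accessibility(se$expression, models, se$peaks)
  inc <- diff(ea$percent_accessible)
  expect_lte(sum(inc < 0), 1)    # non-decreasing up to one sampling inversion
  expect_gt(ea$percent_accessible[10], ea$percent_accessible[1])
})
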