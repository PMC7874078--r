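test_that("candidate regions partition the union by membership", {
  genome <- genome_index(c(chr1 = 1000))
  A <- GRanges("chr1", IRanges(1, 100), seqinfo = genome)    # 0-based [0,100)
  B <- GRanges("chr1", IRanges(51, 150), seqinfo = genome)   # 0-based [50,150)
  segs <- candidate_regions(list(A = A, B = B))
  expect_equal(start(segs), c(1, 51, 101))
  expect_equal(end(segs), c(50, 100, 150))
  expect_equal(segs$A, c(TRUE, TRUE, FALSE))
  expect_equal(segs$B, c(FALSE, TRUE, TRUE))
  # identical sets: one segment per peak, both flags
  segs2 <- candidate_regions(list(A = A, B = A))
  expect_length(segs2, 1)
  expect_true(all(segs2$A & segs2$B))
  # disjoint sets: original intervals, single membership
  C <- GRanges("chr1", IRanges(501, 600), seqinfo = genome)
  segs3 <- candidate_regions(list(A = A, C = C))
  expect_equal(sum(segs3$A & segs3$C), 0)
  expect_length(segs3, 2)
})

test_that("candidate regions conserve the union bp against a mask oracle", {
  set.seed(23)
  genome <- genome_index(c(chr1 = 20000))
  mk <- function() {
    st <- sample.int(19000, 8)
    reduce(GRanges("chr1", IRanges(st, width = sample(100:800, 8,
                                                      replace = TRUE)),
                   seqinfo = genome))
  }
  sets <- list(a = mk(), b = mk(), c = mk())
  segs <- candidate_regions(sets)
  mask <- logical(20000)
  for (s in sets) for (i in seq_along(s))
    mask[start(s)[i]:end(s)[i]] <- TRUE
  expect_equal(sum(width(segs)), sum(mask))
  # adjacent segments always differ in membership
  m <- as.matrix(mcols(segs))
  adjacent <- which(utils::head(end(segs), -1) + 1 == utils::tail(start(segs), -1))
  for (i in adjacent)
    expect_false(all(m[i, ] == m[i + 1, ]))
})

test_that("differential peaks: fold and Welch p follow the definitions", {
  genome <- genome_index(c(chr1 = 10000))
  cand <- GRanges("chr1", IRanges(c(1, 1001, 2001), width = 500),
                  seqinfo = genome)
  ab <- rbind(c(10, 12, 11, 40, 44, 38),
              c(10, 12, 11, 10, 12, 11),
              c(10, 11, 10.5, 16, 17, 16.5))
  calls <- differential_peaks(cand, ab, rep(c("g1", "g2"), each = 3))
  # row 1: clear 4x-ish difference (fold on means with pseudocount 1)
  expect_equal(calls$fold_change[1], (mean(c(40, 44, 38)) + 1) / 12)
  expect_gte(calls$fold_change[1], 2)
  orac <- t.test(log2(c(10, 12, 11) + 1), log2(c(40, 44, 38) + 1))$p.value
  expect_equal(calls$p_value[1], orac, tolerance = 1e-9)
  expect_true(calls$significant[1])
  expect_equal(calls$direction[1], "up_in_g2")
  # row 2: identical groups
  expect_equal(calls$fold_change[2], 1)
  expect_false(calls$significant[2])
  # row 3: fold gate blocks significance regardless of p
  expect_lt(calls$fold_change[3], 2)
  expect_false(calls$significant[3])
})

test_that("differential peaks demand two replicates per group", {
  genome <- genome_index(c(chr1 = 10000))
  cand <- GRanges("chr1", IRanges(1, 500), seqinfo = genome)
  expect_error(
    differential_peaks(cand, matrix(c(1, 2, 3), 1), c("a", "b", "b")),
    "specific_peaks_no_replicate")
})

test_that("group-specific peaks are those with zero overlap", {
  genome <- genome_index(c(chr1 = 1000))
  A <- GRanges("chr1", IRanges(1, 100), seqinfo = genome)
  B <- GRanges("chr1", IRanges(201, 300), seqinfo = genome)
  res <- specific_peaks_no_replicate(A, B)
  expect_identical(res$a_specific, A)
  expect_identical(res$b_specific, B)
  B2 <- GRanges("chr1", IRanges(51, 150), seqinfo = genome)
  res2 <- specific_peaks_no_replicate(A, B2)
  expect_length(res2$a_specific, 0)
  expect_length(res2$b_specific, 0)
  res3 <- specific_peaks_no_replicate(A, A)
  expect_length(res3$a_specific, 0)
})

test_that("reproducible peaks require reciprocal overlap in every replicate", {
  genome <- genome_index(c(chr1 = 1000))
  r1 <- GRanges("chr1", IRanges(1, 100), seqinfo = genome)
  expect_length(reproducible_peaks(list(r1, r1, r1)), 1)
  r2 <- GRanges("chr1", IRanges(41, 140), seqinfo = genome)  # 0.6 reciprocal
  expect_length(reproducible_peaks(list(r1, r2)), 1)
  r3 <- GRanges("chr1", IRanges(91, 190), seqinfo = genome)  # 0.1 reciprocal
  expect_length(reproducible_peaks(list(r1, r3)), 0)
})

test_that("GMM flags planted outliers and is symmetric and deterministic", {
  fx <- gmm_outlier_fixture(13)
  calls <- differential_promoters_gmm(fx$a, fx$b, seed = 1)
  expect_gte(sum(calls$outlier[fx$is_outlier]), 9)
  expect_lte(mean(calls$outlier[!fx$is_outlier]), 0.08)
  swapped <- differential_promoters_gmm(fx$b, fx$a, seed = 1)
  expect_identical(calls$outlier, swapped$outlier)
  again <- differential_promoters_gmm(fx$a, fx$b, seed = 1)
  expect_identical(calls$gmm_p, again$gmm_p)
})

test_that("GMM rejects degenerate input", {
  expect_error(differential_promoters_gmm(rep(5, 30), rep(5, 30)),
               "zero-variance")
  expect_error(differential_promoters_gmm(1:10, 1:10), "at least 20")
})
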