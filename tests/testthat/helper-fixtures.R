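suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# fragments from explicit 1-based closed coordinates
make_frags <- function(contig, start, end, genome, strand = "+",
                       paired = TRUE) {
  gr <- GRanges(contig, IRanges(start, end), strand = strand,
                seqinfo = genome_index(genome))
  mcols(gr)$length <- width(gr)
  metadata(gr)$paired <- paired
  gr
}

# helper used for peak-caller calibration: uniform background fragments at
# `rate` per bp plus an optional planted region at `mult` x background
sim_caller_fragments <- function(seed, genome_len = 1e5, planted = NULL,
                                 rate = 0.02, mult = 20, fraglen = 100) {
  set.seed(seed)
  genome <- genome_index(c(chr1 = genome_len))
  n_bg <- rpois(1, rate * genome_len)
  st <- sample.int(genome_len - fraglen, n_bg, replace = TRUE)
  if (!is.null(planted)) {
    n_p <- rpois(1, rate * (mult - 1) * width(planted))
    st <- c(st, round(runif(n_p, start(planted) - fraglen / 2,
                            end(planted) - fraglen / 2)))
    st <- pmax(1, pmin(st, genome_len - fraglen))
  }
  make_frags("chr1", st, st + fraglen - 1, c(chr1 = genome_len))
}

# bivariate GMM outlier fixture: n_in correlated log-scale inliers plus
# n_out planted outliers at Mahalanobis radius 6-9
gmm_outlier_fixture <- function(seed, n_in = 500, n_out = 10) {
  set.seed(seed)
  mu <- c(4, 4)
  cv <- matrix(c(1, 0.8, 0.8, 1), 2)
  L <- chol(cv)
  z <- matrix(rnorm(2 * n_in), n_in) %*% L + rep(mu, each = n_in)
  th <- runif(n_out, 0, 2 * pi)
  r <- runif(n_out, 6, 9)
  zo <- t(vapply(seq_len(n_out), function(i)
    mu + r[i] * (c(cos(th[i]), sin(th[i])) %*% L)[1, ], numeric(2)))
  ab <- 2^rbind(z, zo) - 1
  ab[ab < 0] <- 0
  list(a = ab[, 1], b = ab[, 2],
       is_outlier = rep(c(FALSE, TRUE), c(n_in, n_out)))
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny GTF: one + gene 101..200 and one - gene 1001..2000 with two
# transcripts' exons on the + gene
tiny_gtf <- function() {
  write_lines_tmp(c(
    'chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\tsrc\texon\t101\t150\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.2";',
    'chr1\tsrc\texon\t101\t160\t.\t+\t.\tgene_id "gA"; transcript_id "gA.2";',
    'chr1\tsrc\texon\t181\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.2";',
    'chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tgene_id "gB";',
    'chr1\tsrc\texon\t1001\t2000\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";'
  ), ".gtf")
}
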