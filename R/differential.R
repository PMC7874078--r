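# Differential accessibility between sample groups.
#
# With replicates: candidate regions (a sweep-line partition of the union of
# all input peak sets, as produced by multi-set intersection), then a
# fold-change gate plus Welch t-test on log2(RPKM + 1).  Without replicates:
# group-specific peaks by absence of overlap.  Promoters: a bivariate
# Gaussian-mixture outlier model on (log2(a+1), log2(b+1)) abundances.

#' Partition the union of peak sets into constant-membership segments
#'
#' Sweep-line equivalent of BEDTools `multiinter`: the union of all input
#' peaks is cut into maximal segments whose set membership is constant.
#'
#' @param peak_sets Named list (>= 2) of peak `GRanges`, each internally
#'   merged.
#' @return `GRanges` of candidate regions with one logical metadata column
#'   per input set.
#' @export
candidate_regions <- function(peak_sets) {
  if (length(peak_sets) < 2) stop("need at least two peak sets")
  if (is.null(names(peak_sets)))
    names(peak_sets) <- sprintf("set%d", seq_along(peak_sets))
  peak_sets <- lapply(peak_sets, function(gr)
    reduce(granges(gr), ignore.strand = TRUE))
  pooled <- do.call(c, unname(peak_sets))
  segs <- disjoin(pooled, ignore.strand = TRUE)
  memb <- vapply(peak_sets, function(gr)
    overlapsAny(segs, gr, minoverlap = 1, ignore.strand = TRUE),
    logical(length(segs)))
  if (length(segs) == 1) memb <- matrix(memb, nrow = 1,
                                        dimnames = list(NULL, names(peak_sets)))
  mcols(segs) <- S4Vectors::DataFrame(memb)
  sort(segs)
}

#' Per-region RPKM abundance from a fragment library
#' @param regions `GRanges` of regions.
#' @param fragments Fragment `GRanges` (one replicate's retained library).
#' @return Numeric RPKM vector, one value per region.
#' @export
region_rpkm <- function(regions, fragments) {
  total <- length(fragments)
  if (total == 0) stop("zero fragments: RPKM undefined")
  count <- countOverlaps(regions, fragments, minoverlap = 1,
                         ignore.strand = TRUE)
  count / ((width(regions) / 1000) * (total / 1e6))
}

# vectorized Welch two-sample t-test on rows of two matrices
.row_welch <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  # degenerate zero-variance rows: identical means are null, different are not
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p
}

#' Differentially accessible regions between two replicate groups
#'
#' A region is significant when the raw-abundance fold change (group means
#' with pseudocount 1) is at least `fold_threshold` and the Welch two-sample
#' t-test on log2(RPKM + 1) gives p below `p_threshold` — the package
#' defaults mirror the conventional >= 2-fold, p < 0.05 gate.  No
#' multiple-testing correction is applied by default; set `fdr = TRUE` for
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param candidates `GRanges` of candidate regions.
#' @param abundance Numeric matrix, rows = candidates, columns = replicates
#'   (RPKM).
#' @param groups Factor/character of length `ncol(abundance)` with exactly
#'   two levels; >= 2 replicates per group.
#' @param fold_threshold Minimum fold change (larger/smaller). Default 2.
#' @param p_threshold p-value threshold. Default 0.05.
#' @param fdr Apply BH correction before thresholding. Default FALSE.
#' @return A `differential_calls` data.frame: region coordinates,
#'   mean_abundance_g1/g2, fold_change, p_value, direction, significant.
#' @export
differential_peaks <- function(candidates, abundance, groups,
                               fold_threshold = 2, p_threshold = 0.05,
                               fdr = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2))
    stop("fewer than 2 replicates in a group; use specific_peaks_no_replicate")
  if (nrow(abundance) != length(candidates))
    stop("abundance rows must match candidates")
  if (any(abundance < 0)) stop("abundances must be >= 0")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  a <- abundance[, groups == g1, drop = FALSE]
  b <- abundance[, groups == g2, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  fold <- pmax(m1 + 1, m2 + 1) / pmin(m1 + 1, m2 + 1)
  p <- .row_welch(log2(a + 1), log2(b + 1))
  if (fdr) p <- p.adjust(p, method = "BH")
  out <- data.frame(
    contig = as.character(seqnames(candidates)),
    start = start(candidates) - 1L, end = end(candidates),
    mean_abundance_g1 = m1, mean_abundance_g2 = m2,
    fold_change = fold, p_value = p,
    direction = ifelse(m2 >= m1, "up_in_g2", "down_in_g2"),
    significant = fold >= fold_threshold & p < p_threshold,
    stringsAsFactors = FALSE)
  class(out) <- c("differential_calls", "data.frame")
  attr(out, "groups") <- c(g1, g2)
  out
}

#' Group-specific peaks without replicates
#'
#' A peak is group-specific when its location is unique to that group: it
#' overlaps no peak of the other group by even 1 bp.
#'
#' @param peaks_a,peaks_b Merged peak `GRanges` for the two groups.
#' @param reproducible_input Caller certifies inputs were already
#'   reproducibility-filtered (e.g. by IDR or [reproducible_peaks()]);
#'   informational flag only.
#' @return List with `a_specific` and `b_specific` `GRanges`.
#' @export
specific_peaks_no_replicate <- function(peaks_a, peaks_b,
                                        reproducible_input = FALSE) {
  a_spec <- peaks_a[!overlapsAny(peaks_a, peaks_b, minoverlap = 1,
                                 ignore.strand = TRUE)]
  b_spec <- peaks_b[!overlapsAny(peaks_b, peaks_a, minoverlap = 1,
                                 ignore.strand = TRUE)]
  list(a_specific = a_spec, b_specific = b_spec,
       reproducible_input = isTRUE(reproducible_input))
}

#' Overlap-based reproducible peaks across replicates
#'
#' A lightweight stand-in for reproducibility filtering: peaks of the first
#' replicate are kept when every other replicate contains a peak with
#' reciprocal overlap of at least `min_overlap_fraction` (of both peak
#' lengths).
#'
#' @param replicate_peak_sets List (>= 2) of peak `GRanges`.
#' @param min_overlap_fraction Reciprocal overlap threshold in (0,1].
#'   Default 0.5.
#' @return `GRanges`: the reproducible peaks of replicate 1.
#' @export
reproducible_peaks <- function(replicate_peak_sets,
                               min_overlap_fraction = 0.5) {
  if (length(replicate_peak_sets) < 2)
    stop("need at least two replicate peak sets")
  base <- replicate_peak_sets[[1]]
  keep <- rep(TRUE, length(base))
  for (other in replicate_peak_sets[-1]) {
    hits <- findOverlaps(base, other, ignore.strand = TRUE)
    ow <- width(pintersect(base[queryHits(hits)], other[subjectHits(hits)],
                           ignore.strand = TRUE))
    good <- ow >= min_overlap_fraction * width(base[queryHits(hits)]) &
            ow >= min_overlap_fraction * width(other[subjectHits(hits)])
    keep <- keep & seq_along(base) %in% unique(queryHits(hits)[good])
  }
  base[keep]
}

# ---------------------------------------------------------------------------
# bivariate Gaussian mixture (EM), used for promoter outlier detection

.gmm_loglik <- function(x, fit) {
  dens <- vapply(seq_along(fit$weights), function(j)
    fit$weights[j] * mvtnorm::dmvnorm(x, fit$means[[j]], fit$covs[[j]]),
    numeric(nrow(x)))
  if (nrow(x) == 1) dens <- matrix(dens, nrow = 1)
  sum(log(pmax(rowSums(dens), 1e-300)))
}

.fit_gmm_once <- function(x, k, init_cluster, max_iter = 200, tol = 1e-8,
                          reg = 1e-6) {
  n <- nrow(x)
  scale_reg <- reg * mean(apply(x, 2, stats::var))
  if (scale_reg == 0) scale_reg <- reg
  means <- lapply(seq_len(k), function(j) colMeans(x[init_cluster == j, ,
                                                     drop = FALSE]))
  covs <- lapply(seq_len(k), function(j) {
    xj <- x[init_cluster == j, , drop = FALSE]
    cv <- if (nrow(xj) > 2) stats::cov(xj) else stats::cov(x)
    cv + diag(scale_reg, 2)
  })
  weights <- as.numeric(table(factor(init_cluster, levels = seq_len(k)))) / n
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      pmax(weights[j] * mvtnorm::dmvnorm(x, means[[j]], covs[[j]]), 1e-300),
      numeric(n))
    if (n == 1) dens <- matrix(dens, nrow = 1)
    tot <- rowSums(dens)
    resp <- dens / tot
    ll <- sum(log(tot))
    nk <- colSums(resp)
    weights <- nk / n
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2, mu)
      cv <- crossprod(xc * resp[, j], xc) / nk[j] + diag(scale_reg, 2)
      means[[j]] <- mu
      covs[[j]] <- cv
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(weights = weights, means = means, covs = covs, loglik = ll, k = k)
}

.fit_gmm <- function(x, k, n_restarts = 10) {
  n <- nrow(x)
  if (k == 1)
    return(.fit_gmm_once(x, 1, rep(1L, n)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- tryCatch(kmeans(x, centers = k, nstart = 1)$cluster,
                     error = function(e) sample.int(k, n, replace = TRUE))
    if (length(unique(init)) < k) init <- sample.int(k, n, replace = TRUE)
    fit <- tryCatch(.fit_gmm_once(x, k, init), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  best
}

#' Differentially accessible promoters via a Gaussian-mixture outlier model
#'
#' Promoter abundances of the two samples are log-transformed
#' (`log2(x + 1)`) and modeled with a bivariate Gaussian mixture; the number
#' of components (1..`n_components_max`) is chosen by BIC over EM fits with
#' deterministic seeded restarts.  Each gene's tail probability is the
#' chi-square(2) survival function at its squared Mahalanobis distance to the
#' most responsible component; promoters with `gmm_p` below `p_threshold`
#' are flagged as differentially accessible.  Mixture components holding
#' less than `min_weight` of the data are rejected during model selection so
#' that a handful of true outliers cannot form their own component and
#' escape detection.
#'
#' @param abundance_a,abundance_b Numeric promoter abundances (RPKM) per
#'   gene, same length (>= 20).
#' @param gene_ids Optional gene identifiers.
#' @param n_components_max Maximum mixture components. Default 3.
#' @param p_threshold Outlier threshold on the tail probability. Default 0.05.
#' @param min_weight Minimum admissible component weight. Default 0.05.
#' @param seed Seed for the deterministic restarts. Default 1.
#' @return A `promoter_calls` data.frame: gene_id, abundance_a, abundance_b,
#'   gmm_p, outlier; attribute `n_components` records the selected model.
#' @export
differential_promoters_gmm <- function(abundance_a, abundance_b,
                                       gene_ids = NULL,
                                       n_components_max = 3,
                                       p_threshold = 0.05,
                                       min_weight = 0.05, seed = 1) {
  if (length(abundance_a) != length(abundance_b))
    stop("abundance vectors must have equal length")
  n <- length(abundance_a)
  if (n < 20) stop("need at least 20 genes with finite abundances")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(n))
  x <- cbind(log2(abundance_a + 1), log2(abundance_b + 1))
  if (!all(is.finite(x))) stop("non-finite abundances")
  if (all(apply(x, 2, function(c) length(unique(c)) == 1)))
    stop("zero-variance input")
  fits <- .with_seed(seed, {
    lapply(seq_len(n_components_max), function(k) .fit_gmm(x, k))
  })
  npar <- function(k) (k - 1) + k * (2 + 3)
  bic <- vapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    if (is.null(f)) return(Inf)
    if (k > 1 && any(f$weights < min_weight)) return(Inf)
    -2 * f$loglik + npar(k) * log(n)
  }, numeric(1))
  k_sel <- which.min(bic)
  fit <- fits[[k_sel]]
  dens <- vapply(seq_len(fit$k), function(j)
    fit$weights[j] * mvtnorm::dmvnorm(x, fit$means[[j]], fit$covs[[j]]),
    numeric(n))
  if (n == 1) dens <- matrix(dens, nrow = 1)
  comp <- max.col(dens, ties.method = "first")
  d2 <- vapply(seq_len(n), function(i) {
    j <- comp[i]
    stats::mahalanobis(x[i, , drop = FALSE], fit$means[[j]], fit$covs[[j]])
  }, numeric(1))
  gmm_p <- pchisq(d2, df = 2, lower.tail = FALSE)
  out <- data.frame(gene_id = gene_ids, abundance_a = abundance_a,
                    abundance_b = abundance_b, gmm_p = gmm_p,
                    outlier = gmm_p < p_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_calls", "data.frame")
  attr(out, "n_components") <- fit$k
  out
}

#' Write differential calls or promoter calls as TSV
#' @param calls A `differential_calls` or `promoter_calls` data.frame.
#' @param path Output TSV.
#' @export
write_differential <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
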