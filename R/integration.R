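# Integration with other interval datasets (ChIP-seq, DNase, MNase) and with
# RNA-seq expression.

#' Hypergeometric overlap test between two peak sets
#'
#' The genome is modeled as `N = floor(S_g / mean width of all peaks)`
#' equally sized bins; drawing the `n_b` B peaks from the `N` bins, the
#' number landing on the `n_a` A-peak bins follows a hypergeometric
#' distribution, and the p-value is the upper tail at the observed count of
#' A peaks with at least 1 bp of B overlap.  The bin population model is a
#' package convention (the test itself is standard); an alternative `N` can
#' be supplied.
#'
#' @param peaks_a,peaks_b Merged peak `GRanges`.
#' @param genome `Seqinfo` genome index.
#' @param population_bins Optional explicit `N` overriding the bin model.
#' @return An `overlap_test`: n_a, n_b, n_shared, population_bins, p_value,
#'   shared_intervals (`GRanges` of A/B intersections).
#' @export
overlap_test <- function(peaks_a, peaks_b, genome, population_bins = NULL) {
  genome <- genome_index(genome)
  peaks_a <- reduce(granges(peaks_a), ignore.strand = TRUE)
  peaks_b <- reduce(granges(peaks_b), ignore.strand = TRUE)
  n_a <- length(peaks_a); n_b <- length(peaks_b)
  if (n_a == 0 || n_b == 0) stop("both peak sets must be non-empty")
  n_shared <- sum(overlapsAny(peaks_a, peaks_b, minoverlap = 1,
                              ignore.strand = TRUE))
  if (is.null(population_bins)) {
    wbar <- mean(width(c(peaks_a, peaks_b)))
    population_bins <- floor(genome_size(genome) / wbar)
  }
  N <- population_bins
  if (N < max(n_a, n_b)) stop("genome too small for bin model")
  p <- phyper(n_shared - 1, m = n_a, n = N - n_a, k = n_b,
              lower.tail = FALSE)
  shared <- intersect(peaks_a, peaks_b, ignore.strand = TRUE)
  structure(list(n_a = n_a, n_b = n_b, n_shared = n_shared,
                 population_bins = N, p_value = p,
                 shared_intervals = shared),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "peak overlap: %d of %d A peaks share >=1 bp with %d B peaks (N = %d, p = %.3g)\n",
    x$n_shared, x$n_a, x$n_b, x$population_bins, x$p_value))
  invisible(x)
}

#' Write overlap-test outputs (shared-interval BED + summary JSON)
#' @param test An `overlap_test`.
#' @param bed,json Output paths (either may be NULL).
#' @export
write_overlap_test <- function(test, bed = NULL, json = NULL) {
  if (!is.null(bed)) .write_bed(test$shared_intervals, bed)
  if (!is.null(json))
    jsonlite::write_json(test[c("n_a", "n_b", "n_shared",
                                "population_bins", "p_value")],
                         json, auto_unbox = TRUE, digits = NA)
  invisible(test)
}

#' Read an expression table (gene_id, RPKM)
#' @param path TSV with a header or two unnamed columns.
#' @return data.frame with columns gene_id, rpkm.
#' @export
read_expression_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("gene", tolower(first))
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  data.frame(gene_id = as.character(tab[[1]]), rpkm = as.numeric(tab[[2]]),
             stringsAsFactors = FALSE)
}

#' Relate chromatin accessibility to gene expression
#'
#' Genes are ranked by expression (RPKM, ties broken by gene id for
#' determinism) and split into `n_groups` near-equal quantile groups (group 1
#' = lowest expression).  A gene is accessible when its gene body or
#' promoter overlaps at least one peak by >= 1 bp.  Returns the percent of
#' accessible genes per group and Venn counts for the top vs bottom group.
#'
#' @param expression data.frame with gene_id and rpkm columns (see
#'   [read_expression_table()]).
#' @param models A `gene_models` object.
#' @param peaks Peak `GRanges`.
#' @param n_groups Number of expression groups. Default 10.
#' @param promoter_length Promoter window used for accessibility (bp).
#'   Default 1000.
#' @return An `expression_accessibility`: per-gene table (gene_id, rpkm,
#'   group, accessible), per-group percent_accessible, venn counts
#'   (top_accessible, top_inaccessible, bottom_accessible,
#'   bottom_inaccessible), n_excluded.
#' @export
expression_accessibility <- function(expression, models, peaks,
                                     n_groups = 10, promoter_length = 1000) {
  stopifnot(inherits(models, "gene_models"))
  known <- expression$gene_id %in% names(models$genes)
  n_excluded <- sum(!known)
  if (n_excluded > 0)
    warning(sprintf("%d genes missing from annotation excluded", n_excluded))
  expr <- expression[known, , drop = FALSE]
  if (nrow(expr) == 0) stop("no expression genes resolvable in annotation")
  ord <- order(expr$rpkm, expr$gene_id)
  expr <- expr[ord, , drop = FALSE]
  n <- nrow(expr)
  # near-equal group sizes, difference <= 1, group 1 = lowest expression
  group <- rep(seq_len(n_groups), times = diff(floor(seq(0, n,
                                                         length.out = n_groups + 1))))
  genes <- models$genes[expr$gene_id]
  prom <- trim(promoters(genes, upstream = promoter_length, downstream = 0))
  accessible <- overlapsAny(genes, peaks, minoverlap = 1,
                            ignore.strand = TRUE) |
    (width(prom) > 0 & overlapsAny(prom, peaks, minoverlap = 1,
                                   ignore.strand = TRUE))
  percent <- vapply(seq_len(n_groups), function(g)
    100 * mean(accessible[group == g]), numeric(1))
  top <- group == n_groups
  bottom <- group == 1
  venn <- c(top_accessible = sum(top & accessible),
            top_inaccessible = sum(top & !accessible),
            bottom_accessible = sum(bottom & accessible),
            bottom_inaccessible = sum(bottom & !accessible))
  structure(list(
    genes = data.frame(gene_id = expr$gene_id, rpkm = expr$rpkm,
                       group = group, accessible = accessible,
                       stringsAsFactors = FALSE),
    percent_accessible = percent,
    venn = venn,
    n_excluded = n_excluded
  ), class = "expression_accessibility")
}

#' @export
print.expression_accessibility <- function(x, ...) {
  cat("accessible genes per expression group (%):\n")
  print(round(x$percent_accessible, 1))
  cat(sprintf("top group: %d/%d accessible; bottom group: %d/%d accessible\n",
              x$venn["top_accessible"],
              x$venn["top_accessible"] + x$venn["top_inaccessible"],
              x$venn["bottom_accessible"],
              x$venn["bottom_accessible"] + x$venn["bottom_inaccessible"]))
  invisible(x)
}

#' Write expression-accessibility outputs
#' @param ea An `expression_accessibility`.
#' @param genes_tsv,groups_tsv,venn_json Output paths (any may be NULL).
#' @export
write_expression_accessibility <- function(ea, genes_tsv = NULL,
                                           groups_tsv = NULL,
                                           venn_json = NULL) {
  if (!is.null(genes_tsv))
    write.table(ea$genes, genes_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(groups_tsv))
    write.table(data.frame(group = seq_along(ea$percent_accessible),
                           percent_accessible = ea$percent_accessible),
                groups_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(venn_json))
    jsonlite::write_json(as.list(ea$venn), venn_json, auto_unbox = TRUE,
                         digits = NA)
  invisible(ea)
}
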