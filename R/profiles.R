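# Feature enrichment, anchored signal matrices and junction tracks.

#' Genomic-feature fold enrichment of peaks
#'
#' For each feature f the statistic is
#' `log2((S_Pf / S_P) / (S_gf / S_g))` where S_P is the total peak size,
#' S_g the genome size, S_Pf the peak/feature overlap and S_gf the feature
#' size, all in bp.  Positive values mean accessible chromatin concentrates
#' in the feature.  Features with zero size or zero overlap are reported as
#' undefined (`NA`, `defined = FALSE`) rather than +/-Inf.
#'
#' @param peaks Peak `GRanges`; overlapping peaks are merged before S_P
#'   accounting.
#' @param feature_set A `feature_set` from [build_feature_set()].
#' @param genome Optional `Seqinfo`; defaults to the feature set's genome.
#' @return An `enrichment_result` data.frame with columns feature, S_P, S_g,
#'   S_Pf, S_gf, log2_enrichment, defined.
#' @export
fold_enrichment <- function(peaks, feature_set, genome = NULL) {
  stopifnot(inherits(feature_set, "feature_set"))
  if (length(peaks) == 0) stop("no peaks")
  if (is.null(genome)) genome <- feature_set$genome
  genome <- genome_index(genome)
  peaks <- reduce(granges(peaks), ignore.strand = TRUE)
  s_p <- sum(as.numeric(width(peaks)))
  s_g <- genome_size(genome)
  rows <- lapply(names(feature_set$features), function(f) {
    feat <- feature_set$features[[f]]
    s_gf <- feature_set$sizes[[f]]
    s_pf <- sum(as.numeric(width(intersect(peaks, feat,
                                           ignore.strand = TRUE))))
    defined <- s_gf > 0 && s_pf > 0
    data.frame(feature = f, S_P = s_p, S_g = s_g, S_Pf = s_pf, S_gf = s_gf,
               log2_enrichment = if (defined)
                 log2((s_pf / s_p) / (s_gf / s_g)) else NA_real_,
               defined = defined)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write enrichment results as TSV
#' @param enrichment An `enrichment_result`.
#' @param path Output TSV.
#' @export
write_enrichment <- function(enrichment, path) {
  write.table(as.data.frame(enrichment), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Bar chart of feature enrichment
#' @param enrichment An `enrichment_result`.
#' @param path Optional PNG path.
#' @export
plot_enrichment <- function(enrichment, path = NULL) {
  if (!is.null(path)) { grDevices::png(path, 800, 500); on.exit(grDevices::dev.off()) }
  e <- enrichment[enrichment$defined, ]
  graphics::barplot(e$log2_enrichment, names.arg = e$feature, las = 2,
                    ylab = "log2 fold enrichment",
                    main = "Peak enrichment by genomic feature")
  invisible(enrichment)
}

# sum of depth over [lo, hi] on a contig depth vector, clipped; 0 when empty
.bin_sums <- function(depth, lo, hi) {
  n <- length(depth)
  cs <- c(0, cumsum(depth))
  lo2 <- pmax(lo, 1L); hi2 <- pmin(hi, n)
  out <- numeric(length(lo))
  ok <- lo2 <= hi2
  out[ok] <- cs[hi2[ok] + 1L] - cs[lo2[ok]]
  out
}

#' Anchored signal matrix (heatmap) and metaplot
#'
#' Two layouts: `gene_scaled` rows are `[flank/bin_width upstream bins]
#' [body_bins scaled-body bins][flank/bin_width downstream bins]`,
#' strand-oriented so upstream is leftmost; `peak_centered` rows are a fixed
#' `2*flank` window around the peak summit.  Each bin holds the fragment
#' depth sum normalized like RPKM: counts per bin-kilobase per million
#' contributing units.  Rows are ranked by descending row mean for the
#' heatmap; the metaplot is the column mean.
#'
#' @param coverage A `coverage_track`.
#' @param anchors Gene models (`gene_models`) for `gene_scaled`, or a peak
#'   `GRanges` for `peak_centered`.
#' @param layout `"gene_scaled"` or `"peak_centered"`.
#' @param flank Flank size in bp (> 0, multiple of `bin_width`). Default 1000.
#' @param bin_width Bin width in bp. Default 10.
#' @param body_bins Number of scaled gene-body bins. Default 100.
#' @return A `signal_matrix`: `matrix` (rows sorted by descending mean, named
#'   by anchor id), `metaplot` (column means), plus layout parameters.
#' @export
signal_matrix <- function(coverage, anchors,
                          layout = c("gene_scaled", "peak_centered"),
                          flank = 1000, bin_width = 10, body_bins = 100) {
  layout <- match.arg(layout)
  stopifnot(inherits(coverage, "coverage_track"))
  if (flank <= 0) stop("flank must be > 0")
  if (flank %% bin_width != 0) stop("bin_width must divide flank")
  n_flank_bins <- flank %/% bin_width
  total <- coverage$total_units
  norm <- function(sums, bin_len) {
    v <- numeric(length(sums))
    ok <- bin_len > 0
    v[ok] <- sums[ok] / ((bin_len[ok] / 1000) * (total / 1e6))
    v
  }
  if (layout == "gene_scaled") {
    if (!inherits(anchors, "gene_models"))
      stop("gene_scaled layout needs gene models")
    genes <- anchors$genes
    ids <- names(genes)
    if (any(width(genes) == 0)) stop("zero-length gene body")
    ncol_total <- 2 * n_flank_bins + body_bins
  } else {
    genes <- anchors
    ids <- if (!is.null(mcols(genes)$name)) mcols(genes)$name
           else sprintf("peak_%d", seq_along(genes))
    ncol_total <- 2 * n_flank_bins
  }
  mat <- matrix(0, nrow = length(genes), ncol = ncol_total)
  rownames(mat) <- ids
  depth_cache <- new.env(parent = emptyenv())
  get_depth <- function(ctg) {
    if (!is.null(depth_cache[[ctg]])) return(depth_cache[[ctg]])
    d <- if (ctg %in% names(coverage$cov)) as.numeric(coverage$cov[[ctg]])
         else numeric(0)
    depth_cache[[ctg]] <- d
    d
  }
  for (i in seq_along(genes)) {
    ctg <- as.character(seqnames(genes)[i])
    depth <- get_depth(ctg)
    if (layout == "gene_scaled") {
      s <- start(genes)[i]; e <- end(genes)[i]
      minus <- as.character(strand(genes)[i]) == "-"
      # flank bins, genomic left-to-right
      up_lo <- seq(s - flank, s - bin_width, by = bin_width)
      dn_lo <- seq(e + 1, e + flank - bin_width + 1, by = bin_width)
      up <- .bin_sums(depth, up_lo, up_lo + bin_width - 1L)
      dn <- .bin_sums(depth, dn_lo, dn_lo + bin_width - 1L)
      bnd <- round(seq(s - 1, e, length.out = body_bins + 1))
      body_lo <- bnd[-length(bnd)] + 1L
      body_hi <- bnd[-1]
      body <- .bin_sums(depth, body_lo, body_hi)
      row_sums <- c(up, body, dn)
      row_len <- c(rep(bin_width, n_flank_bins), pmax(body_hi - body_lo + 1, 0),
                   rep(bin_width, n_flank_bins))
      vals <- norm(row_sums, row_len)
      if (minus) vals <- rev(vals)
      mat[i, ] <- vals
    } else {
      summit <- if ("summit" %in% names(mcols(genes)))
        mcols(genes)$summit[i] else
        (start(genes)[i] + end(genes)[i]) %/% 2L
      lo <- seq(summit - flank, summit + flank - bin_width, by = bin_width)
      sums <- .bin_sums(depth, lo, lo + bin_width - 1L)
      mat[i, ] <- norm(sums, rep(bin_width, length(lo)))
    }
  }
  ord <- order(rowMeans(mat), decreasing = TRUE)
  mat <- mat[ord, , drop = FALSE]
  structure(list(matrix = mat, metaplot = colMeans(mat), layout = layout,
                 flank = flank, bin_width = bin_width,
                 body_bins = if (layout == "gene_scaled") body_bins else 0L),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal matrix (%s): %d anchors x %d bins\n", x$layout,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write a signal matrix (TSV) and its metaplot (TSV)
#' @param sm A `signal_matrix`.
#' @param matrix_path,metaplot_path Output TSVs (either may be NULL).
#' @export
write_signal_matrix <- function(sm, matrix_path = NULL, metaplot_path = NULL) {
  if (!is.null(matrix_path))
    write.table(data.frame(anchor = rownames(sm$matrix), sm$matrix,
                           check.names = FALSE),
                matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metaplot_path))
    write.table(data.frame(bin = seq_along(sm$metaplot),
                           mean_signal = sm$metaplot),
                metaplot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sm)
}

#' Metaplot rendering
#' @param sm A `signal_matrix`.
#' @param path Optional PNG path.
#' @export
plot_metaplot <- function(sm, path = NULL) {
  if (!is.null(path)) { grDevices::png(path, 900, 500); on.exit(grDevices::dev.off()) }
  graphics::plot(seq_along(sm$metaplot), sm$metaplot, type = "l",
                 xlab = "bin", ylab = "mean normalized signal",
                 main = sprintf("Metaplot (%s)", sm$layout))
  invisible(sm)
}

#' Heatmap rendering (rows ranked by mean accessibility)
#' @param sm A `signal_matrix`.
#' @param path Optional PNG path.
#' @export
plot_signal_heatmap <- function(sm, path = NULL) {
  if (!is.null(path)) { grDevices::png(path, 700, 900); on.exit(grDevices::dev.off()) }
  m <- sm$matrix[rev(seq_len(nrow(sm$matrix))), , drop = FALSE]
  graphics::image(t(m), axes = FALSE, useRaster = TRUE,
                  main = sprintf("Accessibility heatmap (%s)", sm$layout))
  invisible(sm)
}

.JUNCTION_NFR_COLOR <- c(0L, 0L, 255L)    # blue, nucleosome-free
.JUNCTION_NUC_COLOR <- c(255L, 0L, 0L)    # red, nucleosome-spanning

#' Fragment junction track for IGV
#'
#' One arc per paired-end fragment connecting its start and end.  Fragments
#' shorter than `threshold` bp are classified `nfr` and colored blue
#' (0,0,255); fragments of `threshold` bp or longer are `nucleosomal`, red
#' (255,0,0).  The boundary length itself (150 bp by default) is assigned to
#' the nucleosomal class.
#'
#' @param fragments Paired-end fragment `GRanges`.
#' @param threshold Length class boundary (bp). Default 150.
#' @return A `junction_track` data.frame: contig, start (0-based), end,
#'   length, cls, color (R,G,B string).
#' @export
junction_track <- function(fragments, threshold = 150) {
  if (!isTRUE(metadata(fragments)$paired))
    stop("junction track requires paired-end fragments")
  len <- width(fragments)
  cls <- ifelse(len < threshold, "nfr", "nucleosomal")
  color <- ifelse(cls == "nfr",
                  paste(.JUNCTION_NFR_COLOR, collapse = ","),
                  paste(.JUNCTION_NUC_COLOR, collapse = ","))
  out <- data.frame(contig = as.character(seqnames(fragments)),
                    start = start(fragments) - 1L, end = end(fragments),
                    length = len, cls = cls, color = color,
                    stringsAsFactors = FALSE)
  class(out) <- c("junction_track", "data.frame")
  out
}

#' Write a junction track as BED12
#'
#' blockCount 2 with 1-bp blocks at the two fragment ends; score is the
#' fragment length capped at 1000; itemRgb encodes the length class.
#' @param track A `junction_track`.
#' @param path Output BED12 path.
#' @export
write_junction_bed12 <- function(track, path) {
  df <- data.frame(
    contig = track$contig, start = track$start, end = track$end,
    name = sprintf("junction_%d", seq_len(nrow(track))),
    score = pmin(track$length, 1000L), strand = ".",
    thickStart = track$start, thickEnd = track$end,
    itemRgb = track$color, blockCount = 2L,
    blockSizes = "1,1",
    blockStarts = paste0("0,", track$length - 1L))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED12 junction track back into a `junction_track`
#' @param path BED12 path written by [write_junction_bed12()].
#' @return A `junction_track` data.frame.
#' @export
read_junction_bed12 <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("not a BED12 file")
  len <- tab[[3]] - tab[[2]]
  out <- data.frame(contig = tab[[1]], start = tab[[2]], end = tab[[3]],
                    length = len,
                    cls = ifelse(tab[[9]] ==
                                   paste(.JUNCTION_NFR_COLOR, collapse = ","),
                                 "nfr", "nucleosomal"),
                    color = tab[[9]], stringsAsFactors = FALSE)
  class(out) <- c("junction_track", "data.frame")
  out
}
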