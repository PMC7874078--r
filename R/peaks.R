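# Coverage tracks and accessible-region detection.
#
# Two coverage modes mirror the two biological questions: full-fragment
# coverage highlights nucleosome-occupied regions, while integration-site
# coverage (small windows around both Tn5 cut sites of each fragment) defines
# nucleosome-free accessible regions.  Regions are called with a bundled
# MACS-like Poisson local-background caller; externally produced peak BEDs
# are accepted everywhere downstream.

#' Build a coverage track from fragments
#'
#' @param fragments Fragment `GRanges` with `seqinfo` set.
#' @param genome Optional `Seqinfo`; defaults to `seqinfo(fragments)`.
#' @param mode `"full_fragment"` adds 1 over each fragment interval;
#'   `"integration_site"` adds 1 over a `2*insertion_window` bp window
#'   centered on each of the two cut sites (fragment start and end), clipped
#'   to the contig.  Integration mode requires paired-end fragments.
#' @param insertion_window Half-width of the cut-site window (bp). Default 25.
#' @param shift_tn5 Apply the +4/-5 Tn5 duplication offset to cut sites
#'   before windowing. Default FALSE.
#' @return A `coverage_track`: `cov` (RleList), `mode`, `insertion_window`,
#'   `total_units` (fragments in full mode, cut-site windows in integration
#'   mode), `n_fragments`, `genome`.
#' @export
make_coverage <- function(fragments, genome = NULL,
                          mode = c("full_fragment", "integration_site"),
                          insertion_window = 25, shift_tn5 = FALSE) {
  mode <- match.arg(mode)
  if (is.null(genome)) genome <- seqinfo(fragments)
  genome <- genome_index(genome)
  sl <- seqlengths(genome)
  bad <- start(fragments) < 1 |
    end(fragments) > sl[as.character(seqnames(fragments))]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("fragment %d (%s:%d-%d) outside genome bounds", i,
                 seqnames(fragments)[i], start(fragments)[i],
                 end(fragments)[i]))
  }
  n_frag <- length(fragments)
  if (mode == "full_fragment") {
    units <- granges(fragments)
    total_units <- n_frag
  } else {
    if (!isTRUE(metadata(fragments)$paired))
      stop("integration-site coverage requires paired-end fragments")
    if (insertion_window < 1) stop("insertion_window must be >= 1")
    w <- as.integer(insertion_window)
    ctg <- rep(seqnames(fragments), 2)
    left_cut <- start(fragments)         # first base of the fragment
    right_cut <- end(fragments)          # 0-based cut boundary at the end
    if (shift_tn5) {
      left_cut <- left_cut + 4L
      right_cut <- right_cut - 5L
    }
    units <- GRanges(ctg,
                     IRanges(c(left_cut - w, right_cut - w + 1L),
                             c(left_cut + w - 1L, right_cut + w)),
                     seqinfo = genome)
    units <- trim(units)
    units <- units[width(units) > 0]
    total_units <- length(units)
  }
  seqlevels(units) <- seqlevels(genome)
  seqinfo(units) <- genome
  cov <- coverage(units, width = sl)
  structure(list(cov = cov, mode = mode,
                 insertion_window = if (mode == "integration_site")
                   as.integer(insertion_window) else NA_integer_,
                 total_units = total_units, n_fragments = n_frag,
                 genome = genome),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage track (%s): %d units over %d contigs\n", x$mode,
              x$total_units, length(x$cov)))
  invisible(x)
}

#' Write a coverage track as 4-column bedGraph
#' @param coverage A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, path) {
  rows <- lapply(names(coverage$cov), function(ctg) {
    r <- coverage$cov[[ctg]]
    ends <- cumsum(runLength(r))
    starts <- c(0, utils::head(ends, -1))
    keep <- runValue(r) != 0
    if (!any(keep)) return(NULL)
    data.frame(contig = ctg, start = starts[keep], end = ends[keep],
               depth = runValue(r)[keep])
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) df <- data.frame()
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Call accessible regions with a Poisson local-background model
#'
#' Each position's depth is tested against a Poisson null with rate
#' `lambda = max(genome-wide rate, local rate in a centered window, scaled
#' control rate)`; p-values are Benjamini-Hochberg corrected over all tested
#' genome positions, significant positions are merged across gaps of at most
#' `merge_gap` bp, and regions shorter than `min_length` are dropped.  The
#' summit is the leftmost position of maximal depth.
#'
#' @param coverage A `coverage_track`.
#' @param control Optional `coverage_track` from a control library; its local
#'   rate is scaled to the treatment's total signal.
#' @param q_threshold BH-corrected significance threshold in (0,1).
#'   Default 0.05.
#' @param min_length Minimum region length (bp). Default 150.
#' @param merge_gap Maximum gap bridged between significant runs (bp).
#'   Default 100.
#' @param local_window Width of the treatment local-background window (bp).
#'   Default 10000.  The control (when given) additionally contributes
#'   rates at 200-bp and 1-kb windows so sharp control enrichment is not
#'   diluted away.
#' @return `GRanges` of peaks with metadata columns `summit` (absolute bp),
#'   `qvalue` (minimum corrected p in the region), and `name`.
#' @export
call_peaks <- function(coverage, control = NULL, q_threshold = 0.05,
                       min_length = 150, merge_gap = 100,
                       local_window = 10000) {
  stopifnot(inherits(coverage, "coverage_track"))
  .stopifnot_fraction(q_threshold, "q_threshold")
  genome <- coverage$genome
  contigs <- names(coverage$cov)
  total_cov <- sum(vapply(coverage$cov, function(r)
    sum(as.numeric(runValue(r)) * runLength(r)), numeric(1)))
  if (total_cov == 0) {
    return(GRanges(seqinfo = genome))
  }
  lambda_bg <- total_cov / genome_size(genome)
  ctrl_scale <- NULL
  if (!is.null(control)) {
    total_ctrl <- sum(vapply(control$cov, function(r)
      sum(as.numeric(runValue(r)) * runLength(r)), numeric(1)))
    ctrl_scale <- if (total_ctrl > 0) total_cov / total_ctrl else 0
  }
  depth_list <- list()
  lambda_list <- list()
  for (ctg in contigs) {
    depth <- as.numeric(coverage$cov[[ctg]])
    lam <- pmax(lambda_bg, .moving_average(depth, .odd_window(local_window)))
    if (!is.null(control) && ctg %in% names(control$cov)) {
      cd <- as.numeric(control$cov[[ctg]])
      for (w in unique(c(200, 1000, local_window)))
        lam <- pmax(lam, .moving_average(cd, .odd_window(w)) * ctrl_scale)
    }
    depth_list[[ctg]] <- depth
    lambda_list[[ctg]] <- lam
  }
  pvals <- ppois(unlist(depth_list, use.names = FALSE) - 1,
                 unlist(lambda_list, use.names = FALSE),
                 lower.tail = FALSE)
  qvals <- p.adjust(pvals, method = "BH")
  offsets <- cumsum(c(0, vapply(depth_list, length, numeric(1))))
  peaks <- GRanges(seqinfo = genome)
  for (i in seq_along(contigs)) {
    ctg <- contigs[i]
    q <- qvals[(offsets[i] + 1):offsets[i + 1]]
    sig <- q < q_threshold
    if (!any(sig)) next
    runs <- reduce(as(Rle(sig), "IRanges"), min.gapwidth = merge_gap + 1)
    runs <- runs[width(runs) >= min_length]
    if (length(runs) == 0) next
    depth <- depth_list[[ctg]]
    summit <- vapply(seq_along(runs), function(j) {
      s <- start(runs)[j]; e <- end(runs)[j]
      s + which.max(depth[s:e]) - 1L
    }, numeric(1))
    qmin <- vapply(seq_along(runs), function(j)
      min(q[start(runs)[j]:end(runs)[j]]), numeric(1))
    gr <- GRanges(ctg, runs, seqinfo = genome)
    mcols(gr)$summit <- as.integer(summit)
    mcols(gr)$qvalue <- qmin
    peaks <- c(peaks, gr)
  }
  peaks <- sort(peaks)
  if (length(peaks) > 0)
    mcols(peaks)$name <- sprintf("peak_%d", seq_along(peaks))
  peaks
}

.odd_window <- function(w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w + 1L else w
}

#' Fill peak fragment counts and RPKM abundances
#'
#' RPKM = count / ((peak length / 1000) * (library size / 1e6)); the library
#' size is the number of retained fragments.
#'
#' @param peaks Peak `GRanges`.
#' @param fragments Fragment `GRanges` (the retained library).
#' @return `peaks` with `count` and `rpkm` metadata columns filled.
#' @export
peak_abundance <- function(peaks, fragments) {
  total <- length(fragments)
  if (total == 0) stop("zero fragments: RPKM undefined")
  count <- countOverlaps(peaks, fragments, minoverlap = 1,
                         ignore.strand = TRUE)
  mcols(peaks)$count <- count
  mcols(peaks)$rpkm <- count / ((width(peaks) / 1000) * (total / 1e6))
  peaks
}

#' Write peaks in narrowPeak-style BED6+ format
#'
#' Columns: contig, start, end, name, score = int(10 x RPKM), strand ".",
#' summit offset from start, q-value.
#' @param peaks Peak `GRanges` (after [peak_abundance()]).
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  m <- mcols(peaks)
  rpkm <- if ("rpkm" %in% names(m)) m$rpkm else rep(0, length(peaks))
  qv <- if ("qvalue" %in% names(m)) m$qvalue else rep(NA_real_, length(peaks))
  summit <- if ("summit" %in% names(m)) m$summit - start(peaks)
            else rep(-1L, length(peaks))
  nm <- if ("name" %in% names(m)) m$name else sprintf("peak_%d", seq_along(peaks))
  .write_bed(peaks, path,
             extra = data.frame(name = nm, score = as.integer(10 * rpkm),
                                strand = ".", summit_offset = summit,
                                qvalue = qv))
}

#' Read a peak BED (3+ columns)
#' @param path BED path (0-based half-open).
#' @param genome Optional `Seqinfo`.
#' @return Peak `GRanges` (strand dropped).
#' @export
read_peaks_bed <- function(path, genome = NULL) {
  gr <- .read_bed(path, genome)
  strand(gr) <- "*"
  gr
}
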