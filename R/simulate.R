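# Deterministic synthetic ATAC-seq data.
#
# The generator emulates the features of a real paired-end ATAC library that
# the package's statistics consume: a sub-nucleosomal fragment-length mode, a
# ladder of nucleosome-periodic modes at a planted spacing, accessible
# regions with elevated fragment density, organelle-derived fragments, and
# PCR duplicates.  It does not model sequence content, Tn5 sequence bias or
# mappability.  All randomness flows through one PRNG stream keyed by the
# seed, so identical configs give byte-identical outputs.

#' Simulation configuration
#'
#' Defaults describe a desk-scale but realistic library: two nuclear contigs
#' (500 kb + 300 kb) plus a 20-kb organelle contig, 50,000 fragments of which
#' 30% are organelle-derived (mitochondrial contamination commonly reaches
#' 20-80%), 10% PCR duplicates, a sub-nucleosomal mode at 60 bp and three
#' nucleosome modes at multiples of a 190-bp spacing, and 20 planted 500-bp
#' accessible regions at 10x background density.
#'
#' @param seed Integer PRNG seed.
#' @param contigs Named vector of nuclear contig lengths (bp).
#' @param organelle_contig Name of the organelle contig.
#' @param organelle_length Organelle contig length (bp).
#' @param organelle_fraction Fraction of fragments on the organelle contig.
#' @param duplicate_rate Fraction of fragments that are PCR copies of another.
#' @param n_fragments Total fragments (including organelle and duplicates).
#' @param nfr_length_mode Mode of the sub-nucleosomal length component (bp).
#' @param nucleosome_spacing Planted inter-nucleosome spacing (bp).
#' @param n_nucleosome_modes Number of nucleosome-ladder modes.
#' @param mode_weights Mixture weights: sub-nucleosomal component followed by
#'   the nucleosome modes (renormalized).
#' @param n_accessible_regions Number of planted accessible regions.
#' @param accessible_width Width of each planted region (bp).
#' @param accessible_multiplier Fragment-density multiplier inside planted
#'   regions.
#' @param promoter_bias Extra density multiplier over promoter windows
#'   (1 = none).
#' @param n_genes Genes in the synthetic annotation.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              contigs = c(chr1 = 5e5, chr2 = 3e5),
                              organelle_contig = "chrM",
                              organelle_length = 2e4,
                              organelle_fraction = 0.3,
                              duplicate_rate = 0.1,
                              n_fragments = 50000,
                              nfr_length_mode = 60,
                              nucleosome_spacing = 190,
                              n_nucleosome_modes = 3,
                              mode_weights = c(0.5, 0.25, 0.15, 0.10),
                              n_accessible_regions = 20,
                              accessible_width = 500,
                              accessible_multiplier = 10,
                              promoter_bias = 1,
                              n_genes = 100) {
  if (organelle_fraction < 0 || organelle_fraction > 1 ||
      duplicate_rate < 0 || duplicate_rate > 1)
    stop("rates must lie in [0, 1]")
  if (nucleosome_spacing <= 0) stop("nucleosome_spacing must be > 0")
  if (accessible_multiplier < 1) stop("multipliers must be >= 1")
  structure(as.list(environment()), class = "simulation_config")
}

# synthetic gene annotation: sequentially placed genes with 1-3 exons,
# CDS and UTRs at the transcript ends
.simulate_genes <- function(config) {
  rows <- list()
  gid <- 0
  per_contig <- ceiling(config$n_genes / length(config$contigs))
  for (ctg in names(config$contigs)) {
    len <- config$contigs[[ctg]]
    pos <- 2000
    for (i in seq_len(per_contig)) {
      if (gid >= config$n_genes) break
      w <- round(runif(1, 1500, 5000))
      gap <- round(runif(1, 2000, max(3000, len / per_contig - w)))
      if (pos + w + 1000 > len) break
      gid <- gid + 1
      strand <- sample(c("+", "-"), 1)
      n_exons <- sample(1:3, 1)
      # exon boundaries inside [pos, pos+w-1]
      if (n_exons == 1) {
        ex_s <- pos; ex_e <- pos + w - 1
      } else {
        cuts <- sort(sample(seq(pos + 200, pos + w - 200, by = 50),
                            2 * (n_exons - 1)))
        ex_s <- c(pos, cuts[seq(2, length(cuts), by = 2)])
        ex_e <- c(cuts[seq(1, length(cuts), by = 2)], pos + w - 1)
      }
      rows[[gid]] <- list(gene_id = sprintf("g%04d", gid), contig = ctg,
                          start = pos, end = pos + w - 1, strand = strand,
                          exon_start = ex_s, exon_end = ex_e)
      pos <- pos + w + gap
    }
  }
  rows
}

.write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                      g$gene_id, g$gene_id)
    add <- function(type, s, e, a)
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", g$contig, type, s, e,
              g$strand, a)
    lines <- c(lines, add("gene", g$start, g$end, attr_g),
               add("transcript", g$start, g$end, attr_t))
    for (j in seq_along(g$exon_start))
      lines <- c(lines, add("exon", g$exon_start[j], g$exon_end[j], attr_t))
    # simple CDS/UTR structure on the first/last 100 bp of the span
    utr_len <- min(100, (g$end - g$start) %/% 4)
    if (g$strand == "+") {
      lines <- c(lines,
                 add("five_prime_utr", g$start, g$start + utr_len - 1, attr_t),
                 add("CDS", g$start + utr_len, g$end - utr_len, attr_t),
                 add("three_prime_utr", g$end - utr_len + 1, g$end, attr_t))
    } else {
      lines <- c(lines,
                 add("three_prime_utr", g$start, g$start + utr_len - 1, attr_t),
                 add("CDS", g$start + utr_len, g$end - utr_len, attr_t),
                 add("five_prime_utr", g$end - utr_len + 1, g$end, attr_t))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# draw fragment lengths from the planted mixture
.simulate_lengths <- function(n, config) {
  k_max <- config$n_nucleosome_modes
  w <- config$mode_weights[seq_len(k_max + 1)]
  w <- w / sum(w)
  comp <- sample.int(k_max + 1, n, replace = TRUE, prob = w) - 1L
  len <- integer(n)
  nfr <- comp == 0
  # gamma sub-nucleosomal mode: mode = (shape-1)*scale
  shape <- 9
  len[nfr] <- round(rgamma(sum(nfr), shape = shape,
                           scale = config$nfr_length_mode / (shape - 1)))
  for (k in seq_len(k_max)) {
    sel <- comp == k
    len[sel] <- round(rnorm(sum(sel), mean = k * config$nucleosome_spacing,
                            sd = 0.12 * config$nucleosome_spacing * sqrt(k)))
  }
  pmax(len, 20L)
}

#' Simulate a synthetic ATAC-seq dataset
#'
#' @param config A [simulation_config()].
#' @return A `simulated_dataset` list: `fragments` (paired fragment
#'   `GRanges`), `genome` (`Seqinfo`, nuclear + organelle contigs), `genes`
#'   (internal gene table), `planted_regions` (`GRanges` with `multiplier`),
#'   and `manifest` (every planted quantity: config echo, per-fragment
#'   organelle and duplicate flags, planted regions).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    contigs <- c(config$contigs,
                 structure(config$organelle_length,
                           names = config$organelle_contig))
    genome <- genome_index(contigs)
    genes <- .simulate_genes(config)
    # planted accessible regions on nuclear contigs
    n_reg <- config$n_accessible_regions
    reg <- GRanges(seqinfo = genome)
    if (n_reg > 0) {
      ctg <- sample(names(config$contigs), n_reg, replace = TRUE,
                    prob = config$contigs / sum(config$contigs))
      starts <- vapply(ctg, function(c)
        round(runif(1, 1000, config$contigs[[c]] - config$accessible_width -
                      1000)), numeric(1))
      reg <- GRanges(ctg, IRanges(starts, width = config$accessible_width),
                     seqinfo = genome)
      mcols(reg)$multiplier <- config$accessible_multiplier
      if (any(end(reg) > seqlengths(genome)[as.character(seqnames(reg))]))
        stop("planted region outside contig")
    }
    if (config$promoter_bias > 1 && length(genes) > 0) {
      prom <- GRanges(
        vapply(genes, `[[`, character(1), "contig"),
        IRanges(
          start = vapply(genes, function(g)
            if (g$strand == "+") max(1, g$start - 1000) else g$end + 1,
            numeric(1)),
          width = 1000),
        seqinfo = genome)
      prom <- trim(prom)
      mcols(prom)$multiplier <- config$promoter_bias
      reg <- c(reg, prom)
    }
    n <- config$n_fragments
    is_org <- runif(n) < config$organelle_fraction
    lens <- .simulate_lengths(n, config)
    # sampling segments: whole nuclear contigs (background weight = length)
    # plus planted regions (extra weight = (multiplier - 1) * width)
    seg_ctg <- names(config$contigs)
    seg_lo <- rep(1, length(seg_ctg))
    seg_hi <- unname(config$contigs)
    seg_w <- unname(config$contigs)
    if (length(reg) > 0) {
      seg_ctg <- c(seg_ctg, as.character(seqnames(reg)))
      seg_lo <- c(seg_lo, start(reg))
      seg_hi <- c(seg_hi, end(reg))
      seg_w <- c(seg_w, (mcols(reg)$multiplier - 1) * width(reg))
    }
    n_nuc <- sum(!is_org)
    seg_idx <- sample.int(length(seg_w), n_nuc, replace = TRUE,
                          prob = seg_w / sum(seg_w))
    mid <- round(runif(n_nuc, seg_lo[seg_idx], seg_hi[seg_idx]))
    ctg <- character(n)
    mids <- integer(n)
    ctg[!is_org] <- seg_ctg[seg_idx]
    mids[!is_org] <- mid
    ctg[is_org] <- config$organelle_contig
    mids[is_org] <- round(runif(sum(is_org), 1, config$organelle_length))
    starts <- mids - lens %/% 2L
    sl <- contigs[ctg]
    starts <- pmax(1L, pmin(starts, sl - lens + 1L))
    starts <- pmax(starts, 1L)
    lens <- pmin(lens, sl)                       # organelle shorter than frag
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # PCR duplicates: copy an earlier fragment's coordinates
    is_dup <- runif(n) < config$duplicate_rate
    is_dup[1] <- FALSE
    src <- which(!is_dup)
    for (i in which(is_dup)) {
      j <- src[sample.int(length(src), 1)]
      ctg[i] <- ctg[j]; starts[i] <- starts[j]; lens[i] <- lens[j]
      strand[i] <- strand[j]
      is_org[i] <- is_org[j]
    }
    frags <- GRanges(ctg, IRanges(starts, width = lens), strand = strand,
                     seqinfo = genome)
    mcols(frags)$length <- width(frags)
    metadata(frags)$paired <- TRUE
    manifest <- list(
      config = unclass(config)[!vapply(unclass(config), is.function,
                                       logical(1))],
      n_fragments = n,
      organelle_flags = is_org,
      duplicate_flags = is_dup,
      planted_regions = if (length(reg) > 0)
        data.frame(contig = as.character(seqnames(reg)),
                   start = start(reg) - 1L, end = end(reg),
                   multiplier = mcols(reg)$multiplier) else
        data.frame(),
      fragment_lengths = width(frags))
    structure(list(fragments = frags, genome = genome, genes = genes,
                   planted_regions = reg, manifest = manifest),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated ATAC dataset: %d fragments, %d contigs, %d genes\n",
              length(x$fragments), length(seqlengths(x$genome)),
              length(x$genes)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits a fragment BED, a SAM file of synthetic read pairs (convertible to
#' BAM with `Rsamtools::asBam`), a GTF annotation, a chrom.sizes TSV, and a
#' truth-manifest JSON.
#'
#' @param sim A `simulated_dataset`.
#' @param dir Output directory (created).
#' @param prefix File-name prefix. Default "sim".
#' @return Invisibly, a named vector of written paths.
#' @export
write_simulated_dataset <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fragments_bed = file.path(dir, paste0(prefix, "_fragments.bed")),
    sam = file.path(dir, paste0(prefix, "_reads.sam")),
    gtf = file.path(dir, paste0(prefix, "_genes.gtf")),
    chrom_sizes = file.path(dir, paste0(prefix, ".chrom.sizes")),
    manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  write_fragments_bed(sim$fragments, paths["fragments_bed"])
  write_fragments_sam(sim$fragments, paths["sam"])
  .write_gtf(sim$genes, paths["gtf"])
  write_chrom_sizes(sim$genome, paths["chrom_sizes"])
  jsonlite::write_json(sim$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write fragments as a SAM file of synthetic read pairs
#'
#' Each fragment becomes one properly paired read pair whose outer span
#' equals the fragment; sequence is N-filled.  Convert to BAM with
#' `Rsamtools::asBam` when BAM input is needed.
#'
#' @param fragments Fragment `GRanges` with `seqinfo`.
#' @param path Output SAM path.
#' @param read_length Mate read length (bp); shortened for short fragments.
#' @export
write_fragments_sam <- function(fragments, path, read_length = 50) {
  si <- seqinfo(fragments)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", seqnames(si), seqlengths(si)))
  n <- length(fragments)
  w <- width(fragments)
  rl <- pmin(read_length, w)
  ctg <- as.character(seqnames(fragments))
  s <- start(fragments)
  e <- end(fragments)
  minus <- as.character(strand(fragments)) == "-"
  # first mate on the fragment strand; flags: 99/147 (+) or 83/163 (-)
  flag1 <- ifelse(minus, 83L, 99L)
  flag2 <- ifelse(minus, 163L, 147L)
  pos1 <- ifelse(minus, e - rl + 1L, s)
  pos2 <- ifelse(minus, s, e - rl + 1L)
  tlen1 <- ifelse(minus, -w, w)
  qname <- sprintf("frag%07d", seq_len(n))
  cig <- sprintf("%dM", rl)
  seqs <- strrep("N", rl)
  rec <- function(flag, pos, tlen)
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*", qname, flag, ctg,
            pos, cig, ifelse(flag %in% c(99L, 83L), pos2, pos1), tlen, seqs)
  lines1 <- rec(flag1, pos1, tlen1)
  lines2 <- rec(flag2, pos2, -tlen1)
  body <- c(rbind(lines1, lines2))
  ord <- order(rep(ctg, each = 2), c(rbind(pos1, pos2)))
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Simulate expression coupled to promoter accessibility
#'
#' Gene RPKM is log-normal; the probability that a gene's promoter carries
#' an accessible peak rises linearly with expression rank at the configured
#' slope (`prob = base + slope * rank_fraction`).
#'
#' @param models A `gene_models` object (or a `simulated_dataset`, whose GTF
#'   must first be parsed).
#' @param slope Rank-accessibility slope in \[0, 1 - base\]. Default 0.8.
#' @param base Baseline accessibility probability. Default 0.05.
#' @param seed PRNG seed.
#' @param peak_halfwidth Half-width of the planted promoter peak (bp).
#' @return List: `expression` (gene_id, rpkm), `peaks` (`GRanges`),
#'   `truth_accessible` (named logical).
#' @export
simulate_expression <- function(models, slope = 0.8, base = 0.05, seed = 1,
                                peak_halfwidth = 250) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  if (length(genes) == 0) stop("empty gene list")
  .with_seed(seed, {
    n <- length(genes)
    rpkm <- rlnorm(n, meanlog = 2, sdlog = 1.5)
    rank_frac <- (rank(rpkm, ties.method = "first") - 1) / max(n - 1, 1)
    prob <- pmin(base + slope * rank_frac, 1)
    accessible <- runif(n) < prob
    tss <- gene_tss(models)
    pk <- trim(resize(tss[accessible], width = 2 * peak_halfwidth,
                      fix = "center"))
    names(accessible) <- names(genes)
    list(expression = data.frame(gene_id = names(genes), rpkm = rpkm,
                                 stringsAsFactors = FALSE),
         peaks = granges(pk),
         truth_accessible = accessible)
  })
}
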