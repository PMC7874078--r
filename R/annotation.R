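# Gene annotation parsing and derivation of the eight genomic feature sets:
# promoter, gene body, exon, intron, 5'UTR, CDS, 3'UTR and intergenic region
# (IGR).  Feature sizes are the S_gf terms of the enrichment statistic.

#' Parse a GTF/GFF3 gene annotation into gene models
#'
#' Multi-transcript genes are collapsed by exon union.  Both Ensembl-style
#' (`five_prime_utr`) and UCSC-style (`5UTR`) UTR record types are accepted;
#' when UTR records are absent the UTR sets stay empty (with a warning from
#' [build_feature_set()]), never inferred.
#'
#' @param path GTF or GFF3 file.
#' @param genome Optional `Seqinfo`; contigs default to those seen in the file.
#' @return A `gene_models` object: `genes` (GRanges, names = gene ids) and
#'   `exons`, `cds`, `utr5`, `utr3` (GRangesLists indexed by gene id).
#' @export
parse_annotation <- function(path, genome = NULL) {
  gff <- rtracklayer::import(path)
  if (!"type" %in% names(mcols(gff))) stop("annotation lacks a type column")
  gid <- .annotation_gene_ids(gff)
  type <- tolower(as.character(gff$type))
  relevant <- type %in% c("gene", "transcript", "mrna", "exon", "cds",
                          "five_prime_utr", "three_prime_utr",
                          "5utr", "3utr", "utr5", "utr3")
  if (any(relevant & is.na(gid))) {
    bad <- which(relevant & is.na(gid))[1]
    stop(sprintf("record %d (%s %s:%d-%d) has no resolvable gene identifier",
                 bad, type[bad], seqnames(gff)[bad], start(gff)[bad],
                 end(gff)[bad]))
  }
  gff <- gff[relevant]
  gid <- gid[relevant]
  type <- type[relevant]
  pick <- function(types) {
    sel <- type %in% types
    grl <- split(granges(gff[sel]), gid[sel])
    reduce(grl)
  }
  exons <- pick("exon")
  span_src <- if (any(type == "gene")) "gene"
              else if (any(type %in% c("transcript", "mrna")))
                c("transcript", "mrna") else "exon"
  spans <- unlist(range(split(granges(gff[type %in% span_src]),
                              gid[type %in% span_src])))
  # genes lacking an explicit span record: use exon span
  missing_span <- setdiff(names(exons), names(spans))
  if (length(missing_span) > 0)
    spans <- c(spans, unlist(range(exons[missing_span])))
  spans <- spans[order(names(spans))]
  ids <- names(spans)
  empty <- function() {
    grl <- GRangesList(rep(list(GRanges()), length(ids)))
    names(grl) <- ids
    grl
  }
  fill <- function(grl) {
    out <- empty()
    common <- intersect(names(grl), ids)
    out[common] <- grl[common]
    out
  }
  models <- structure(list(
    genes = spans,
    exons = fill(exons),
    cds = fill(pick("cds")),
    utr5 = fill(pick(c("five_prime_utr", "5utr", "utr5"))),
    utr3 = fill(pick(c("three_prime_utr", "3utr", "utr3")))
  ), class = "gene_models")
  if (!is.null(genome)) {
    absent <- setdiff(seqlevelsInUse(models$genes), seqnames(genome))
    if (length(absent) > 0)
      stop("gene(s) on contig(s) absent from genome: ",
           paste(absent, collapse = ", "))
    models <- .set_models_genome(models, genome)
  }
  models
}

.annotation_gene_ids <- function(gff) {
  m <- mcols(gff)
  gid <- if ("gene_id" %in% names(m)) as.character(m$gene_id) else
    rep(NA_character_, length(gff))
  if ("Parent" %in% names(m)) {
    parent <- vapply(as.list(m$Parent), function(p)
      if (length(p) > 0) sub("^(gene|transcript):", "", p[[1]])
      else NA_character_, character(1))
    gid <- ifelse(is.na(gid) | gid == "", parent, gid)
  }
  if ("ID" %in% names(m)) {
    id <- sub("^gene:", "", as.character(m$ID))
    is_gene <- tolower(as.character(gff$type)) == "gene"
    gid <- ifelse((is.na(gid) | gid == "") & is_gene, id, gid)
  }
  ifelse(gid == "", NA_character_, gid)
}

.set_models_genome <- function(models, genome) {
  fix <- function(gr) {
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
    gr
  }
  models$genes <- fix(models$genes)
  for (f in c("exons", "cds", "utr5", "utr3"))
    models[[f]] <- fix(models[[f]])
  models
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene models: %d genes on %d contigs\n", length(x$genes),
              length(seqlevelsInUse(x$genes))))
  invisible(x)
}

#' Transcription start sites of gene models
#' @param models A `gene_models` object.
#' @return `GRanges` of width-1 TSS positions (strand-aware).
#' @export
gene_tss <- function(models) resize(models$genes, width = 1, fix = "start")

#' Assemble a feature set from explicit interval lists
#'
#' Escape hatch for enrichment against arbitrary named interval collections
#' (e.g. externally derived features); [build_feature_set()] is the standard
#' route from an annotation.
#'
#' @param features Named list of `GRanges`; each is merged.
#' @param genome `Seqinfo` genome index.
#' @return A `feature_set`.
#' @export
feature_set <- function(features, genome) {
  genome <- genome_index(genome)
  feats <- lapply(features, function(gr) {
    gr <- reduce(granges(gr), ignore.strand = TRUE)
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
    strand(gr) <- "*"
    sort(gr)
  })
  structure(list(features = feats,
                 sizes = vapply(feats, function(gr)
                   sum(as.numeric(width(gr))), numeric(1)),
                 genome = genome, promoter_length = NA_real_),
            class = "feature_set")
}

#' Build the eight genomic feature interval sets
#'
#' Promoters are strand-aware windows of `promoter_length` bp immediately
#' upstream of each TSS, clipped to the contig.  Introns are gene bodies
#' minus exons; the IGR is the genome complement of gene bodies and
#' promoters.  Features are unions over genes, so (except IGR) a base may
#' belong to several features at once.
#'
#' @param models A `gene_models` object.
#' @param genome `Seqinfo` genome index.
#' @param promoter_length Promoter window (bp), > 0. Default 1000.
#' @return A `feature_set`: `features` (named list of reduced GRanges for
#'   promoter, gene_body, exon, intron, utr5, cds, utr3, igr) and `sizes`
#'   (named numeric, total bp per feature — the S_gf values).
#' @export
build_feature_set <- function(models, genome, promoter_length = 1000) {
  stopifnot(inherits(models, "gene_models"))
  if (promoter_length <= 0) stop("promoter_length must be > 0")
  genome <- genome_index(genome)
  absent <- setdiff(seqlevelsInUse(models$genes), seqnames(genome))
  if (length(absent) > 0)
    stop("gene(s) on contig(s) absent from genome: ",
         paste(absent, collapse = ", "))
  models <- .set_models_genome(models, genome)
  genes <- models$genes
  gene_body <- reduce(granges(genes), ignore.strand = TRUE)
  promoter <- trim(promoters(genes, upstream = promoter_length,
                             downstream = 0))
  promoter <- reduce(granges(promoter[width(promoter) > 0]),
                     ignore.strand = TRUE)
  exon <- reduce(unlist(models$exons), ignore.strand = TRUE)
  intron <- setdiff(gene_body, exon, ignore.strand = TRUE)
  cds <- reduce(unlist(models$cds), ignore.strand = TRUE)
  utr5 <- reduce(unlist(models$utr5), ignore.strand = TRUE)
  utr3 <- reduce(unlist(models$utr3), ignore.strand = TRUE)
  if (length(utr5) == 0 && length(utr3) == 0)
    warning("annotation has no UTR records; utr5/utr3 are empty")
  igr <- setdiff(.genome_granges(genome),
                 reduce(c(gene_body, promoter)), ignore.strand = TRUE)
  feats <- list(promoter = promoter, gene_body = gene_body, exon = exon,
                intron = intron, utr5 = utr5, cds = cds, utr3 = utr3,
                igr = igr)
  feats <- lapply(feats, function(gr) {
    gr <- sort(gr)
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
    strand(gr) <- "*"
    gr
  })
  structure(list(features = feats,
                 sizes = vapply(feats, function(gr) sum(as.numeric(width(gr))),
                                numeric(1)),
                 genome = genome,
                 promoter_length = promoter_length),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("genomic feature set (bp):\n")
  print(x$sizes)
  invisible(x)
}

#' Write one BED per feature plus a sizes TSV
#' @param feature_set A `feature_set`.
#' @param dir Output directory.
#' @param prefix File-name prefix. Default "feature".
#' @return Invisibly, the written paths.
#' @export
write_feature_beds <- function(feature_set, dir, prefix = "feature") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(feature_set$features), function(f) {
    p <- file.path(dir, sprintf("%s_%s.bed", prefix, f))
    .write_bed(feature_set$features[[f]], p)
    p
  }, character(1))
  sizes_path <- file.path(dir, sprintf("%s_sizes.tsv", prefix))
  write.table(data.frame(feature = names(feature_set$sizes),
                         bp = feature_set$sizes),
              sizes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, sizes = sizes_path))
}
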