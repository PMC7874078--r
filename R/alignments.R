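# Fragment input and filtering.
#
# A fragment is one sequenced paired-end ATAC insert, held as a GRanges row
# whose strand is the strand of the first mate.  metadata(gr)$paired records
# whether fragments came from proper pairs; downstream steps that need
# paired-end input (fragment-size analysis, junction tracks, integration-site
# coverage) check it.

#' Default organelle contig names
#'
#' Mitochondrial and plastid contigs under their common names; matched
#' case-insensitively as exact names unless `regex = TRUE` in
#' [filter_organelle_and_duplicates()].
#' @export
default_organelle_patterns <- function() {
  c("chrM", "MT", "Mt", "Pt", "chrMT", "chloroplast")
}

#' Load ATAC-seq fragments from a BAM file or a fragment BED
#'
#' In paired mode one fragment is emitted per properly paired read pair,
#' spanning from the leftmost to the rightmost aligned base of the two mates.
#' In single mode one fragment per aligned read (its span).  Reads that are
#' unpaired or improperly paired in paired mode are skipped with a counted
#' warning.
#'
#' @param path BAM file (indexed or index built on the fly) or a 6-column
#'   fragment BED (contig, start, end, name, length, strand).
#' @param pairing_mode `"paired"` (default) or `"single"`.
#' @param genome Optional `Seqinfo`; required for BED input without
#'   `chrom_sizes`; for BAM it defaults to the header.
#' @param chrom_sizes Optional path to a 2-column chrom.sizes TSV.
#' @param min_mapq Minimum mapping quality (BAM only). Default 10.
#' @return A `GRanges` of fragments with `seqinfo` set, `length` metadata
#'   column, and `metadata()$paired`.
#' @export
load_fragments <- function(path, pairing_mode = c("paired", "single"),
                           genome = NULL, chrom_sizes = NULL, min_mapq = 10) {
  pairing_mode <- match.arg(pairing_mode)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (!is.null(chrom_sizes)) genome <- read_chrom_sizes(chrom_sizes)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    .load_fragments_bam(path, pairing_mode, genome, min_mapq)
  } else {
    read_fragments_bed(path, genome = genome, paired = pairing_mode == "paired")
  }
}

.load_fragments_bam <- function(path, pairing_mode, genome, min_mapq) {
  bf <- Rsamtools::BamFile(path)
  hdr_si <- seqinfo(bf)
  if (is.null(genome)) genome <- hdr_si
  if (pairing_mode == "paired") {
    flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                   isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
    gp <- GenomicAlignments::readGAlignmentPairs(bf, param = param,
                                                 strandMode = 1)
    frags <- granges(gp, on.discordant.seqnames = "drop")
    n_records <- Rsamtools::countBam(bf)$records
    n_skipped <- max(0L, n_records - 2L * length(frags))
    if (n_skipped > 0)
      warning(sprintf("%d alignment records skipped (unpaired/improper/low MAPQ)",
                      n_skipped))
  } else {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
    frags <- granges(GenomicAlignments::readGAlignments(bf, param = param))
  }
  seqlevels(frags) <- seqlevels(genome)
  seqinfo(frags) <- genome
  mcols(frags)$length <- width(frags)
  metadata(frags)$paired <- pairing_mode == "paired"
  frags
}

#' Read a 6-column fragment BED
#'
#' Columns: contig, start (0-based), end (exclusive), name, length, strand of
#' the first mate.  Length must equal end - start.
#' @param path BED path.
#' @param genome `Seqinfo` genome index (required unless the BED carries a
#'   `#chrom_sizes` style sidecar; pass [read_chrom_sizes()] output).
#' @param paired Whether these fragments represent proper pairs. Default TRUE.
#' @return `GRanges` of fragments.
#' @export
read_fragments_bed <- function(path, genome = NULL, paired = TRUE) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("fragment BED needs >= 3 columns")
  if (is.null(genome))
    genome <- genome_index(tapply(tab[[3]], tab[[1]], max)[unique(tab[[1]])])
  gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]),
                strand = if (ncol(tab) >= 6)
                  ifelse(tab[[6]] %in% c("+", "-"), tab[[6]], "*") else "*")
  seqlevels(gr) <- seqlevels(genome)
  seqinfo(gr) <- genome
  mcols(gr)$length <- width(gr)
  metadata(gr)$paired <- paired
  gr
}

#' Write fragments as a 6-column fragment BED
#' @param fragments Fragment `GRanges`.
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  n <- length(fragments)
  .write_bed(fragments, path,
             extra = data.frame(
               name = sprintf("frag%d", seq_len(max(n, 0))),
               length = width(fragments),
               strand = ifelse(as.character(strand(fragments)) == "*", ".",
                               as.character(strand(fragments)))))
}

#' Remove organelle-derived fragments and PCR duplicates
#'
#' Mitochondrial reads can make up 20-80% of an ATAC-seq library and distort
#' every downstream statistic; this drops fragments on organelle contigs and
#' (optionally) collapses PCR duplicates, defined at the fragment level by
#' identical (contig, start, end, strand).
#'
#' @param fragments Fragment `GRanges`.
#' @param organelle_patterns Contig names to drop; matched case-insensitively
#'   as exact names, or as regular expressions when `regex = TRUE`.
#' @param dedup Collapse duplicate fragments. Default TRUE.
#' @param regex Treat `organelle_patterns` as regular expressions.
#' @return A list with `fragments` (retained) and `report` (a
#'   `filter_report`: n_input, n_organelle_removed, n_duplicates_removed,
#'   n_retained, organelle_fraction).
#' @export
filter_organelle_and_duplicates <- function(fragments,
                                            organelle_patterns = default_organelle_patterns(),
                                            dedup = TRUE, regex = FALSE) {
  if (length(organelle_patterns) == 0)
    stop("organelle_patterns must be non-empty")
  n_input <- length(fragments)
  contigs <- seqlevels(fragments)
  if (regex) {
    hit <- Reduce(`|`, lapply(organelle_patterns,
                              function(p) grepl(p, contigs)))
  } else {
    hit <- tolower(contigs) %in% tolower(organelle_patterns)
  }
  if (length(contigs) > 0 && all(hit))
    stop("no nuclear contigs remain after organelle filtering")
  organelle <- as.character(seqnames(fragments)) %in% contigs[hit]
  kept <- fragments[!organelle]
  n_org <- sum(organelle)
  n_dup <- 0L
  if (dedup && length(kept) > 0) {
    dup <- duplicated(granges(kept))
    n_dup <- sum(dup)
    kept <- kept[!dup]
  }
  report <- structure(list(
    n_input = n_input,
    n_organelle_removed = n_org,
    n_duplicates_removed = n_dup,
    n_retained = length(kept),
    organelle_fraction = if (n_input > 0) n_org / n_input else 0
  ), class = "filter_report")
  list(fragments = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "fragment filter: %d in, %d organelle (%.1f%%), %d duplicates, %d retained\n",
    x$n_input, x$n_organelle_removed, 100 * x$organelle_fraction,
    x$n_duplicates_removed, x$n_retained))
  invisible(x)
}

#' Write a filter report as TSV and/or JSON
#' @param report A `filter_report`.
#' @param tsv,json Output paths (either may be NULL).
#' @export
write_filter_report <- function(report, tsv = NULL, json = NULL) {
  fields <- unclass(report)
  if (!is.null(tsv))
    write.table(data.frame(field = names(fields),
                           value = unlist(fields)),
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(fields, json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Select fragments by length
#'
#' Splitting a library at the sub-nucleosomal cutoff (commonly 150 bp)
#' separates nucleosome-free from nucleosome-spanning fragments.
#'
#' @param fragments Fragment `GRanges`.
#' @param cutoff Length cutoff in bp (> 0).
#' @param side `"at_most"` keeps length <= cutoff; `"above"` keeps > cutoff.
#' @return Filtered `GRanges`, input order preserved.
#' @export
select_fragments_by_length <- function(fragments, cutoff,
                                       side = c("at_most", "above")) {
  side <- match.arg(side)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("cutoff must be a positive number of bp")
  keep <- if (side == "at_most") width(fragments) <= cutoff
          else width(fragments) > cutoff
  out <- fragments[keep]
  if (length(out) == 0 && length(fragments) > 0)
    warning("no fragments retained by length selection")
  out
}
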