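#' @import GenomicRanges IRanges S4Vectors methods
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqnames seqlengths seqlevels
#'   seqlevelsInUse "seqinfo<-" "seqlevels<-" "seqlengths<-"
#' @importFrom stats fft kmeans p.adjust pchisq phyper ppois pt rgamma
#'   rlnorm rnorm runif
#' @importFrom utils read.table write.table packageVersion
NULL

# Internal coordinates are GRanges (1-based closed), the Bioconductor
# convention.  All BED-family text formats are 0-based half-open; conversion
# happens only in the readers/writers below.

#' Build a genome index
#'
#' A genome index is the universe for coverage, enrichment and interval
#' complement: an ordered set of contig names with lengths.  Internally it is
#' a [GenomeInfoDb::Seqinfo] object.
#'
#' @param contigs Named integer/numeric vector of contig lengths (bp), or a
#'   `Seqinfo` object (returned unchanged).
#' @return A `Seqinfo` object.
#' @examples
#' genome_index(c(chr1 = 1e5, chrM = 2e4))
#' @export
genome_index <- function(contigs) {
  if (is(contigs, "Seqinfo")) {
    if (anyNA(seqlengths(contigs))) stop("all contigs must have lengths")
    return(contigs)
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contig lengths must be uniquely named")
  if (any(contigs <= 0)) stop("contig lengths must be > 0")
  Seqinfo(seqnames = names(contigs), seqlengths = as.integer(contigs))
}

#' Total genome size in bp
#' @param genome A `Seqinfo` genome index.
#' @return Numeric scalar, the sum of contig lengths (S_g).
#' @export
genome_size <- function(genome) sum(as.numeric(seqlengths(genome)))

#' Read a two-column chrom.sizes table
#' @param path TSV with columns contig name and length.
#' @return A `Seqinfo` genome index.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("contig", "length"),
                    colClasses = c("character", "integer"))
  genome_index(structure(tab$length, names = tab$contig))
}

#' Write a chrom.sizes table
#' @param genome A `Seqinfo` genome index.
#' @param path Output TSV path.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(seqnames(genome), seqlengths(genome)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges over the whole genome, one range per contig
.genome_granges <- function(genome) {
  GRanges(seqnames(genome), IRanges(1L, seqlengths(genome)),
          seqinfo = genome)
}

# read generic BED (>=3 columns, 0-based half-open) into GRanges
.read_bed <- function(path, genome = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]))
  if (ncol(tab) >= 6) strand(gr) <- ifelse(tab[[6]] %in% c("+", "-"), tab[[6]], "*")
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
  }
  gr
}

.write_bed <- function(gr, path, extra = NULL) {
  df <- data.frame(contig = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(extra)) df <- cbind(df, extra)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# run code under a temporary seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("%s must lie in (0, 1)", name))
}
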