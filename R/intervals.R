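#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits elementNROWS
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames seqlevels
#' @importFrom methods is as
#' @importFrom stats ppois p.adjust pt pnorm runif setNames aggregate t.test
#' @importFrom utils write.table read.delim combn
NULL

# All user-facing files are BED-family: 0-based, half-open. In memory the
# package uses GRanges (1-based, closed). These two helpers are the only
# place the conversion happens.

#' Build a GRanges from 0-based half-open (BED) coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open (`start < end`).
#' @param strand strand characters (`"+"`, `"-"`, `"."`); `"."` maps to `"*"`.
#' @param genome optional named vector of chromosome lengths (bp), recorded as
#'   seqlengths so downstream stages know the genome size.
#' @return A [GenomicRanges::GRanges] object.
#' @export
bed_granges <- function(chrom, start, end, strand = ".", genome = NULL) {
  stopifnot(all(start >= 0), all(start < end), all(nzchar(chrom)))
  strand <- rep(ifelse(strand == ".", "*", strand),
                length.out = length(chrom))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                               strand = strand)
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- as.integer(genome)
  }
  gr
}

#' Convert a GRanges back to a 0-based half-open coordinate table
#'
#' @param gr a GRanges.
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive),
#'   `strand` (`"."` for unstranded).
#' @export
granges_bed <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(s == "*", ".", s),
    stringsAsFactors = FALSE
  )
}

# Width-1 GRanges at each fragment's midpoint, floor((start0 + end0) / 2) in
# 0-based coordinates. A midpoint m0 lies in BED region [s0, e0) iff the
# 1-based position m0 + 1 falls inside the region's GRanges.
midpoint_granges <- function(gr) {
  m0 <- (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::IRanges(m0 + 1L, width = 1L))
  suppressWarnings(GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(gr))
  out
}

# Genome length from seqlengths; errors if absent (needed for background rates).
genome_length <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) {
    stop("genome (seqlengths) must be known for this operation")
  }
  sum(as.numeric(sl))
}

#' Write intervals as a BED file
#'
#' Emits 0-based half-open BED with as many of the standard columns as are
#' provided. Used for peak, candidate-region and truth-region output.
#'
#' @param gr GRanges to write; metadata columns `name` and `score` are used
#'   for BED columns 4-5 when present, extra columns are appended after
#'   column 6.
#' @param path output file path.
#' @param extra_cols character vector of metadata column names to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, extra_cols = character()) {
  df <- granges_bed(gr)
  mc <- S4Vectors::mcols(gr)
  df$name <- if ("name" %in% colnames(mc)) as.character(mc$name) else "."
  df$score <- if ("score" %in% colnames(mc)) mc$score else 0
  out <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  for (col in extra_cols) out[[col]] <- mc[[col]]
  o <- order(out$chrom, out$start, out$end)
  write.table(out[o, , drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

region_labels <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}
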