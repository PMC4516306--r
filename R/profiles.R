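# Coverage summaries over gene models: a length-normalized metagene profile
# (gene body rescaled to 0-100% with proportional flanks) and a fixed-window
# TSS profile. Densities are tag counts per bp per million mapped tags,
# scaled by 1e9 so a bin's value matches the RPKM of that bin.

#' Length-normalized metagene (gene body) profile
#'
#' Each gene body is split into `n_body_bins` equal bins; each flank spans
#' `flank_fraction` of the gene length, split into
#' `n_body_bins * flank_fraction` bins (so all bins of one gene have equal
#' width). Minus-strand genes are reversed so bin 0 is always the upstream
#' flank. The profile is the unweighted mean of the per-gene normalized
#' densities.
#'
#' @param library a [tag_library()].
#' @param genes a [gene_models()] object; genes shorter than `n_body_bins`
#'   bp are dropped (with a message).
#' @param n_body_bins body bins (default 100, i.e. 1% of gene length each).
#' @param flank_fraction flank length as a fraction of gene length
#'   (default 0.2).
#' @return An object of class `MetageneProfile`: list with `bins` (named
#'   numeric vector of mean densities), `n_body_bins`, `n_flank_bins`,
#'   `n_genes`.
#' @export
metagene_profile <- function(library, genes, n_body_bins = 100,
                             flank_fraction = 0.2) {
  stopifnot(inherits(library, "TagLibrary"), inherits(genes, "GeneModels"),
            n_body_bins > 0)
  tx <- genes$tx
  if (!length(tx)) stop("empty gene list")
  strand <- as.character(GenomicRanges::strand(tx))
  if (any(!strand %in% c("+", "-"))) stop("all genes must be stranded")
  n_flank <- round(n_body_bins * flank_fraction)
  n_bins <- n_body_bins + 2L * n_flank
  len <- GenomicRanges::width(tx)
  keep <- len >= n_body_bins
  if (any(!keep)) {
    message(sum(!keep), " gene(s) shorter than ", n_body_bins, " bp dropped")
  }
  tx <- tx[keep]; strand <- strand[keep]; len <- len[keep]
  if (!length(tx)) stop("no gene long enough to profile")
  denom <- max(library$total_tags, 1L)   # empty library -> all-zero profile

  mids <- midpoint_granges(library$tags)
  m0 <- GenomicRanges::start(mids) - 1L
  mchrom <- as.character(GenomeInfoDb::seqnames(mids))
  by_chrom <- split(m0, mchrom)
  by_chrom <- lapply(by_chrom, sort)

  acc <- numeric(n_bins)
  for (i in seq_along(tx)) {
    cn <- as.character(GenomeInfoDb::seqnames(tx))[i]
    pos <- by_chrom[[cn]]
    binw <- len[i] / n_body_bins
    span0 <- (GenomicRanges::start(tx)[i] - 1) - n_flank * binw
    counts <- integer(n_bins)
    if (!is.null(pos) && length(pos)) {
      edges <- span0 + binw * (0:n_bins)
      idx <- findInterval(pos, edges)          # 1..n_bins inside the span
      inside <- idx >= 1 & idx <= n_bins & pos >= edges[1]
      if (any(inside)) counts <- tabulate(idx[inside], n_bins)
    }
    dens <- counts / (binw * denom) * 1e9
    if (strand[i] == "-") dens <- rev(dens)
    acc <- acc + dens
  }
  bins <- acc / length(tx)
  names(bins) <- c(sprintf("up%02d", seq_len(n_flank)),
                   sprintf("body%03d", seq_len(n_body_bins)),
                   sprintf("down%02d", seq_len(n_flank)))
  structure(list(bins = bins, n_body_bins = as.integer(n_body_bins),
                 n_flank_bins = as.integer(n_flank),
                 n_genes = length(tx)),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile: %d body + 2x%d flank bins over %d genes\n",
              x$n_body_bins, x$n_flank_bins, x$n_genes))
  invisible(x)
}

#' TSS-centered coverage profile
#'
#' Mean normalized tag density in fixed-width bins over a strand-oriented
#' window around each TSS (upstream offsets negative).
#'
#' @param library a [tag_library()].
#' @param genes a [gene_models()] object (stranded).
#' @param flank half-window around the TSS in bp (default 5000).
#' @param bin_size bin width in bp (default 100); must divide `flank`.
#' @return An object of class `TssProfile`: list with `bins` (named by the
#'   bin's start offset), `offsets`, `flank`, `bin_size`, `n_genes`.
#' @export
tss_profile <- function(library, genes, flank = 5000, bin_size = 100) {
  stopifnot(inherits(library, "TagLibrary"), inherits(genes, "GeneModels"))
  if (flank %% bin_size != 0) stop("flank must be divisible by bin_size")
  tx <- genes$tx
  if (!length(tx)) stop("empty gene list")
  strand <- as.character(GenomicRanges::strand(tx))
  if (any(!strand %in% c("+", "-"))) stop("all genes must be stranded")
  n_bins <- as.integer(2 * flank / bin_size)
  t0 <- tss_positions(tx)
  denom <- max(library$total_tags, 1L)   # empty library -> all-zero profile

  mids <- midpoint_granges(library$tags)
  m0 <- GenomicRanges::start(mids) - 1L
  by_chrom <- lapply(split(m0, as.character(GenomeInfoDb::seqnames(mids))),
                     sort)
  acc <- numeric(n_bins)
  for (i in seq_along(tx)) {
    pos <- by_chrom[[as.character(GenomeInfoDb::seqnames(tx))[i]]]
    counts <- integer(n_bins)
    if (!is.null(pos) && length(pos)) {
      off <- if (strand[i] == "+") pos - t0[i] else t0[i] - pos
      idx <- (off + flank) %/% bin_size + 1L
      inside <- idx >= 1 & idx <= n_bins
      if (any(inside)) counts <- tabulate(idx[inside], n_bins)
    }
    acc <- acc + counts / (bin_size * denom) * 1e9
  }
  offsets <- seq(-flank, flank - bin_size, by = bin_size)
  bins <- acc / length(tx)
  names(bins) <- as.character(offsets)
  structure(list(bins = bins, offsets = offsets, flank = flank,
                 bin_size = bin_size, n_genes = length(tx)),
            class = "TssProfile")
}

#' @export
print.TssProfile <- function(x, ...) {
  cat(sprintf("TssProfile: +/-%d bp in %d bp bins over %d genes\n",
              x$flank, x$bin_size, x$n_genes))
  invisible(x)
}

#' Write a profile as a 2-column TSV (bin label, density)
#'
#' @param profile a `MetageneProfile` or `TssProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(bin = names(profile$bins),
                         density = unname(profile$bins)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
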