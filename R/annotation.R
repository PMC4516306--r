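# Gene models and region annotation: promoter definition (TSS +/- 2 kb),
# single-category genomic-feature classification of a region's midpoint
# under the precedence promoter > 5'UTR > 3'UTR > exon > intron >
# intergenic, and any-overlap gene association with promoter/body location
# summaries.

#' Construct a gene-model set
#'
#' @param tx GRanges of transcripts with strand and metadata columns
#'   `gene_id` plus optional `cds_start`/`cds_end` (0-based half-open CDS
#'   bounds, `NA` for non-coding genes).
#' @param exons GRangesList of exons, parallel to `tx` (absolute
#'   coordinates, non-overlapping, sorted, within the transcript).
#' @return An object of class `GeneModels`.
#' @export
gene_models <- function(tx, exons) {
  stopifnot(is(tx, "GRanges"), is(exons, "GRangesList"),
            length(tx) == length(exons))
  if (length(tx)) {
    stopifnot(!is.null(S4Vectors::mcols(tx)$gene_id))
    if (is.null(S4Vectors::mcols(tx)$cds_start)) {
      S4Vectors::mcols(tx)$cds_start <- NA_integer_
      S4Vectors::mcols(tx)$cds_end <- NA_integer_
    }
  }
  structure(list(tx = tx, exons = exons), class = "GeneModels")
}

#' @export
length.GeneModels <- function(x) length(x$tx)

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d transcripts, %d with CDS\n", length(x),
              sum(!is.na(S4Vectors::mcols(x$tx)$cds_start))))
  invisible(x)
}

#' Read gene models from a BED12 file
#'
#' Blocks become exons; thickStart/thickEnd become the CDS (a zero-width
#' thick interval means no CDS).
#'
#' @param path BED12 file.
#' @param genome optional named vector of chromosome lengths.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- as.integer(genome)
  }
  mc <- S4Vectors::mcols(gr)
  tx <- GenomicRanges::granges(gr)
  S4Vectors::mcols(tx)$gene_id <- mc$name
  thick <- mc$thick
  has_cds <- !is.null(thick) & IRanges::width(thick) > 1
  S4Vectors::mcols(tx)$cds_start <- ifelse(has_cds,
                                           IRanges::start(thick) - 1L,
                                           NA_integer_)
  S4Vectors::mcols(tx)$cds_end <- ifelse(has_cds, IRanges::end(thick),
                                         NA_integer_)
  if (!is.null(mc$blocks)) {
    # rtracklayer returns blocks relative to the transcript (1-based)
    exons <- GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
      b <- mc$blocks[[i]]
      GenomicRanges::shift(
        GenomicRanges::GRanges(GenomeInfoDb::seqnames(tx)[i], b,
                               strand = GenomicRanges::strand(tx)[i],
                               seqlengths = GenomeInfoDb::seqlengths(tx)),
        GenomicRanges::start(tx)[i] - 1L)
    }))
  } else {
    exons <- methods::as(tx, "GRangesList")
  }
  names(exons) <- S4Vectors::mcols(tx)$gene_id
  gene_models(tx, exons)
}

#' Write gene models as BED12
#'
#' @param genes a [gene_models()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  tx <- genes$tx
  n <- length(tx)
  bed <- granges_bed(tx)
  mc <- S4Vectors::mcols(tx)
  cds_s <- ifelse(is.na(mc$cds_start), bed$start, mc$cds_start)
  cds_e <- ifelse(is.na(mc$cds_end), bed$start, mc$cds_end)
  rows <- vapply(seq_len(n), function(i) {
    ex <- genes$exons[[i]]
    bs <- GenomicRanges::start(ex) - 1L - bed$start[i]
    bl <- GenomicRanges::width(ex)
    paste(bed$chrom[i], bed$start[i], bed$end[i], mc$gene_id[i], 0,
          bed$strand[i], cds_s[i], cds_e[i], 0, length(ex),
          paste0(paste(bl, collapse = ","), ","),
          paste0(paste(bs, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

tss_positions <- function(tx) {
  # 0-based TSS coordinate: tx start for "+", tx end (exclusive bound) for "-"
  s <- as.character(GenomicRanges::strand(tx))
  if (any(!s %in% c("+", "-"))) {
    stop("gene models must be stranded (+ or -) for TSS-based operations")
  }
  ifelse(s == "+", GenomicRanges::start(tx) - 1L, GenomicRanges::end(tx))
}

#' Promoter intervals around each TSS
#'
#' The promoter is `[TSS - upstream, TSS + downstream)` in 0-based
#' coordinates (default -2 kb to +2 kb), clipped to chromosome bounds, and
#' carries the gene's strand.
#'
#' @param genes a [gene_models()] object (or a stranded tx GRanges).
#' @param upstream,downstream bp around the TSS (defaults 2000/2000).
#' @return GRanges of promoters with metadata column `gene_id`.
#' @export
promoter_interval <- function(genes, upstream = 2000, downstream = 2000) {
  tx <- if (inherits(genes, "GeneModels")) genes$tx else genes
  if (!length(tx)) return(GenomicRanges::granges(tx))
  t0 <- tss_positions(tx)
  s0 <- t0 - upstream
  e0 <- t0 + downstream
  sl <- GenomeInfoDb::seqlengths(tx)
  chrom <- as.character(GenomeInfoDb::seqnames(tx))
  s0 <- pmax(0, s0)
  if (!any(is.na(sl))) e0 <- pmin(unname(sl[chrom]), e0)
  out <- bed_granges(chrom, s0, e0, as.character(GenomicRanges::strand(tx)),
                     genome = if (any(is.na(sl))) NULL else sl)
  S4Vectors::mcols(out)$gene_id <- S4Vectors::mcols(tx)$gene_id
  out
}

# Category interval sets used by classify_interval / gene association.
annotation_index <- function(genes, upstream = 2000, downstream = 2000) {
  tx <- genes$tx
  ex <- unlist(genes$exons, use.names = FALSE)
  gidx <- rep(seq_along(tx), S4Vectors::elementNROWS(genes$exons))
  cs <- S4Vectors::mcols(tx)$cds_start[gidx]   # 0-based CDS bounds per exon
  ce <- S4Vectors::mcols(tx)$cds_end[gidx]
  es0 <- GenomicRanges::start(ex) - 1L
  ee0 <- GenomicRanges::end(ex)
  strand_ex <- as.character(GenomicRanges::strand(ex))
  clip <- function(s, e) {
    keep <- !is.na(s) & !is.na(e) & s < e
    gr <- ex[keep]
    GenomicRanges::ranges(gr) <- IRanges::IRanges(s[keep] + 1L, e[keep])
    GenomicRanges::granges(gr)
  }
  # exonic sequence outside the CDS span: left of cds_start / right of cds_end
  left <- clip(es0, pmin(ee0, cs))
  right <- clip(pmax(es0, ce), ee0)
  left_is_5p <- strand_ex[!is.na(cs) & es0 < pmin(ee0, cs)] == "+"
  right_is_5p <- strand_ex[!is.na(ce) & pmax(es0, ce) < ee0] == "-"
  utr5 <- c(left[left_is_5p], right[right_is_5p])
  utr3 <- c(left[!left_is_5p], right[!right_is_5p])
  list(
    promoter = GenomicRanges::granges(promoter_interval(genes, upstream,
                                                        downstream)),
    utr5 = utr5, utr3 = utr3,
    exon = GenomicRanges::granges(ex),
    intron = GenomicRanges::setdiff(GenomicRanges::granges(tx),
                                    GenomicRanges::granges(ex),
                                    ignore.strand = TRUE)
  )
}

#' Classify regions into genomic-feature categories
#'
#' Each region is assigned the single category of its midpoint under the
#' precedence promoter > 5'UTR > 3'UTR > exon > intron > intergenic.
#' Genes without a CDS contribute no UTRs (their exonic sequence counts as
#' exon).
#'
#' @param regions GRanges of regions to classify.
#' @param genes a [gene_models()] object.
#' @param upstream,downstream promoter extent around the TSS (bp).
#' @return Factor of categories (levels `promoter`, `5'UTR`, `3'UTR`,
#'   `exon`, `intron`, `intergenic`), parallel to `regions`.
#' @export
classify_interval <- function(regions, genes, upstream = 2000,
                              downstream = 2000) {
  stopifnot(is(regions, "GRanges"), inherits(genes, "GeneModels"))
  lv <- c("promoter", "5'UTR", "3'UTR", "exon", "intron", "intergenic")
  mids <- midpoint_granges(regions)
  out <- rep("intergenic", length(regions))
  idx <- annotation_index(genes, upstream, downstream)
  sets <- list("promoter" = idx$promoter, "5'UTR" = idx$utr5,
               "3'UTR" = idx$utr3, "exon" = idx$exon, "intron" = idx$intron)
  unassigned <- rep(TRUE, length(regions))
  for (cat in names(sets)) {
    if (!length(sets[[cat]])) next
    hit <- GenomicRanges::countOverlaps(mids, sets[[cat]],
                                        ignore.strand = TRUE) > 0
    take <- unassigned & hit
    out[take] <- cat
    unassigned <- unassigned & !hit
  }
  factor(out, levels = lv)
}

#' Associate regions with genes and summarize promoter/body locations
#'
#' A region is associated with every gene whose transcript or promoter it
#' overlaps (any overlap, not midpoint). Location is `promoter` for promoter
#' overlap and `body` for transcript overlap; a region can contribute both.
#'
#' @param regions GRanges of regions (e.g. called differential regions); an
#'   optional metadata column `direction` feeds the per-direction summary.
#' @param genes a [gene_models()] object.
#' @param upstream,downstream promoter extent around the TSS (bp).
#' @return List with `table` (data.frame: `region`, `gene_id`, `location`)
#'   and `summary` (list: `n_regions`, `n_associated_genes`,
#'   `n_promoter_genes`, `n_body_genes`, `n_both_genes`, and when directions
#'   are present `n_up_in_case` and `frac_up_in_case`).
#' @export
associate_regions_with_genes <- function(regions, genes, upstream = 2000,
                                         downstream = 2000) {
  stopifnot(is(regions, "GRanges"), inherits(genes, "GeneModels"))
  labs <- region_labels(regions)
  prom <- promoter_interval(genes, upstream, downstream)
  gid <- S4Vectors::mcols(genes$tx)$gene_id
  hp <- GenomicRanges::findOverlaps(regions, prom, ignore.strand = TRUE)
  hb <- GenomicRanges::findOverlaps(regions, genes$tx, ignore.strand = TRUE)
  tab <- rbind(
    data.frame(region = labs[S4Vectors::queryHits(hp)],
               gene_id = gid[S4Vectors::subjectHits(hp)],
               location = rep("promoter", length(hp)),
               stringsAsFactors = FALSE),
    data.frame(region = labs[S4Vectors::queryHits(hb)],
               gene_id = gid[S4Vectors::subjectHits(hb)],
               location = rep("body", length(hb)),
               stringsAsFactors = FALSE)
  )
  tab <- unique(tab)
  tab <- tab[order(tab$region, tab$gene_id, tab$location), , drop = FALSE]
  rownames(tab) <- NULL
  prom_genes <- unique(tab$gene_id[tab$location == "promoter"])
  body_genes <- unique(tab$gene_id[tab$location == "body"])
  summary <- list(
    n_regions = length(regions),
    n_associated_genes = length(unique(tab$gene_id)),
    n_promoter_genes = length(prom_genes),
    n_body_genes = length(body_genes),
    n_both_genes = length(intersect(prom_genes, body_genes))
  )
  dir <- S4Vectors::mcols(regions)$direction
  if (!is.null(dir)) {
    summary$n_up_in_case <- sum(dir == "up-in-case")
    summary$frac_up_in_case <- if (length(regions))
      sum(dir == "up-in-case") / length(regions) else NA_real_
  }
  list(table = tab, summary = summary)
}
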