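# Tag counting and RPKM density. A tag is assigned to a region iff its
# fragment midpoint, floor((start + end) / 2) in 0-based coordinates, lies in
# [region.start, region.end); strand is ignored (MeDIP fragments cover the
# methylated site symmetrically).

#' Count tags whose midpoint falls in each region
#'
#' @param library a [tag_library()].
#' @param regions a GRanges of query regions (any number).
#' @return Integer vector of counts, parallel to `regions`.
#' @export
region_tag_count <- function(library, regions) {
  stopifnot(inherits(library, "TagLibrary"), is(regions, "GRanges"))
  if (library$total_tags == 0) {
    return(integer(length(regions)))
  }
  mids <- midpoint_granges(library$tags)
  GenomicRanges::countOverlaps(regions, mids, ignore.strand = TRUE)
}

#' RPKM density of a count over a region
#'
#' Reads per kilobase of region per million mapped tags:
#' `count * 1e9 / (region_length * total_tags)`.
#'
#' @param count tag count (vectorized).
#' @param region_length region length in bp (> 0).
#' @param total_tags total mapped tags of the library (> 0).
#' @return Numeric RPKM values.
#' @export
rpkm_density <- function(count, region_length, total_tags) {
  if (any(region_length <= 0)) stop("region_length must be > 0")
  if (any(total_tags <= 0)) stop("total_tags must be > 0")
  count * 1e9 / (region_length * total_tags)
}

#' Per-region density records for one or more libraries
#'
#' @param regions GRanges of regions.
#' @param libraries a list of [tag_library()] objects.
#' @return data.frame with columns `region`, `chrom`, `start`, `end`,
#'   `library_id`, `count`, `rpkm` (one row per region x library).
#' @export
density_table <- function(regions, libraries) {
  if (inherits(libraries, "TagLibrary")) libraries <- list(libraries)
  labs <- region_labels(regions)
  bed <- granges_bed(regions)
  out <- lapply(libraries, function(lib) {
    cnt <- region_tag_count(lib, regions)
    data.frame(region = labs, chrom = bed$chrom, start = bed$start,
               end = bed$end, library_id = lib$library_id, count = cnt,
               rpkm = rpkm_density(cnt, GenomicRanges::width(regions),
                                   lib$total_tags),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a density table as TSV
#'
#' @param tab output of [density_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
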