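ASSAYS <- c("5mC-IP", "5hmC-IP", "input")
GROUPS <- c("case", "control")

#' Construct a tag library
#'
#' A tag library is one sample's set of aligned immunoprecipitation (or input)
#' fragments, together with the assay, the group label and the total tag
#' count that serves as the RPKM denominator.
#'
#' @param tags GRanges of aligned fragments (1-based; build from BED
#'   coordinates with [bed_granges()]).
#' @param library_id unique identifier for the library.
#' @param assay one of `"5mC-IP"`, `"5hmC-IP"`, `"input"`.
#' @param group one of `"case"`, `"control"`.
#' @return An object of class `TagLibrary`: a list with elements `tags`,
#'   `library_id`, `assay`, `group` and `total_tags` (`= length(tags)`).
#' @export
tag_library <- function(tags, library_id, assay, group) {
  stopifnot(is(tags, "GRanges"))
  if (!assay %in% ASSAYS) {
    stop("unknown assay '", assay, "'; expected one of: ",
         paste(ASSAYS, collapse = ", "))
  }
  if (!group %in% GROUPS) {
    stop("unknown group '", group, "'; expected one of: ",
         paste(GROUPS, collapse = ", "))
  }
  structure(
    list(tags = tags, library_id = as.character(library_id), assay = assay,
         group = group, total_tags = length(tags)),
    class = "TagLibrary"
  )
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary '%s' (%s, %s): %d tags\n",
              x$library_id, x$assay, x$group, x$total_tags))
  invisible(x)
}

#' Read a tag library from a 6-column BED file
#'
#' @param path BED file (chrom, start, end, name, score, strand).
#' @param library_id,assay,group library metadata (see [tag_library()]).
#' @param genome optional named vector of chromosome lengths.
#' @return A `TagLibrary`.
#' @export
read_tag_library <- function(path, library_id, assay, group, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- as.integer(genome)
  }
  S4Vectors::mcols(gr) <- NULL
  tag_library(gr, library_id, assay, group)
}

#' Write a tag library as a 6-column BED file
#'
#' @param library a `TagLibrary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tag_library <- function(library, path) {
  gr <- library$tags
  S4Vectors::mcols(gr)$name <- library$library_id
  S4Vectors::mcols(gr)$score <- 0
  write_bed(gr, path)
}
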