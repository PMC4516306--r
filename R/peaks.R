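# Sliding-window Poisson peak caller: a transparent enrichment test of an IP
# library against its input. Each window's expected IP count is the input
# count scaled by the library-size ratio, floored at the genome-wide
# background rate; the p-value is the Poisson upper tail and the FDR is
# Benjamini-Hochberg across all scanned windows of the library.

#' Scan sliding windows and score IP enrichment against input
#'
#' @param ip,input [tag_library()] objects; `input` is the non-IP background
#'   library. Both must be non-empty and carry seqlengths.
#' @param window_size window width in bp (default 200, on the order of the
#'   sonicated fragment size).
#' @param step window step in bp (default 50); must satisfy
#'   `window_size >= step > 0`.
#' @return GRanges of windows with metadata columns `ip_count`, `expected`,
#'   `p_value`, `q_value`; `metadata()$library_id` records the IP library.
#' @export
window_scan <- function(ip, input, window_size = 200, step = 50) {
  stopifnot(inherits(ip, "TagLibrary"), inherits(input, "TagLibrary"))
  if (!(window_size >= step && step > 0)) {
    stop("need window_size >= step > 0")
  }
  if (ip$total_tags == 0 || input$total_tags == 0) {
    stop("both libraries must contain tags")
  }
  G <- genome_length(ip$tags)
  if (G <= 0) stop("zero-length genome")
  sl <- GenomeInfoDb::seqlengths(ip$tags)
  wins <- lapply(names(sl), function(cn) {
    L <- sl[[cn]]
    if (L < window_size) return(NULL)
    s0 <- seq.int(0, L - window_size, by = step)
    bed_granges(rep(cn, length(s0)), s0, s0 + window_size, genome = sl)
  })
  wins <- do.call(c, Filter(Negate(is.null), wins))
  ip_count <- GenomicRanges::countOverlaps(wins, midpoint_granges(ip$tags),
                                           ignore.strand = TRUE)
  in_count <- GenomicRanges::countOverlaps(wins, midpoint_granges(input$tags),
                                           ignore.strand = TRUE)
  bg_rate <- ip$total_tags / G                       # tags per bp, genome-wide
  expected <- pmax(in_count * ip$total_tags / input$total_tags,
                   bg_rate * window_size)
  p <- ppois(ip_count - 1, expected, lower.tail = FALSE)  # P(X >= ip_count)
  S4Vectors::mcols(wins)$ip_count <- ip_count
  S4Vectors::mcols(wins)$expected <- expected
  S4Vectors::mcols(wins)$p_value <- p
  S4Vectors::mcols(wins)$q_value <- p.adjust(p, method = "BH")
  S4Vectors::metadata(wins)$library_id <- ip$library_id
  wins
}

#' Call peaks from window statistics
#'
#' Windows are kept iff `p_value < p_max` and `q_value < fdr_max`; kept
#' windows closer than `merge_gap` are merged into maximal peaks.
#'
#' @param stats output of [window_scan()].
#' @param p_max Poisson p-value threshold (default 1e-5).
#' @param fdr_max Benjamini-Hochberg FDR threshold (default 0.01).
#' @param merge_gap maximum gap (bp) between windows merged into one peak.
#' @return GRanges of peaks with metadata columns `best_p` (minimum window
#'   p-value), `n_windows`, `name` and `score` (`-log10(best_p)`, capped at
#'   1000); `metadata()$library_id` is carried over.
#' @export
call_peaks <- function(stats, p_max = 1e-5, fdr_max = 0.01, merge_gap = 100) {
  stopifnot(is(stats, "GRanges"))
  lib_id <- S4Vectors::metadata(stats)$library_id
  empty <- GenomicRanges::GRanges(
    seqlengths = GenomeInfoDb::seqlengths(stats),
    best_p = numeric(), n_windows = integer(),
    name = character(), score = numeric())
  S4Vectors::metadata(empty)$library_id <- lib_id
  if (!length(stats)) return(empty)
  keep <- S4Vectors::mcols(stats)$p_value < p_max &
    S4Vectors::mcols(stats)$q_value < fdr_max
  if (!any(keep)) return(empty)
  kept <- stats[keep]
  peaks <- GenomicRanges::reduce(kept, min.gapwidth = merge_gap + 1L)
  hit <- GenomicRanges::findOverlaps(peaks, kept)
  pmin_by <- tapply(S4Vectors::mcols(kept)$p_value[S4Vectors::subjectHits(hit)],
                    S4Vectors::queryHits(hit), min)
  S4Vectors::mcols(peaks)$best_p <- as.numeric(pmin_by)
  S4Vectors::mcols(peaks)$n_windows <-
    as.integer(table(factor(S4Vectors::queryHits(hit), seq_along(peaks))))
  S4Vectors::mcols(peaks)$name <-
    sprintf("%s_peak_%d", if (is.null(lib_id)) "lib" else lib_id,
            seq_along(peaks))
  S4Vectors::mcols(peaks)$score <-
    pmin(1000, -log10(pmax(S4Vectors::mcols(peaks)$best_p, 1e-300)))
  S4Vectors::metadata(peaks)$library_id <- lib_id
  peaks
}

#' Write peaks as BED5+ (name, -log10 best p as score)
#'
#' @param peaks output of [call_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  write_bed(peaks, path, extra_cols = c("best_p", "n_windows"))
}
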