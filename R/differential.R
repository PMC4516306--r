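# DMR/DHMR identification: consensus-union candidate regions from per-sample
# peak sets, an RPKM matrix (region x library), then a per-region pooled
# Student's t-test between groups combined with a fold-change filter
# (|log2 FC| >= log2(fold_min) and p < alpha, no multiple-testing
# correction). Fold changes use a small pseudo-density so empty regions do
# not divide by zero; the t-test is computed on the raw RPKM values.

#' Merge per-library peak sets into candidate regions
#'
#' The candidate universe for differential testing is the overlap-merged
#' union of every library's peaks for one assay.
#'
#' @param peak_sets list of peak GRanges (from [call_peaks()]), all from the
#'   same assay.
#' @param assay `"5mC"` or `"5hmC"` label recorded on the output.
#' @return GRanges of merged candidates with metadata columns `assay` and
#'   `source_libraries` (comma-joined contributing library ids).
#' @export
build_candidate_regions <- function(peak_sets, assay) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  if (length(assay) != 1) stop("candidates must come from a single assay")
  ids <- vapply(peak_sets, function(p) {
    id <- S4Vectors::metadata(p)$library_id
    if (is.null(id)) NA_character_ else id
  }, character(1))
  pooled <- do.call(c, unname(lapply(peak_sets, GenomicRanges::granges)))
  cand <- GenomicRanges::reduce(pooled, ignore.strand = TRUE)
  src <- character(length(cand))
  for (i in seq_along(peak_sets)) {
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(cand, peak_sets[[i]], ignore.strand = TRUE)))
    src[hit] <- ifelse(nzchar(src[hit]), paste(src[hit], ids[i], sep = ","),
                       ids[i])
  }
  S4Vectors::mcols(cand)$assay <- assay
  S4Vectors::mcols(cand)$source_libraries <- src
  cand
}

#' RPKM density matrix over candidate regions
#'
#' @param candidates GRanges of regions (e.g. [build_candidate_regions()]).
#' @param libraries list of IP [tag_library()] objects sharing one assay.
#' @return Numeric matrix (regions x libraries) of RPKM; rownames are
#'   `chrom:start-end` labels, colnames library ids. The candidate GRanges is
#'   kept as `attr(, "regions")`.
#' @export
density_matrix <- function(candidates, libraries) {
  stopifnot(is(candidates, "GRanges"), is.list(libraries))
  assays <- unique(vapply(libraries, `[[`, character(1), "assay"))
  if (length(assays) > 1) {
    stop("libraries mix assays: ", paste(assays, collapse = ", "))
  }
  m <- vapply(libraries, function(lib) {
    rpkm_density(region_tag_count(lib, candidates),
                 GenomicRanges::width(candidates), lib$total_tags)
  }, numeric(length(candidates)))
  m <- matrix(m, nrow = length(candidates),
              dimnames = list(region_labels(candidates),
                              vapply(libraries, `[[`, character(1),
                                     "library_id")))
  attr(m, "regions") <- candidates
  m
}

# Full per-region differential table (called and uncalled rows).
differential_table <- function(matrix, groups, fold_min = 2, alpha = 0.05,
                               eps = 0.5) {
  stopifnot(is.matrix(matrix))
  groups <- groups[colnames(matrix)]
  if (any(is.na(groups)) || !all(groups %in% GROUPS)) {
    stop("`groups` must map every matrix column to 'case' or 'control'")
  }
  idx_case <- which(groups == "case")
  idx_ctrl <- which(groups == "control")
  if (length(idx_case) < 2 || length(idx_ctrl) < 2) {
    stop("each group needs at least 2 libraries")
  }
  mean_case <- rowMeans(matrix[, idx_case, drop = FALSE])
  mean_ctrl <- rowMeans(matrix[, idx_ctrl, drop = FALSE])
  log2_fc <- log2((mean_case + eps) / (mean_ctrl + eps))
  n <- nrow(matrix)
  p <- rep(NA_real_, n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    x <- matrix[i, idx_case]; y <- matrix[i, idx_ctrl]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        skipped[i] <- TRUE          # degenerate: constant and equal
      } else {
        p[i] <- 0
      }
    } else {
      p[i] <- pooled_t_test(x, y)$p_value
    }
  }
  if (any(skipped)) {
    message(sum(skipped),
            " region(s) skipped: zero variance in both groups, equal means")
  }
  data.frame(
    region = rownames(matrix),
    mean_case = mean_case, mean_control = mean_ctrl,
    log2_fc = log2_fc, p_value = p,
    direction = ifelse(log2_fc >= 0, "up-in-case", "down-in-case"),
    called = !skipped & !is.na(p) & p < alpha &
      abs(log2_fc) >= log2(fold_min),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Call differential regions (DMRs / DHMRs)
#'
#' A region is called iff the two-sided pooled-variance t-test between the
#' case and control RPKM values gives `p < alpha` and the pseudo-counted
#' group-mean fold change satisfies `|log2 FC| >= log2(fold_min)`. P-values
#' are not multiple-testing corrected.
#'
#' @param matrix RPKM matrix from [density_matrix()].
#' @param groups named character vector mapping library ids (matrix columns)
#'   to `"case"` / `"control"`; each group needs >= 2 libraries.
#' @param fold_min minimum density fold difference (default 2).
#' @param alpha t-test p-value threshold (default 0.05).
#' @param eps pseudo-density (RPKM) added to both group means for the fold
#'   change only, never the t-test (default 0.5).
#' @return data.frame of called regions with columns `region`, `chrom`,
#'   `start`, `end`, `mean_case`, `mean_control`, `log2_fc`, `p_value`,
#'   `direction`; regions whose RPKM is constant and equal in both groups are
#'   skipped with a diagnostic message.
#' @export
call_differential_regions <- function(matrix, groups, fold_min = 2,
                                      alpha = 0.05, eps = 0.5) {
  tab <- differential_table(matrix, groups, fold_min, alpha, eps)
  out <- tab[tab$called, setdiff(names(tab), "called"), drop = FALSE]
  regions <- attr(matrix, "regions")
  coords <- if (!is.null(regions)) {
    granges_bed(regions)[tab$called, , drop = FALSE]
  } else {
    parse_region_labels(out$region)
  }
  out <- cbind(out[, "region", drop = FALSE],
               coords[, c("chrom", "start", "end")],
               out[, setdiff(names(out), "region"), drop = FALSE])
  rownames(out) <- NULL
  out
}

parse_region_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  data.frame(chrom = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             end = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' MA coordinates for every candidate region
#'
#' @inheritParams call_differential_regions
#' @return data.frame with `region`, `A` (mean RPKM across all libraries,
#'   plus `eps`), `M` (pseudo-counted log2 fold change, case over control)
#'   and `called` (the [call_differential_regions()] flag).
#' @export
ma_transform <- function(matrix, groups, fold_min = 2, alpha = 0.05,
                         eps = 0.5) {
  tab <- differential_table(matrix, groups, fold_min, alpha, eps)
  data.frame(region = tab$region,
             A = rowMeans(matrix) + eps,
             M = tab$log2_fc,
             called = tab$called,
             stringsAsFactors = FALSE)
}

#' Genes with both 5mC and 5hmC changes
#'
#' @param dmr_genes,dhmr_genes character vectors of gene ids associated with
#'   DMRs and DHMRs respectively.
#' @return Character vector of genes present in both sets.
#' @export
dmr_dhmr_gene_overlap <- function(dmr_genes, dhmr_genes) {
  intersect(unique(dmr_genes), unique(dhmr_genes))
}

#' Write a differential-region table as TSV
#'
#' @param regions output of [call_differential_regions()] (optionally with an
#'   added `genes` column from [associate_regions_with_genes()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_regions <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
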