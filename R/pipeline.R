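# One-config orchestration of the full analysis: simulate (or ingest) tag
# libraries, call peaks per IP library against its input, build candidate
# regions, call DMRs/DHMRs, annotate them against the gene models, compute
# metagene/TSS profiles, and write a machine-readable run report whose
# counts cross-check the output files.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate data from `synthetic`) or `"files"`
#'   (read libraries and gene models from `files`).
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param files list for file mode: `libraries` (data.frame with `path`,
#'   `library_id`, `assay`, `group`, `sample_id`), `gene_models` (BED12
#'   path), `genome` (named vector of chromosome lengths).
#' @param assays assays to analyze (`"5mC"`, `"5hmC"` or both).
#' @param window_size,step,merge_gap peak-caller geometry (bp).
#' @param p_max,fdr_max peak thresholds (Poisson p and BH FDR).
#' @param fold_min,alpha,eps differential thresholds (fold filter, t-test
#'   alpha, pseudo-density).
#' @param promoter_upstream,promoter_downstream promoter extent (bp).
#' @param n_body_bins,flank_fraction,tss_flank,tss_bin_size profile
#'   parameters.
#' @param output_dir directory for all outputs (created if needed).
#' @param write_libraries also write each simulated tag library as BED.
#' @param seed integer seed for the whole run; in synthetic mode it
#'   overrides `synthetic$seed`.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            synthetic = synthetic_config(),
                            files = NULL,
                            assays = c("5mC", "5hmC"),
                            window_size = 200, step = 50, merge_gap = 100,
                            p_max = 1e-5, fdr_max = 0.01,
                            fold_min = 2, alpha = 0.05, eps = 0.5,
                            promoter_upstream = 2000,
                            promoter_downstream = 2000,
                            n_body_bins = 100, flank_fraction = 0.2,
                            tss_flank = 5000, tss_bin_size = 100,
                            output_dir = tempfile("medipdiff_run_"),
                            write_libraries = FALSE,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(assays %in% c("5mC", "5hmC")),
            p_max > 0, fdr_max > 0, fold_min > 0, alpha > 0,
            window_size >= step, step > 0)
  if (mode == "files") {
    need <- c("libraries", "gene_models", "genome")
    if (is.null(files) || !all(need %in% names(files))) {
      stop("file mode needs `files` with: ", paste(need, collapse = ", "))
    }
  } else {
    stopifnot(inherits(synthetic, "SyntheticConfig"))
    synthetic$seed <- as.integer(seed)
  }
  structure(
    list(mode = mode, synthetic = synthetic, files = files, assays = assays,
         window_size = window_size, step = step, merge_gap = merge_gap,
         p_max = p_max, fdr_max = fdr_max, fold_min = fold_min,
         alpha = alpha, eps = eps,
         promoter_upstream = promoter_upstream,
         promoter_downstream = promoter_downstream,
         n_body_bins = n_body_bins, flank_fraction = flank_fraction,
         tss_flank = tss_flank, tss_bin_size = tss_bin_size,
         output_dir = output_dir, write_libraries = write_libraries,
         seed = as.integer(seed)),
    class = "PipelineConfig"
  )
}

assay_label <- function(assay) sub("-IP$", "", assay)

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, peak calling, differential calling, annotation
#' and profiling for every requested assay, writes BED/TSV outputs plus a
#' JSON run report to `config$output_dir`, and returns the report. The
#' report is a deterministic function of the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return The run report (list), invisibly; also written as `report.json`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  synthetic <- config$mode == "synthetic"
  if (synthetic) {
    sc <- config$synthetic
    genes <- stage("simulate", generate_gene_models(sc))
    truth <- stage("simulate", generate_truth_regions(sc, genes))
    samples <- data.frame(
      sample_id = c(sprintf("case_%d", seq_len(sc$n_case)),
                    sprintf("control_%d", seq_len(sc$n_control))),
      group = rep(GROUPS, c(sc$n_case, sc$n_control)),
      stringsAsFactors = FALSE)
    libs <- list()
    for (s in seq_len(nrow(samples))) {
      for (a in seq_along(ASSAYS)) {
        lib <- stage("simulate",
                     simulate_library(sc, truth, ASSAYS[a],
                                      samples$group[s],
                                      replicate_seed = s * 10L + a))
        lib$library_id <- paste0(samples$sample_id[s], "_",
                                 assay_label(ASSAYS[a]))
        lib$sample_id <- samples$sample_id[s]
        libs[[lib$library_id]] <- lib
      }
    }
    write_gene_models(genes, out("gene_models.bed"))
    write_truth_regions(truth, out("truth_regions.bed"))
  } else {
    fs <- config$files
    genes <- stage("ingest", read_gene_models(fs$gene_models, fs$genome))
    libs <- list()
    for (i in seq_len(nrow(fs$libraries))) {
      row <- fs$libraries[i, ]
      lib <- stage("ingest",
                   read_tag_library(row$path, row$library_id, row$assay,
                                    row$group, fs$genome))
      lib$sample_id <- row$sample_id
      libs[[lib$library_id]] <- lib
    }
    truth <- NULL
  }
  if (config$write_libraries) {
    for (lib in libs) {
      write_tag_library(lib, out(paste0("library_", lib$library_id, ".bed")))
    }
  }

  assay_of <- vapply(libs, `[[`, character(1), "assay")
  group_of <- vapply(libs, `[[`, character(1), "group")
  sample_of <- vapply(libs, `[[`, character(1), "sample_id")
  inputs <- libs[assay_of == "input"]
  names(inputs) <- sample_of[assay_of == "input"]

  report <- list(
    tool = "medipdiff", version = as.character(utils::packageVersion("medipdiff")),
    seed = config$seed, mode = config$mode,
    thresholds = list(p_max = config$p_max, fdr_max = config$fdr_max,
                      fold_min = config$fold_min, alpha = config$alpha),
    n_libraries = length(libs), assays = list())
  assoc_genes <- list()

  for (al in config$assays) {
    assay <- paste0(al, "-IP")
    ip_libs <- libs[assay_of == assay]
    peak_sets <- list()
    peak_counts <- list()
    for (lib in ip_libs) {
      inp <- inputs[[lib$sample_id]]
      if (is.null(inp)) stop("no input library for sample ", lib$sample_id)
      stats <- stage("peaks", window_scan(lib, inp, config$window_size,
                                          config$step))
      pk <- stage("peaks", call_peaks(stats, config$p_max, config$fdr_max,
                                      config$merge_gap))
      write_peaks(pk, out(paste0("peaks_", lib$library_id, ".bed")))
      peak_sets[[lib$library_id]] <- pk
      peak_counts[[lib$library_id]] <- length(pk)
    }

    cand <- stage("candidates", build_candidate_regions(peak_sets, al))
    write_bed(cand, out(paste0("candidates_", al, ".bed")),
              extra_cols = "source_libraries")
    mat <- stage("differential", density_matrix(cand, ip_libs))
    grp <- setNames(group_of[names(ip_libs)], names(ip_libs))
    dmr <- stage("differential",
                 call_differential_regions(mat, grp, config$fold_min,
                                           config$alpha, config$eps))
    ma <- stage("differential",
                ma_transform(mat, grp, config$fold_min, config$alpha,
                             config$eps))
    write.table(ma, out(paste0("ma_", al, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)

    dmr_gr <- bed_granges(dmr$chrom, dmr$start, dmr$end,
                          genome = GenomeInfoDb::seqlengths(genes$tx))
    S4Vectors::mcols(dmr_gr)$direction <- dmr$direction
    assoc <- stage("annotation",
                   associate_regions_with_genes(dmr_gr, genes,
                                                config$promoter_upstream,
                                                config$promoter_downstream))
    dmr$category <- as.character(
      classify_interval(dmr_gr, genes, config$promoter_upstream,
                        config$promoter_downstream))
    dmr$genes <- vapply(region_labels(dmr_gr), function(r) {
      paste(assoc$table$gene_id[assoc$table$region == r], collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    write_differential_regions(dmr, out(paste0("differential_", al, ".tsv")))
    write.table(assoc$table, out(paste0("associations_", al, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    pooled_tags <- sort(do.call(c, lapply(unname(ip_libs), function(l)
      GenomicRanges::granges(l$tags))))
    pooled <- tag_library(pooled_tags, paste0(al, "_pooled"), assay, "case")
    meta <- stage("profiles",
                  metagene_profile(pooled, genes, config$n_body_bins,
                                   config$flank_fraction))
    tssp <- stage("profiles",
                  tss_profile(pooled, genes, config$tss_flank,
                              config$tss_bin_size))
    write_profile(meta, out(paste0("metagene_", al, ".tsv")))
    write_profile(tssp, out(paste0("tss_profile_", al, ".tsv")))

    arep <- list(
      peaks_per_library = peak_counts,
      n_candidates = length(cand),
      n_differential = nrow(dmr),
      n_up_in_case = sum(dmr$direction == "up-in-case"),
      frac_up_in_case = if (nrow(dmr)) sum(dmr$direction == "up-in-case") /
        nrow(dmr) else NA,
      association = assoc$summary,
      category_counts = as.list(table(dmr$category)),
      metagene_genes = meta$n_genes)

    if (synthetic) {
      cross <- truth_crossref(truth, dmr_gr)
      write.table(cross, out(paste0("truth_crossref_", al, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      td <- cross[cross$kind != "shared-enriched", , drop = FALSE]
      n_calls <- length(dmr_gr)
      hit_any <- if (n_calls) GenomicRanges::countOverlaps(
        dmr_gr, truth, ignore.strand = TRUE) > 0 else logical(0)
      arep$truth_recovery <- list(
        n_truth_differential = nrow(td),
        n_recovered = sum(td$recovered),
        recovery_frac = if (nrow(td)) mean(td$recovered) else NA,
        n_false_calls = sum(!hit_any),
        false_call_frac = if (n_calls) mean(!hit_any) else 0)
    }
    report$assays[[al]] <- arep
    assoc_genes[[al]] <- unique(assoc$table$gene_id)
  }

  if (length(config$assays) == 2) {
    both <- dmr_dhmr_gene_overlap(assoc_genes[["5mC"]], assoc_genes[["5hmC"]])
    report$genes_with_both_5mC_and_5hmC_changes <- as.list(sort(both))
    report$n_genes_with_both <- length(both)
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}

# Truth regions vs called differential regions: a truth region is recovered
# iff some call of the matching direction overlaps it.
truth_crossref <- function(truth, calls_gr) {
  dir <- S4Vectors::mcols(calls_gr)$direction
  kind <- S4Vectors::mcols(truth)$kind
  want <- ifelse(kind == "case-up", "up-in-case",
                 ifelse(kind == "control-up", "down-in-case", NA))
  hits <- GenomicRanges::findOverlaps(truth, calls_gr, ignore.strand = TRUE)
  ok <- logical(length(truth)); match_lab <- character(length(truth))
  for (h in seq_along(hits)) {
    q <- S4Vectors::queryHits(hits)[h]; s <- S4Vectors::subjectHits(hits)[h]
    if (!is.na(want[q]) && dir[s] == want[q] && !ok[q]) {
      ok[q] <- TRUE
      match_lab[q] <- region_labels(calls_gr)[s]
    }
  }
  data.frame(region = region_labels(truth), kind = kind,
             fold = S4Vectors::mcols(truth)$fold,
             recovered = ok, matched_call = match_lab,
             stringsAsFactors = FALSE)
}
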