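peaks_gr <- function(starts, ends, lib_id) {
  gr <- bed_granges(rep("chr1", length(starts)), starts, ends,
                    genome = c(chr1 = 1e6))
  S4Vectors::metadata(gr)$library_id <- lib_id
  gr
}

toy_matrix <- function(case_vals, ctrl_vals) {
  m <- matrix(c(case_vals, ctrl_vals), nrow = 1)
  colnames(m) <- c(paste0("ca", seq_along(case_vals)),
                   paste0("co", seq_along(ctrl_vals)))
  rownames(m) <- "chr1:0-1000"
  m
}

toy_groups <- function(n_case = 4, n_ctrl = 4) {
  setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
           c(paste0("ca", 1:n_case), paste0("co", 1:n_ctrl)))
}

test_that("candidate regions are the overlap-merged union of peak sets", {
  a <- peaks_gr(c(100, 1000), c(300, 1200), "A")
  cand <- build_candidate_regions(list(a), "5mC")
  expect_identical(granges_bed(cand)[, 1:3], granges_bed(a)[, 1:3])

  b <- peaks_gr(c(100, 1000), c(300, 1200), "B")
  cand <- build_candidate_regions(list(a, b), "5mC")
  expect_length(cand, 2)
  expect_true(all(S4Vectors::mcols(cand)$source_libraries == "A,B"))

  c2 <- peaks_gr(250, 400, "C")
  cand <- build_candidate_regions(list(peaks_gr(100, 300, "A"), c2), "5mC")
  expect_identical(granges_bed(cand)[, c("start", "end")],
                   data.frame(start = 100L, end = 400L))
  expect_error(build_candidate_regions(list(a), c("5mC", "5hmC")), "single")
})

test_that("density matrix equals the composition of count and rpkm", {
  lib1 <- manual_library(c(100, 300, 700), c(200, 400, 800), id = "L1")
  lib2 <- manual_library(5000, 5200, id = "L2")
  cand <- bed_granges(c("chr1", "chr1"), c(0, 4000), c(1000, 6000))
  m <- density_matrix(cand, list(lib1, lib2))
  expect_identical(dim(m), c(2L, 2L))
  for (i in 1:2) {
    for (lib in list(lib1, lib2)) {
      expect_equal(m[i, lib$library_id],
                   rpkm_density(region_tag_count(lib, cand[i]),
                                width(cand[i]), lib$total_tags),
                   ignore_attr = TRUE)
    }
  }
  # zero row where no library has tags (toy genome is 10 kb)
  none <- bed_granges("chr1", 9000, 9100)
  expect_true(all(density_matrix(none, list(lib1, lib2)) == 0))
  bad <- manual_library(1, 10, assay = "5hmC-IP")
  expect_error(density_matrix(cand, list(lib1, bad)), "mix assays")
})

test_that("differential calls require both the fold and p-value thresholds", {
  # worked example: strong separation, log2 fc = log2(4.5/1.5)
  m <- toy_matrix(c(4.1, 3.9, 4.0, 4.0), c(1.0, 1.1, 0.9, 1.0))
  res <- call_differential_regions(m, toy_groups(), eps = 0.5)
  expect_identical(nrow(res), 1L)
  expect_identical(res$direction, "up-in-case")
  expect_equal(res$log2_fc, log2(4.5 / 1.5))
  # independent pooled-t oracle from the closed formula
  x <- c(4.1, 3.9, 4.0, 4.0); y <- c(1.0, 1.1, 0.9, 1.0)
  sp2 <- (3 * stats::var(x) + 3 * stats::var(y)) / 6
  t_ora <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_ora <- 2 * pt(-abs(t_ora), 6)
  expect_equal(res$p_value, p_ora, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-4)

  # equal groups: nothing called
  m <- toy_matrix(c(2, 2.1, 1.9, 2), c(2, 2.1, 1.9, 2))
  expect_identical(nrow(call_differential_regions(m, toy_groups())), 0L)

  # significant but below 2-fold: filtered out even at eps = 0
  m <- toy_matrix(c(2.0, 2.1, 1.9, 2.0), c(1.5, 1.6, 1.4, 1.5))
  expect_identical(nrow(call_differential_regions(m, toy_groups(), eps = 0)),
                   0L)
  full <- ma_transform(m, toy_groups(), eps = 0)
  expect_equal(full$M, log2(2 / 1.5))

  expect_error(call_differential_regions(m, setNames(
    c("case", "case", "case", "control", "control", "control", "missing",
      NA)[1:8], colnames(m))), "case")
  expect_error(
    call_differential_regions(toy_matrix(1:2, 3:4)[, 1:3, drop = FALSE],
                              toy_groups(2, 1)), "at least 2")
})

test_that("constant equal regions are skipped with a diagnostic", {
  m <- rbind("chr1:0-1000" = rep(2, 8),
             "chr1:5000-6000" = c(4, 4.2, 3.8, 4, 1, 1.2, 0.8, 1))
  colnames(m) <- names(toy_groups())
  expect_message(res <- call_differential_regions(m, toy_groups()),
                 "skipped")
  expect_identical(res$region, "chr1:5000-6000")
})

test_that("MA coordinates behave under group swap", {
  m <- toy_matrix(c(4, 4.2, 3.8, 4), c(1, 1.2, 0.8, 1))
  g <- toy_groups()
  ma <- ma_transform(m, g, eps = 0)
  expect_equal(ma$M, log2(4 / 1))
  expect_equal(ma$A, mean(m))
  swapped <- setNames(ifelse(g == "case", "control", "case"), names(g))
  ma2 <- ma_transform(m, swapped, eps = 0)
  expect_equal(ma2$A, ma$A)
  expect_equal(ma2$M, -ma$M)
})

test_that("swapping group labels mirrors calls exactly", {
  cfg <- small_config(seed = 31)
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  libs <- lapply(1:8, function(i) {
    g <- if (i <= 4) "case" else "control"
    lib <- simulate_library(cfg, truth, "5mC-IP", g, i)
    lib$library_id <- paste0("L", i)
    lib
  })
  cand <- granges(truth)   # use truth regions as the candidate universe
  m <- density_matrix(cand, libs)
  g <- setNames(rep(c("case", "control"), each = 4), paste0("L", 1:8))
  res <- call_differential_regions(m, g)
  swapped <- setNames(ifelse(g == "case", "control", "case"), names(g))
  res2 <- call_differential_regions(m, swapped)
  expect_identical(res$region, res2$region)
  expect_identical(res$direction,
                   ifelse(res2$direction == "up-in-case", "down-in-case",
                          "up-in-case"))
  expect_equal(res$p_value, res2$p_value)
})

test_that("every call satisfies both thresholds by construction", {
  cfg <- small_config(seed = 37)
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  libs <- lapply(1:8, function(i) {
    g <- if (i <= 4) "case" else "control"
    lib <- simulate_library(cfg, truth, "5hmC-IP", g, i)
    lib$library_id <- paste0("L", i)
    lib
  })
  m <- density_matrix(granges(truth), libs)
  g <- setNames(rep(c("case", "control"), each = 4), paste0("L", 1:8))
  res <- call_differential_regions(m, g)
  expect_gt(nrow(res), 0)
  expect_true(all(res$p_value < 0.05))
  expect_true(all(abs(res$log2_fc) >= 1))
  expect_identical(res$direction,
                   ifelse(res$log2_fc >= 0, "up-in-case", "down-in-case"))
})

test_that("null data (fold 1) is called at most at the alpha rate", {
  called <- 0; total <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(genome = c(chr1 = 5e5), n_genes = 0,
                            n_enriched_regions = 12,
                            n_differential_regions = 0,
                            enrichment_fold = 8, tags_per_library = 2e4,
                            seed = 100 + s)
    truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
    libs <- lapply(1:8, function(i) {
      g <- if (i <= 4) "case" else "control"
      lib <- simulate_library(cfg, truth, "5mC-IP", g, i)
      lib$library_id <- paste0("L", i)
      lib
    })
    m <- density_matrix(granges(truth), libs)
    g <- setNames(rep(c("case", "control"), each = 4), paste0("L", 1:8))
    res <- call_differential_regions(m, g)
    called <- called + nrow(res)
    total <- total + nrow(m)
  }
  expect_lte(called / total, 0.05)
})

test_that("gene-set overlap is plain intersection", {
  expect_identical(dmr_dhmr_gene_overlap(c("A", "B"), c("C")), character(0))
  expect_identical(dmr_dhmr_gene_overlap(c("PTPRN2", "GATA4"),
                                         c("PTPRN2", "CCDC149")), "PTPRN2")
  expect_setequal(dmr_dhmr_gene_overlap(c("A", "B"), c("A", "B")),
                  c("A", "B"))
})
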