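test_that("config validation enforces the generator's invariants", {
  expect_error(synthetic_config(fragment_length_range = c(100, 600)),
               "shorter than 500")
  expect_error(synthetic_config(differential_fold = 0.5), ">= 1")
  expect_error(synthetic_config(n_genes = -1), ">= 0")
  expect_error(synthetic_config(genome = c(chr1 = 1e4),
                                n_enriched_regions = 100), "too small")
})

test_that("gene models respect counts, bounds and length range", {
  cfg <- synthetic_config(genome = c(chr1 = 1e6), n_genes = 0, seed = 3)
  expect_length(generate_gene_models(cfg), 0)

  cfg <- synthetic_config(genome = c(chr1 = 1e6), n_genes = 5,
                          gene_length_range = c(1000, 2000), seed = 3)
  gm <- generate_gene_models(cfg)
  expect_length(gm, 5)
  expect_true(all(width(gm$tx) >= 1000 & width(gm$tx) <= 2000))
  expect_true(all(start(gm$tx) >= 1 & end(gm$tx) <= 1e6))
  # non-overlapping transcripts, each with >= 1 exon inside the tx
  expect_identical(length(reduce(gm$tx, ignore.strand = TRUE)), 5L)
  for (i in 1:5) {
    ex <- gm$exons[[i]]
    expect_gte(length(ex), 1)
    expect_true(all(start(ex) >= start(gm$tx[i]) & end(ex) <= end(gm$tx[i])))
    expect_true(!any(duplicated(unlist(mapply(seq, start(ex), end(ex))))))
  }
})

test_that("gene models are deterministic for a fixed seed", {
  cfg <- synthetic_config(genome = c(chr1 = 1e6), n_genes = 10, seed = 42)
  a <- generate_gene_models(cfg)
  b <- generate_gene_models(cfg)
  expect_identical(granges_bed(a$tx), granges_bed(b$tx))
  expect_identical(lapply(a$exons, granges_bed), lapply(b$exons, granges_bed))
})

test_that("truth regions echo the config and never overlap", {
  cfg <- small_config(n_differential_regions = 0)
  gm <- generate_gene_models(cfg)
  truth <- generate_truth_regions(cfg, gm)
  expect_true(all(mcols(truth)$kind == "shared-enriched"))

  cfg <- small_config(n_differential_regions = 20, differential_fold = 4)
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  diff <- truth[mcols(truth)$kind != "shared-enriched"]
  expect_length(diff, 20)
  expect_true(all(mcols(diff)$fold == 4))
  expect_setequal(unique(mcols(diff)$kind), c("case-up", "control-up"))
  expect_identical(length(reduce(truth, ignore.strand = TRUE)),
                   length(truth))
  # deterministic
  truth2 <- generate_truth_regions(cfg, generate_gene_models(cfg))
  expect_identical(granges_bed(truth), granges_bed(truth2))
})

test_that("simulated libraries are reproducible and within bounds", {
  cfg <- small_config()
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  a <- simulate_library(cfg, truth, "5mC-IP", "case", 1)
  b <- simulate_library(cfg, truth, "5mC-IP", "case", 1)
  expect_identical(granges_bed(a$tags), granges_bed(b$tags))
  expect_identical(a$total_tags, cfg$tags_per_library)
  w <- width(a$tags)
  expect_true(all(w >= 100 & w <= 400 & w < 500))
  sl <- GenomeInfoDb::seqlengths(a$tags)
  bed <- granges_bed(a$tags)
  expect_true(all(bed$start >= 0 & bed$end <= sl[bed$chrom]))
  # a different replicate seed gives a different library
  c <- simulate_library(cfg, truth, "5mC-IP", "case", 2)
  expect_false(identical(granges_bed(a$tags), granges_bed(c$tags)))
  expect_error(simulate_library(cfg, truth, "H3K4", "case", 1), "assay")
  expect_error(simulate_library(cfg, truth, "input", "treated", 1), "group")
})

test_that("input libraries have background density inside truth regions", {
  cfg <- synthetic_config(genome = c(chr1 = 1e6), n_genes = 0,
                          n_enriched_regions = 5, n_differential_regions = 0,
                          region_length_range = c(5000, 10000),
                          tags_per_library = 1e6, seed = 5)
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  lib <- simulate_library(cfg, truth, "input", "case", 9)
  inside <- sum(region_tag_count(lib, truth))
  frac_len <- sum(width(truth)) / 1e6
  ratio <- (inside / lib$total_tags) / frac_len
  expect_lt(abs(ratio - 1), 0.10)
})

test_that("case-up regions show the configured density ratio between groups", {
  cfg <- synthetic_config(genome = c(chr1 = 2e6), n_genes = 0,
                          n_enriched_regions = 0,
                          n_differential_regions = 10,
                          differential_fold = 4, enrichment_fold = 8,
                          region_length_range = c(1000, 2000),
                          tags_per_library = 2e5, seed = 8)
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  up <- truth[mcols(truth)$kind == "case-up"]
  case_lib <- simulate_library(cfg, truth, "5mC-IP", "case", 1)
  ctrl_lib <- simulate_library(cfg, truth, "5mC-IP", "control", 2)
  ratio <- sum(region_tag_count(case_lib, up)) /
    sum(region_tag_count(ctrl_lib, up))
  expect_lt(abs(ratio - 4), 4 * 0.15)
})

test_that("region tag counts match the mixture's closed-form expectations", {
  # chi-square goodness of fit (regions + rest-of-genome) across seeds
  passes <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(genome = c(chr1 = 2e5), n_genes = 0,
                            n_enriched_regions = 3,
                            n_differential_regions = 2,
                            differential_fold = 4, enrichment_fold = 8,
                            region_length_range = c(500, 2000),
                            tags_per_library = 5000, seed = s)
    truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
    lib <- simulate_library(cfg, truth, "5mC-IP", "case", s + 1000)
    obs <- region_tag_count(lib, truth)
    exp_counts <- expected_region_count(cfg, truth, "5mC-IP", "case")
    obs <- c(obs, lib$total_tags - sum(obs))
    probs <- c(exp_counts, cfg$tags_per_library - sum(exp_counts)) /
      cfg$tags_per_library
    p <- suppressWarnings(stats::chisq.test(obs, p = probs)$p.value)
    if (p > 0.01) passes <- passes + 1
  }
  expect_gte(passes, 95)
})

test_that("degenerate enrichment makes IP indistinguishable from input", {
  cfg <- synthetic_config(genome = c(chr1 = 5e5), n_genes = 0,
                          n_enriched_regions = 5, n_differential_regions = 4,
                          enrichment_fold = 1, differential_fold = 1,
                          tags_per_library = 2e4, seed = 13)
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  ps <- vapply(1:20, function(s) {
    ip <- simulate_library(cfg, truth, "5mC-IP", "case", s)
    inp <- simulate_library(cfg, truth, "input", "case", s + 100)
    suppressWarnings(stats::ks.test(start(ip$tags), start(inp$tags))$p.value)
  }, numeric(1))
  # p-values should look uniform, not concentrated at 0
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("truth regions and libraries round-trip through BED", {
  cfg <- small_config()
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  f <- tempfile(fileext = ".bed")
  write_truth_regions(truth, f)
  tab <- read.delim(f, header = FALSE)
  expect_identical(nrow(tab), length(truth))
  expect_setequal(unique(tab$V4),
                  unique(mcols(truth)$kind))

  lib <- simulate_library(cfg, truth, "input", "control", 3)
  f2 <- tempfile(fileext = ".bed")
  write_tag_library(lib, f2)
  back <- read_tag_library(f2, lib$library_id, lib$assay, lib$group,
                           genome = cfg$genome)
  expect_identical(back$total_tags, lib$total_tags)
  expect_identical(granges_bed(sort(back$tags)), granges_bed(sort(lib$tags)))
})
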