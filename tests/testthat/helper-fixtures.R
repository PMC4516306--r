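# Shared fixtures: all synthetic, built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# A library with explicitly placed fragments on a toy genome.
manual_library <- function(starts, ends, chrom = "chr1",
                           genome = c(chr1 = 1e4),
                           id = "lib", assay = "5mC-IP", group = "case") {
  tag_library(bed_granges(rep(chrom, length(starts)), starts, ends,
                          genome = genome),
              id, assay, group)
}

# Uniform-background library via the generator (input assay = no enrichment).
uniform_library <- function(genome = c(chr1 = 1e5), n_tags = 2e4, seed = 1,
                            assay = "input", group = "case") {
  cfg <- synthetic_config(genome = genome, n_genes = 0,
                          n_enriched_regions = 0, n_differential_regions = 0,
                          tags_per_library = n_tags, seed = seed)
  truth <- generate_truth_regions(cfg, generate_gene_models(cfg))
  simulate_library(cfg, truth, assay, group, replicate_seed = seed)
}

# Small but non-trivial scenario for stage-level tests.
small_config <- function(seed = 11, n_genes = 50, n_enriched_regions = 8,
                         n_differential_regions = 8, ...) {
  synthetic_config(genome = c(chr1 = 1e6, chr2 = 5e5), n_genes = n_genes,
                   n_enriched_regions = n_enriched_regions,
                   n_differential_regions = n_differential_regions,
                   tags_per_library = 5e4, seed = seed, ...)
}

# One stranded gene with known structure on a 1e5 bp chromosome:
# tx [10000, 20000), exons [10000,12000) [14000,16000) [18000,20000),
# CDS [11000, 19000).
toy_genes <- function(strand = "+", genome = c(chr1 = 1e5)) {
  tx <- bed_granges("chr1", 10000, 20000, strand, genome = genome)
  mcols(tx)$gene_id <- "G1"
  mcols(tx)$cds_start <- 11000L
  mcols(tx)$cds_end <- 19000L
  exons <- GRangesList(G1 = bed_granges(rep("chr1", 3),
                                        c(10000, 14000, 18000),
                                        c(12000, 16000, 20000),
                                        rep(strand, 3), genome = genome))
  gene_models(tx, exons)
}
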