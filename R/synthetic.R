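# Seeded synthetic (h)MeDIP-seq data: a small genome, non-overlapping gene
# models, a truth set of enriched / differential regions, and per-sample tag
# libraries drawn from a categorical mixture (uniform background plus
# region-wise enrichment). The mixture gives closed-form expected counts, so
# every downstream stage can be checked against ground truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study design the package targets: two groups of four
#' samples, three libraries (5mC-IP, 5hmC-IP, input) per sample, sonicated
#' fragments shorter than 500 bp, a background of genome-wide coverage,
#' enriched regions shared by both groups, and spiked differential regions
#' with a 4-fold between-group density difference.
#'
#' @param genome named vector of chromosome lengths in bp.
#' @param n_genes number of non-overlapping gene models to place.
#' @param gene_length_range min/max transcript length (bp).
#' @param n_enriched_regions shared (non-differential) enriched regions.
#' @param n_differential_regions spiked differential regions, split evenly
#'   between case-up and control-up.
#' @param differential_fold between-group density ratio inside differential
#'   regions (>= 1).
#' @param enrichment_fold IP enrichment of regions over background (>= 1).
#' @param fragment_length_range min/max fragment length; max must be < 500.
#' @param tags_per_library fragments emitted per library.
#' @param n_case,n_control samples per group.
#' @param region_length_range min/max truth-region length (bp).
#' @param seed integer seed governing genome layout and truth placement.
#' @return A validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(genome = c(chr1 = 5e6, chr2 = 5e6),
                             n_genes = 200,
                             gene_length_range = c(2000, 10000),
                             n_enriched_regions = 30,
                             n_differential_regions = 20,
                             differential_fold = 4,
                             enrichment_fold = 8,
                             fragment_length_range = c(100, 400),
                             tags_per_library = 2e5,
                             n_case = 4, n_control = 4,
                             region_length_range = c(500, 2000),
                             seed = 1L) {
  stopifnot(length(genome) >= 1, all(genome > 0), !is.null(names(genome)))
  counts <- c(n_genes, n_enriched_regions, n_differential_regions,
              tags_per_library, n_case, n_control)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (max(fragment_length_range) >= 500) {
    stop("fragments must be shorter than 500 bp")
  }
  if (min(fragment_length_range) < 1) stop("fragment lengths must be >= 1")
  if (differential_fold < 1) stop("differential_fold must be >= 1")
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  stopifnot(gene_length_range[1] <= gene_length_range[2],
            region_length_range[1] <= region_length_range[2])
  need <- (n_enriched_regions + n_differential_regions) *
    max(region_length_range)
  if (need > sum(genome)) {
    stop("genome too small for the requested truth regions (need ~", need,
         " bp, have ", sum(genome), ")")
  }
  structure(
    list(genome = genome, n_genes = as.integer(n_genes),
         gene_length_range = gene_length_range,
         n_enriched_regions = as.integer(n_enriched_regions),
         n_differential_regions = as.integer(n_differential_regions),
         differential_fold = differential_fold,
         enrichment_fold = enrichment_fold,
         fragment_length_range = fragment_length_range,
         tags_per_library = as.integer(tags_per_library),
         n_case = as.integer(n_case), n_control = as.integer(n_control),
         region_length_range = region_length_range,
         seed = as.integer(seed)),
    class = "SyntheticConfig"
  )
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed %% 2147483647L)
  code
}

genome_granges <- function(genome) {
  bed_granges(names(genome), rep(0, length(genome)), unname(genome),
              genome = genome)
}

#' Generate non-overlapping synthetic gene models
#'
#' Transcripts are assigned to chromosomes proportionally to length and laid
#' out without overlap; each has 1-6 exons spanning the transcript and, for
#' most genes, a CDS strictly inside it (so 5'/3' UTRs exist). Deterministic
#' for a fixed `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A [gene_models()] object with `config$n_genes` transcripts.
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$n_genes
  if (n == 0) {
    return(gene_models(GenomicRanges::GRanges(seqlengths = config$genome),
                       GenomicRanges::GRangesList()))
  }
  with_seed(config$seed, {
    lr <- config$gene_length_range
    len <- sample(seq.int(lr[1], lr[2]), n, replace = TRUE)
    chrom <- sample(names(config$genome), n, replace = TRUE,
                    prob = config$genome / sum(config$genome))
    starts <- integer(n); ok <- TRUE; shortfall <- 0
    for (cn in names(config$genome)) {
      idx <- which(chrom == cn)
      if (!length(idx)) next
      free <- config$genome[[cn]] - sum(len[idx])
      if (free < 0) {
        stop("cannot place ", length(idx), " genes on ", cn,
             ": short by ", -free, " bp")
      }
      u <- sort(runif(length(idx), 0, free))
      starts[idx] <- floor(u + cumsum(c(0, len[idx][-length(idx)])))
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tx <- bed_granges(chrom, starts, starts + len, strand, config$genome)
    ids <- sprintf("SYNG%04d", seq_len(n))
    S4Vectors::mcols(tx)$gene_id <- ids

    exon_list <- vector("list", n)
    cds_start <- cds_end <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      li <- len[i]
      n_ex <- sample(1:6, 1)
      n_seg <- 2L * n_ex - 1L
      if (li < 4L * n_seg) n_ex <- 1L
      if (n_ex == 1L) {
        ex0 <- starts[i]; ex1 <- starts[i] + li
      } else {
        cuts <- sort(sample(seq_len(li - 1L), 2L * n_ex - 2L))
        bounds <- c(0L, cuts, li)
        seg_s <- bounds[-length(bounds)]
        seg_e <- bounds[-1]
        keep <- seq(1, 2L * n_ex - 1L, by = 2)   # odd segments are exons
        ex0 <- starts[i] + seg_s[keep]
        ex1 <- starts[i] + seg_e[keep]
      }
      exon_list[[i]] <- bed_granges(rep(chrom[i], length(ex0)), ex0, ex1,
                                    rep(strand[i], length(ex0)),
                                    config$genome)
      if (runif(1) < 0.8 && li >= 300) {
        off5 <- floor(runif(1, 0.05, 0.35) * li)
        off3 <- floor(runif(1, 0.05, 0.35) * li)
        cds_start[i] <- starts[i] + off5
        cds_end[i] <- starts[i] + li - off3
      }
    }
    S4Vectors::mcols(tx)$cds_start <- cds_start   # 0-based, half-open
    S4Vectors::mcols(tx)$cds_end <- cds_end
    exons <- GenomicRanges::GRangesList(exon_list)
    names(exons) <- ids
    gene_models(tx, exons)
  })
}

#' Generate the truth set of enriched and differential regions
#'
#' Shared-enriched regions are uniform over the genome; differential regions
#' alternate between promoter-anchored and gene-body-anchored placements when
#' gene models are available (random otherwise), and are split between
#' case-up and control-up. Regions never overlap one another.
#'
#' @param config a [synthetic_config()].
#' @param genes a [gene_models()] object (may be empty).
#' @param min_gap minimum separation between truth regions (bp).
#' @return GRanges with metadata columns `kind` (`shared-enriched`,
#'   `case-up`, `control-up`) and `fold` (1 for shared regions,
#'   `config$differential_fold` for differential ones).
#' @export
generate_truth_regions <- function(config, genes, min_gap = 2000) {
  stopifnot(inherits(config, "SyntheticConfig"), inherits(genes, "GeneModels"))
  n_diff <- config$n_differential_regions
  n_up <- ceiling(n_diff / 2)
  kinds <- c(rep("shared-enriched", config$n_enriched_regions),
             rep("case-up", n_up), rep("control-up", n_diff - n_up))
  n <- length(kinds)
  if (n == 0) {
    return(GenomicRanges::GRanges(seqlengths = config$genome,
                                  kind = character(), fold = numeric()))
  }
  with_seed(config$seed + 1L, {
    rl <- config$region_length_range
    lens <- sample(seq.int(rl[1], rl[2]), n, replace = TRUE)
    placed <- GenomicRanges::GRanges(seqlengths = config$genome)
    chroms <- character(n); starts <- numeric(n)
    have_genes <- length(genes) > 0
    diff_idx <- 0
    for (i in seq_len(n)) {
      anchor <- "random"
      if (kinds[i] != "shared-enriched" && have_genes) {
        diff_idx <- diff_idx + 1
        anchor <- if (diff_idx %% 2 == 1) "promoter" else "body"
      }
      done <- FALSE
      for (try in 1:1000) {
        if (anchor == "random") {
          cn <- sample(names(config$genome), 1,
                       prob = config$genome / sum(config$genome))
          s0 <- floor(runif(1, 0, config$genome[[cn]] - lens[i]))
        } else {
          g <- sample(length(genes), 1)
          tx <- genes$tx[g]
          cn <- as.character(GenomeInfoDb::seqnames(tx))
          if (anchor == "promoter") {
            tss0 <- if (as.character(GenomicRanges::strand(tx)) == "+")
              GenomicRanges::start(tx) - 1L else GenomicRanges::end(tx)
            lo <- tss0 - 2000; hi <- tss0 + 2000 - lens[i]
          } else {
            lo <- GenomicRanges::start(tx) - 1L
            hi <- GenomicRanges::end(tx) - lens[i]
          }
          lo <- max(0, lo)
          hi <- min(config$genome[[cn]] - lens[i], hi)
          if (hi <= lo) next
          s0 <- floor(runif(1, lo, hi))
        }
        cand <- bed_granges(cn, s0, s0 + lens[i], genome = config$genome)
        pad <- suppressWarnings(
          GenomicRanges::trim(GenomicRanges::resize(cand,
                                                    lens[i] + 2 * min_gap,
                                                    fix = "center")))
        if (!length(placed) ||
            !any(GenomicRanges::countOverlaps(pad, placed) > 0)) {
          placed <- c(placed, cand)
          chroms[i] <- cn; starts[i] <- s0
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop("could not place truth region ", i, " (", kinds[i],
             ") without overlap; genome too crowded")
      }
    }
    out <- bed_granges(chroms, starts, starts + lens, genome = config$genome)
    S4Vectors::mcols(out)$kind <- kinds
    S4Vectors::mcols(out)$fold <- ifelse(kinds == "shared-enriched", 1,
                                         config$differential_fold)
    sort(out)
  })
}

# Per-region density multiplier over background for one (assay, group).
# Differential regions split the fold symmetrically (x sqrt(fold) for the
# favored group, / sqrt(fold) for the other) so the between-group density
# ratio is exactly `fold` while both groups remain enriched.
region_multipliers <- function(config, truth, assay, group) {
  if (!assay %in% ASSAYS) stop("unknown assay '", assay, "'")
  if (!group %in% GROUPS) stop("unknown group '", group, "'")
  if (assay == "input" || !length(truth)) {
    return(rep(1, length(truth)))
  }
  e <- config$enrichment_fold
  kind <- S4Vectors::mcols(truth)$kind
  fold <- S4Vectors::mcols(truth)$fold
  f <- rep(e, length(truth))
  up <- (kind == "case-up" & group == "case") |
    (kind == "control-up" & group == "control")
  dn <- (kind == "case-up" & group == "control") |
    (kind == "control-up" & group == "case")
  f[up] <- e * sqrt(fold[up])
  f[dn] <- e / sqrt(fold[dn])
  f
}

#' Closed-form expected tag count in each truth region
#'
#' Under the generator's mixture model the probability that one fragment
#' midpoint lands in region r of length L_r and multiplier f_r is
#' L_r f_r / T with T = G + sum L_r (f_r - 1) (G = genome length).
#'
#' @inheritParams simulate_library
#' @return numeric vector of expected counts, parallel to `truth`.
#' @export
expected_region_count <- function(config, truth, assay, group) {
  f <- region_multipliers(config, truth, assay, group)
  L <- GenomicRanges::width(truth)
  G <- sum(as.numeric(config$genome))
  total_mass <- G + sum(L * (f - 1))
  config$tags_per_library * L * f / total_mass
}

#' Simulate one tag library
#'
#' Fragment midpoints are drawn from a categorical mixture: uniform
#' background over the genome plus, for IP assays, the truth regions at
#' their enrichment multipliers (see [generate_truth_regions()]). Input
#' libraries draw background only. Fragment lengths are uniform in
#' `config$fragment_length_range`; fragments are shifted to stay inside
#' chromosome bounds.
#'
#' @param config a [synthetic_config()].
#' @param truth truth-region GRanges from [generate_truth_regions()].
#' @param assay `"5mC-IP"`, `"5hmC-IP"` or `"input"`.
#' @param group `"case"` or `"control"`.
#' @param replicate_seed per-library seed; the emitted library is a
#'   deterministic function of `(config$seed, replicate_seed)`.
#' @return A [tag_library()] with `config$tags_per_library` fragments.
#' @export
simulate_library <- function(config, truth, assay, group, replicate_seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  f <- region_multipliers(config, truth, assay, group)  # validates labels
  n <- config$tags_per_library
  genome <- config$genome
  seed <- (config$seed * 10007 + as.integer(replicate_seed)) %% 2147483647L
  with_seed(seed, {
    L <- GenomicRanges::width(truth)
    G <- sum(as.numeric(genome))
    bg <- GenomicRanges::setdiff(genome_granges(genome),
                                 GenomicRanges::granges(truth),
                                 ignore.strand = TRUE)
    w <- c(L * f, GenomicRanges::width(bg))        # region comps, then bg comps
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    all_comp <- c(GenomicRanges::granges(truth), GenomicRanges::granges(bg))
    cs0 <- GenomicRanges::start(all_comp)[comp] - 1L
    cw <- GenomicRanges::width(all_comp)[comp]
    chrom <- as.character(GenomeInfoDb::seqnames(all_comp))[comp]
    m0 <- cs0 + floor(runif(n) * cw)
    fl <- config$fragment_length_range
    len <- sample(seq.int(fl[1], fl[2]), n, replace = TRUE)
    s0 <- m0 - len %/% 2L
    cl <- unname(genome[chrom])
    s0 <- pmax(0, pmin(s0, cl - len))
    tags <- bed_granges(chrom, s0, s0 + len, genome = genome)
    tag_library(sort(tags),
                sprintf("%s_%s_r%d", group, assay, as.integer(replicate_seed)),
                assay, group)
  })
}

#' Write truth regions as BED (kind in column 4, fold in column 5)
#'
#' @param truth GRanges from [generate_truth_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_regions <- function(truth, path) {
  gr <- truth
  S4Vectors::mcols(gr)$name <- S4Vectors::mcols(truth)$kind
  S4Vectors::mcols(gr)$score <- S4Vectors::mcols(truth)$fold
  write_bed(gr, path)
}
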