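---
title: "Methods: differential 5mC/5hmC analysis from (h)MeDIP-seq tag libraries"
author: "medipdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential 5mC/5hmC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdiff)
```

# Scope and data model

`medipdiff` analyzes (hydroxy)methylated-DNA immunoprecipitation sequencing
experiments in which each sample contributes up to three aligned tag
libraries — a 5mC IP, a 5hmC IP and a non-immunoprecipitated input — and
samples fall into two groups (case/control). The package starts from
aligned fragment coordinates (BED-like), not reads: base calling, alignment
and demultiplexing are upstream of its scope, as are affinity-matrix
methods (DiffBind-style), gene-ontology enrichment and instrument-level
MassARRAY processing.

All files exchanged with the package are BED-family, 0-based half-open.
Internally every interval is a `GRanges`. Throughout the package a fragment
is reduced to a single tag position, the **fragment midpoint**
`floor((start + end) / 2)`, and strand is ignored. Rationale: MeDIP
fragments cover the methylated site roughly symmetrically, and no
shift/extension model is available for this assay; the midpoint rule also
makes counts exactly additive over interval partitions, which the tests
exploit. The alternative (counting any overlap) would count one fragment in
several adjacent windows and break additivity.

# Peak calling

IP enrichment against input is tested on sliding windows (defaults: 200 bp
window, 50 bp step). For window $w$ with IP count $k_w$,

$$\lambda_w = \max\!\left(k^{\mathrm{input}}_w \cdot
  \frac{N_{\mathrm{IP}}}{N_{\mathrm{input}}},\;
  \frac{N_{\mathrm{IP}}}{G}\cdot |w|\right),
  \qquad p_w = P\{X \ge k_w\},\; X \sim \mathrm{Poisson}(\lambda_w),$$

where $N$ are total mapped tags and $G$ the genome length. The flooring at
the genome-wide background rate prevents zero-expected windows where the
input is locally empty. FDR is Benjamini–Hochberg across all scanned
windows of one library. Windows with $p < 10^{-5}$ **and** $q < 0.01$ are
kept and merged into peaks across gaps of at most `merge_gap` (default
100 bp).

This is a deliberately transparent stand-in for model-based callers such as
MACS: no fragment-shift model, no local-lambda cascade. The thresholds
($p < 10^{-5}$, FDR $< 0.01$) are the analysis-level contract; the caller
itself is simple enough to verify against an exact Poisson tail-sum oracle
(the tests require agreement to $10^{-12}$). Window size was chosen on the
order of the sonicated fragment size (< 500 bp); peaks on real data from
other callers can be supplied through the same candidate-region interface.

# Differential regions (DMRs / DHMRs)

The differential unit is the **candidate region**: the overlap-merged union
of all libraries' peaks of one assay. This consensus-union choice mirrors
the common consensus-peak practice of affinity-based tools and guarantees
that a region enriched in only one group still enters the test.

For candidate $r$ and library $s$, the density is
$\mathrm{RPKM}_{rs} = 10^9 \, k_{rs} / (L_r N_s)$ — reads per kb of region
per million mapped tags of that library. A region is called differential
iff

* a two-sided pooled-variance Student's t-test on the per-library RPKMs
  (case vs control) gives $p < \alpha$ (default 0.05), and
* the pseudo-counted fold change
  $\log_2\frac{\bar d_{\mathrm{case}} + \varepsilon}
              {\bar d_{\mathrm{control}} + \varepsilon}$
  has magnitude $\ge \log_2(\texttt{fold\_min})$ (default 2-fold).

No multiple-testing correction is applied to the per-region p-values; this
matches the analysis the package reproduces but is anti-conservative, and
users comparing many thousands of candidates should treat the calls as a
screening set. The pseudo-density $\varepsilon$ (default 0.5 RPKM) guards
the fold change against empty control means; it is **not** added to the
t-test values, so it only disables fold-filter blowups, never manufactures
significance. Regions with zero variance and equal means in both groups
are skipped with a diagnostic; zero variance with unequal means yields
$p = 0$ (the pooled statistic degenerates).

`ma_transform()` exposes the same quantities in MA form: $A$ = mean RPKM
across all libraries ($+\varepsilon$), $M$ = the pseudo-counted log2 fold
change, with the call flag attached.

# Annotation and profiles

Promoters are $[\mathrm{TSS} - 2\,\mathrm{kb},\ \mathrm{TSS} +
2\,\mathrm{kb})$, strand-aware (TSS is the transcript start for `+` genes
and the transcript end bound for `-` genes), clipped at chromosome edges.
Single-category classification uses the region **midpoint** under the
precedence promoter > 5'UTR > 3'UTR > exon > intron > intergenic; a
precedence is required because one midpoint can legitimately sit in several
features of overlapping genes, and pie-chart style accounting needs the
categories to sum to one. Gene **association** is deliberately different:
any overlap of the region with a transcript or promoter associates the
region with that gene (location `body` / `promoter`, possibly both), since
per-gene counting should not drop a region that straddles a boundary.
Collapsed single-transcript gene models are assumed; isoform resolution is
out of scope.

Metagene profiles rescale each gene body to `n_body_bins` (default 100)
equal bins with flanks of 20 % of the gene length (20 bins per side), so
all bins of one gene share one width; minus-strand genes are reversed so
bin 0 is always upstream. Genes shorter than `n_body_bins` bp are dropped
with a message (sub-bp bins are meaningless). TSS profiles use fixed
±5 kb windows in 100 bp bins, strand-oriented with upstream negative. Both
report mean per-gene density in tags per bp per million mapped tags
(×10⁹, i.e. bin-level RPKM), so a uniform library gives a flat profile at
the genome-average density — a property the tests check (max/min bin ratio
< 1.2 at the tested depth). A `genes` argument lets callers profile all
genes or only, e.g., DMR-associated genes.

# Validation statistics

* `qpcr_relative_enrichment()`: comparative-CT enrichment
  $2^{\mathrm{Ct_{input}} - \mathrm{Ct_{IP}}}$.
* `pooled_t_test()`: classical pooled-variance two-sample t
  (df $= n_1 + n_2 - 2$). On the bundled 4 vs 4 clinical table it
  reproduces six of the printed p-values to three decimals (systolic BP
  0.002, gestation 0.469, BMI 0.799, hemoglobin 0.358, AST 0.777, ALT
  0.447). Rows it does not reproduce (maternal age, diastolic BP,
  proteinuria) are consistent with an analysis that applied the
  Mann–Whitney test to some rows; `clinical_table_compare()` therefore
  accepts per-row test overrides rather than silently fitting a test to
  each printed value.
* `mann_whitney()`: exact mode enumerates all $\binom{n_1+n_2}{n_1}$ group
  assignments of the midrank-tied pooled sample (feasible for
  $n_1+n_2 \le 12$; at 4 vs 4 complete separation gives $p = 2/70$);
  asymptotic mode is the tie-corrected normal approximation **without**
  continuity correction, matching the asymptotic defaults of classic
  statistical packages such as SPSS. A consequence worth knowing: for 6 vs 6 untied data the
  exact and uncorrected-asymptotic two-sided p-values can differ by up to
  0.069 (enumeration over all U values); the test suite checks observed
  discrepancies against that analytic bound.
* `amplicon_methylation_summary()`: inapplicable (missing) readings are
  excluded listwise per CpG unit, never imputed; per-sample amplicon means
  average the remaining units, group means average the sample means, and
  per-CpG-unit group comparisons use the pooled t-test.

# The synthetic-data generator

The generator emulates the study design the package targets: 4 case + 4
control samples, three libraries per sample, fragments uniform in
100–400 bp (sonication < 500 bp), genome-wide background coverage,
shared-enriched regions present in both groups, and spiked differential
regions with a configurable between-group fold (default 4, i.e. clearly
above the 2-fold calling threshold).

Tags are drawn from a categorical mixture: with regions $r$ of length
$L_r$ and density multiplier $f_r$ over background, a fragment midpoint
falls in region $r$ with probability $L_r f_r / T$,
$T = G + \sum_r L_r (f_r - 1)$, and is otherwise uniform on the rest of the
genome. Background is uniform per chromosome — the simplest null for which
the Poisson window caller is exactly calibrated — and enrichment is a
per-region multiplier rather than a per-base rate field so every expected
count has closed form (`expected_region_count()`), enabling χ²
goodness-of-fit tests of the generator itself. Input libraries draw
background only. For a differential region with fold $\phi$, the favored
group's IP multiplier is $e\sqrt{\phi}$ and the other group's
$e/\sqrt{\phi}$ ($e$ = `enrichment_fold`, default 8): the symmetric split
keeps both groups enriched over background (so the region is discovered as
a peak in both) while making the between-group density ratio exactly
$\phi$. Truth regions never overlap and, when gene models exist,
differential regions alternate between promoter-anchored and
body-anchored placements so annotation summaries have guaranteed hits.

Two seeds govern reproducibility: the config seed fixes genome layout,
gene models and truth regions; a per-library replicate seed fixes each
library. Identical seed pairs give byte-identical libraries.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: CpG-density-dependent antibody efficiency,
GC/mappability bias, duplicate reads, copy-number variation,
overdispersion beyond multinomial sampling, and correlated biological
replicate structure. Recovery rates on this simulator are an upper bound
on real-data performance; the calibration results (null window discovery
rate, null differential call rate) are exact statements only under the
uniform-background model.

# Defaults, problem sizes and numerical choices

| Parameter | Default | Why |
|---|---|---|
| window, step, merge gap | 200 / 50 / 100 bp | fragment-scale windows |
| peak thresholds | $p<10^{-5}$, FDR $<0.01$ | the analysis contract |
| fold filter, alpha | 2-fold, 0.05 | DMR/DHMR definition |
| pseudo-density ε | 0.5 RPKM | fold-change guard only |
| promoter | TSS ± 2 kb | promoter definition |
| metagene bins | 100 body + 2×20 flank | 1 % resolution, 20 % flanks |
| TSS window | ±5 kb, 100 bp bins | promoter-scale profile |
| synthetic genome | 2 × 5 Mb | smallest genome at which windows ≫ regions |
| tags per library | 2 × 10⁵ | per-library depth is a free parameter of the design (totals, not per-library depths, are what such studies report); this value gives ~4 expected background tags per window, enough for the spiked folds to be unambiguous |
| spiked regions | 30 shared + 20 differential, fold 4 | default recovery scenario |

Property suites run at sizes chosen for tight feedback loops: the χ²
mixture-calibration property uses 100 seeds at 5 000 tags on a 200 kb
genome; the null window-calibration check 50 seeds at 20 000 tags on
200 kb; the Mann–Whitney agreement property 200 seeds at 6 vs 6. The
deterministic seeds used in fixtures are arbitrary fixed constants.

Numerical details: Poisson tails come from `ppois(k − 1, λ, lower = FALSE)`
(upper tail includes the observed count); BH adjustment from `p.adjust`;
merging from `GenomicRanges::reduce` with `min.gapwidth = merge_gap + 1`;
fold changes computed on group means, direction ties (`log2 FC = 0`)
reported as `up-in-case` but never called (the fold filter excludes them);
peak scores are $-\log_{10} p$ capped at 1000 to keep BED scores finite.
Fragments whose sampled length would leave the chromosome are shifted
inward, preserving length; at default settings this affects a vanishing
fraction of tags and slightly depletes coverage only at chromosome ends.

# Known limitations

* The peak caller is intentionally simpler than MACS; peak boundaries on
  real data will differ from MACS output even at identical thresholds.
* Uncorrected per-region p-values inflate the false-positive rate when the
  candidate universe is large; the fold filter mitigates but does not fix
  this.
* Midpoint counting under-counts regions shorter than half a fragment.
* Collapsed gene models; no nearest-gene assignment for intergenic
  regions.
* The clinical-table comparison cannot decide per row which of the two
  admissible tests produced a printed p-value; it defaults to pooled t and
  exposes overrides.
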