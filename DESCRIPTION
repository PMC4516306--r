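Package: medipdiff
Title: Differential Methylation and Hydroxymethylation Analysis for MeDIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for differential 5-methylcytosine (5mC) and
    5-hydroxymethylcytosine (5hmC) analysis from (hydroxy)methylated DNA
    immunoprecipitation sequencing ((h)MeDIP-seq) tag libraries. Covers
    sliding-window Poisson peak calling of IP libraries against input,
    RPKM-normalized density matrices over consensus candidate regions,
    two-group differential region (DMR/DHMR) calling with a fold-change and
    Student's t-test filter, promoter/gene-body annotation, metagene and TSS
    coverage profiles, and the validation arithmetic used in small two-group
    studies (comparative-CT qPCR enrichment, per-CpG amplicon methylation
    summaries, pooled t and exact Mann-Whitney tests). Includes a seeded
    synthetic-data generator with spike-in truth regions so every stage can be
    exercised and calibrated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
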