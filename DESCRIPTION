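Package: varbench
Title: Haplotype-Aware Benchmarking of Variant Call Sets Against a
    High-Confidence Truth Set
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares diploid variant call sets (VCF) against a
    high-confidence benchmark call set restricted to high-confidence
    regions (BED), using representation normalization and exhaustive
    haplotype-aware matching of complex variants. Classifies calls into
    true positives, false negative variants (FNVs) and questionable
    variants (QVs); stratifies sensitivity with Wilson 95% binomial
    confidence intervals by functional class and gene set; attributes
    false-negative causes (filtering, low coverage, GC content, repeat
    context); detects platform-systematic error sites at homozygous
    reference positions and intersects them allele-aware with variant
    databases; and characterizes confidence regions against gene models,
    repeat tracks and k-mer uniqueness / mismatch-tolerant alignability
    tracks. Includes a seeded synthetic-data generator that emulates the
    structure of real benchmarking inputs with full ground-truth
    bookkeeping for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
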