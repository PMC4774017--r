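---
title: "Benchmarking small-variant call sets against a high-confidence truth set"
author: "varbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking small-variant call sets against a high-confidence truth set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varbench)
```

## The problem

Clinical interpretation of exome and genome sequencing depends on knowing
where, and for which classes of variation, a sequencing-plus-calling
pipeline can be trusted. Benchmark materials such as the Genome in a
Bottle consensus genotypes for NA12878 make this measurable: within
*high-confidence regions* the benchmark asserts every genotype (variant
or homozygous reference), so a query call set can be scored against it.
varbench implements that style of analysis as a reusable, tested
pipeline:

* haplotype-aware comparison of a query VCF against a truth VCF within
  high-confidence regions, yielding true positives (TP), false negative
  variants (FNVs) and *questionable variants* (QVs — extra calls that are
  often boundary artifacts or genotype errors rather than clean false
  positives);
* sensitivity stratified by functional class (non-synonymous,
  synonymous, truncating, splicing) and gene set, with Wilson 95%
  binomial confidence intervals;
* attribution of FNV causes (removed by filtering, low read depth, high
  GC context, repeat context);
* characterization of the high-confidence regions themselves against
  gene models, repeat tracks, and k-mer uniqueness / alignability;
* detection of platform-systematic error sites at homozygous-reference
  positions, intersected allele-aware with variant databases.

The real inputs of such a study (GIAB calls, hg19, ClinVar, dbSNP,
RepeatMasker, UCSC mappability tracks) are large and external. varbench
therefore ships a seeded synthetic-data generator that emulates their
*structure* at desk scale, with complete ground-truth bookkeeping, so the
whole pipeline is exercisable and testable end to end.

## Comparison model

### Representation normalization

The same sequence edit can be written many ways in a VCF (shifted
indels, MNVs vs component SNVs, padded alleles). `normalize_variant()`
canonicalizes each record: shared trailing then leading bases are
trimmed (keeping at least one base per allele), and indels are
left-aligned — shifted to the lowest 1-based position at which the
representation is irreducible. Multi-allelic records are split into
per-alt records with genotypes projected onto each allele. The test
suite checks the canonical form against an exhaustive oracle that
enumerates every equivalent `(pos, ref, alt)` triple by sequence
equality and takes the leftmost minimal one.

### Haplotype-aware matching

Exact matching on `(chrom, pos, ref, alt)` after normalization resolves
most records. The remainder — different representations of complex,
nearby variation — are clustered (variants within 50 bp are chained) and
compared at the haplotype-sequence level: every assignment of
heterozygous records to the two haplotypes is enumerated (2^h, capped at
h = 12 per side), each consistent assignment is reconstructed into an
unordered pair of window sequences, and two clusters match iff they
share a reconstructable pair. This makes the classification invariant to
representation: a phased SNV pair and its MNV rewrite score identically,
which the generator plants deliberately and the tests assert.

### Classification contract

Every truth record inside the high-confidence regions is `TP` or `FNV`;
every passing query record inside them is `TP` or `QV`; records outside
are `OUTSIDE` and excluded from metrics. Two partition identities are
asserted on every run: `truth_in_region = TP + FNV` and
`query_in_region = TP + QV`. Non-PASS query records are excluded from
matching but retained as `FILTERED` — they are exactly the "called but
removed by filtering" class that dominates FNV etiology for aggressively
filtered pipelines, and they feed both FN-cause attribution and the
filter-specificity table.

Two policies are deliberate choices rather than consequences of the
model, and both are configurable:

* **Genotype-discordant allele matches** (right allele, wrong zygosity)
  count as TP for sensitivity but are flagged and reported in a separate
  genotype-diagnostic table. This mirrors the observation that many
  exome QVs are correctly identified as non-reference with an incorrect
  genotype. `genotype_strict = TRUE` instead scores them FNV + QV.
* **Half-calls** (`./1`) are treated as heterozygous for matching and
  flagged; the benchmark literature is silent on them and this is the
  conservative reading.

* **Edge flags**: "within 50 bp of the inside edge" is implemented as
  the inclusive test `edge_distance <= 49`, where a variant on the first
  or last base of a region has distance 0. The width is the `edge_bp`
  parameter.

## Stratified sensitivity

`classify_function()` is a deliberately small transcript-aware
classifier (the full multi-database annotation machinery of production
annotators is out of scope): an SNV within 2 bp of an internal exon
boundary on the intron side is `splicing`; a coding SNV is translated on
its codon (reverse-complemented for minus-strand genes) and scored
`truncating` (stop-gain), `synonymous` or `non-synonymous`; a frameshift
indel in the CDS is `truncating`; everything else — UTR, deep intron,
in-frame indels, stop-loss mapped to non-synonymous — falls where the
four-class scheme puts it. When a gene has several transcripts the
longest CDS is used, so stratification is deterministic. The tests
validate the codon logic against whole-CDS translation with Biostrings
on random synthetic genes of both strands.

Sensitivity per (class × gene set) cell is `TP / (TP + FNV)` over truth
variants in high-confidence regions, with a Wilson score interval
(no continuity correction). The Wilson choice is load-bearing: with
x = n successes its lower bound has the closed form `n / (n + z²)`,
which reproduces the printed bounds of fully-detected strata (for
example `binomial_ci(7, 7)` gives a lower bound of 0.646 and
`binomial_ci(43, 47)` gives (0.801, 0.966)). `stats::prop.test(correct
= FALSE)` serves as an independent cross-check in the tests, never as
the implementation.

### FN causes and filter specificity

Causes are assigned non-exclusively per FNV: `filtered` if a matching
raw call with a non-empty filter set exists; `low_coverage` if site
depth < 10 (the hard read-coverage rule); `high_gc` if reference GC
fraction exceeds 0.75 in a 100 bp window centered on the site (the
threshold is the published rule; the window width is this package's
choice at read-length scale, configurable via `gc_window`); one
`repeat_<class>` flag per repeat track containing the site;
`unexplained` otherwise. `filter_specificity()` tabulates, for every
filter-label combination, how often the filtered allele is absent from
truth (a likely false positive) versus present (a wrongly filtered true
variant), plus aggregate single-filter/multi-filter rows.

## Region characterization

Interval arithmetic is base-set semantics over 0-based half-open
regions (IRanges underneath, with abutting intervals merged, because
the analysis reasons in covered bases). Per-gene coverage merges exons
across transcripts before intersecting with the high-confidence
regions; per-set summaries are *base-weighted* (covered exonic bases
over total exonic bases), which is the natural reading of "proportion
of exonic bases", with the gene-averaged mean also emitted for
comparison. Exon-position coverage uses strand-aware ordinal classes
with precedence first > last > second > penultimate > middle, so genes
with fewer than five exons still partition deterministically (a 2-exon
gene is first + last). Low-confidence bases are attributed to the first
reason track containing them, in a caller-supplied precedence order, so
overlapping annotations never double-count.

## Uniqueness and alignability

`exact_uniqueness(reference, k = 35)` flags positions whose k-mer
occurs at exactly one forward-strand start position genome-wide;
k-mers containing N are never unique, since undefined sequence cannot
certify uniqueness. Forward-strand counting matches the construction of
the classic browser tracks (the reference is broken into fragments and
realigned); `both_strands = TRUE` exposes the stricter
reverse-complement-aware variant. `alignability(reference, k = 100,
max_mismatch = 2)` flags positions with no second location within
Hamming distance 2, gapless; candidate pairs are found by the
pigeonhole principle (two k-mers within distance m share one of m+1
chunks), so only colliding chunk groups are verified and the scan stays
far below the quadratic worst case on realistic sequence. With
`max_mismatch = 0` it equals exact uniqueness, and both tracks are
tested against full all-pairs Hamming scans on small genomes.
`variant_context()` reports, per variant set and optional subset label,
the percentage in high-confidence regions and the percentage starting a
unique/alignable sequence, at two decimals.

## Systematic-error sites

A site is a systematic-error candidate when the benchmark asserts
homozygous reference but a platform's datasets repeatedly call a
variant there: evidence is any call whose genotype contains a
non-reference allele with quality above 2 (a deliberately permissive
threshold, to be comprehensive), and a platform flags the site when
*all* of its datasets have evidence or *more than two* do. For
platforms with exactly three datasets the two rules coincide; a
single-dataset platform trivially satisfies "all", which is the rule as
written. Calls are normalized first so shifted homopolymer-indel
representations land on one position, and database intersection is
allele-aware: a database record with only a different alternative
allele is not a hit. Per-database counts and a deduplicated
any-database total are reported.

## The synthetic-data generator

`generate_bundle(sim_config(...))` builds everything from one seeded
stream: a uniform-random diploid reference with planted homopolymers
(12–30 bp, all beyond the 10 bp "long homopolymer" rule), tandem
repeats, mismatched duplicated blocks and GC-rich windows; genes with
valid ORFs (start codon, clean internal codons, stop) written into the
sequence on both strands; per-stratum truth variants planted by direct
codon editing (synonymous/non-synonymous/stop-gain via the genetic
code, frameshift indels, splice-site SNVs, intergenic SNVs and
indels); and a query derived from the truth by independent per-variant
error draws. The high-confidence BED excludes every planted difficult
feature with a 10 bp margin, plus masked exon stretches, and the
low-confidence bases are partitioned into reason tracks with exact
planned fractions (47/34/15/4% by default, mirroring the relative
ordering seen in real low-confidence attributions: structural-variant
overlap dominating, then short tandem repeats, then segmental
duplications).

Default study conditions: 2 chromosomes × 500 kb, 60 genes, ~2,900
truth variants (400 non-synonymous, 400 synonymous, 47 truncating, 60
splicing, ~2,000 intergenic), per-stratum detection probabilities
0.90–0.97, 87% of misses "called but filtered" and the rest absent at
depth < 10, a 2% genotype-error rate, 15 phased SNV pairs rewritten as
MNVs in the query, planted passing and filtered false calls, three
platforms with 4/3/2 datasets, 25 systematic-error sites plus
sub-threshold noise sites, and two databases overlapping the systematic
sites at 40% and 12%. These defaults are the conditions under which the
acceptance script reports its numbers; the test suite uses a scaled-down
single-chromosome configuration (150 kb, 8 genes, ~260 variants) so the
whole suite stays fast, and the statistical-recovery test runs 20 such
seeds.

Each planted variant's fate (kept, filtered miss with labels,
low-coverage miss), genotype error, MNV pairing, per-base
high-confidence membership, per-gene covered-base counts, reason
partition and systematic-site list are recorded in bookkeeping tables
computed by direct per-base indexing during construction — independent
of the pipeline's interval and matching code — and
`expected_metrics()` turns them into oracle tables that the tests
compare against pipeline output exactly.

What the generator does *not* emulate: linkage structure and realistic
allele frequencies, read-level error physics, alignment artifacts,
coverage autocorrelation, overlapping genes and alternative isoform
complexity. Passing tests therefore demonstrate that the pipeline's
logic is correct under the stated error model, not that any particular
real pipeline achieves these sensitivities.

## Numerical and design choices

* Coordinates: regions are 0-based half-open (BED convention); variant
  positions are 1-based (VCF convention); conversion happens at one
  boundary. Chromosome names are compared verbatim — no "chr" aliasing.
* Symbolic/breakend ALT alleles are rejected with a clear error;
  structural variants are outside the benchmark scope.
* Clustering window and haplotype cap: 50 bp chaining with h ≤ 12
  heterozygous records per side bounds the 2^h enumeration; clusters
  exceeding the cap fail closed (no match) with a diagnostic.
* Ties in the systematic-error majority alt go to the lexicographically
  smallest allele, with all observed alts reported alongside.
* All report writers fix column order and numeric formatting
  (sensitivities 3 decimals, percentages 2), so identical inputs yield
  byte-identical outputs; the generator is byte-deterministic under a
  fixed seed.

## Worked example

```{r example, eval = FALSE}
library(varbench)
bundle <- generate_bundle(sim_config(seed = 1))
dir <- tempfile(); write_bundle(bundle, dir)
report <- run_report(list(dir = dir, out_dir = file.path(dir, "out")))
report$summary
```

The summary lists the truth/query partition (TP, FNV, QV), the
whole-genome sensitivity with its Wilson interval in the Table-1-style
TSV, and the systematic-site counts; `expected_metrics(bundle)` gives
the bookkeeping-oracle versions of the same tables for comparison.

## Known limitations

* Ploidy is fixed at 2; somatic fractions, phasing output and
  structural-variant matching are out of scope.
* The haplotype matcher is exhaustive rather than graph-based; extremely
  dense clusters (> 12 heterozygous records in 50 bp) are not matched.
* Track computation is in-memory and aimed at desk-scale genomes
  (tens of megabases for exact uniqueness), not full human genomes.
* One transcript per gene is used for classification; transcript-model
  discordance analysis is intentionally not implemented.
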