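two_gene_models <- function() {
  g <- data.frame(gene = c("GA", "GB"), transcript_id = c("T1", "T2"),
                  chrom = "chr1", strand = "+",
                  cds_start = c(110L, 1010L), cds_end = c(190L, 1090L),
                  stringsAsFactors = FALSE)
  g$exon_start <- list(100L, 1000L)
  g$exon_end <- list(200L, 1100L)
  g
}

test_that("gene coverage is base-weighted with full/partial gene counts", {
  gm <- two_gene_models()
  sets <- list(SetA = c("GA", "GB"))
  # GA fully covered; GB half covered; equal exonic lengths -> 0.75
  hiconf <- regions(c("chr1", "chr1"), c(0, 1000), c(500, 1050))
  out <- gene_coverage(gm, sets, hiconf)
  expect_equal(out$genes$fraction[out$genes$gene == "GA"], 1.0)
  expect_equal(out$genes$fraction[out$genes$gene == "GB"], 0.5)
  expect_equal(out$sets$fraction_base_weighted, 0.75)
  expect_equal(out$sets$n_fully_covered, 1L)
  expect_equal(out$sets$n_below_half, 0L)
  # base-weighted summary equals sum(covered)/sum(exonic) exactly
  expect_equal(out$sets$fraction_base_weighted,
               sum(out$genes$covered_bases) / sum(out$genes$exonic_bases))
})

test_that("exons merge across transcripts before coverage", {
  gm <- two_gene_models()[c(1, 1), ]
  gm$transcript_id <- c("T1", "T1b")
  gm$exon_start <- list(100L, 150L)
  gm$exon_end <- list(200L, 260L)
  out <- gene_coverage(gm, list(S = "GA"), regions("chr1", 0, 5000))
  expect_equal(out$genes$exonic_bases, 160L)  # merged 100..260
})

test_that("exon classes partition every gene strand-aware", {
  expect_equal(exon_classes(6, "+"),
               c("first", "second", "middle", "middle", "penultimate",
                 "last"))
  expect_equal(exon_classes(2, "+"), c("first", "last"))
  expect_equal(exon_classes(1, "+"), "first")
  expect_equal(exon_classes(3, "-"), c("last", "second", "first"))
  expect_equal(exon_classes(4, "+"),
               c("first", "second", "penultimate", "last"))
  for (n in 1:8) {
    for (s in c("+", "-")) expect_length(exon_classes(n, s), n)
  }
})

test_that("exon position coverage distinguishes covered classes", {
  g <- data.frame(gene = "GX", transcript_id = "T", chrom = "chr1",
                  strand = "+", cds_start = 10L, cds_end = 580L,
                  stringsAsFactors = FALSE)
  g$exon_start <- list(c(0L, 200L, 400L))
  g$exon_end <- list(c(100L, 300L, 500L))
  # exclude the first exon entirely
  hic <- regions("chr1", 100, 1000)
  out <- exon_position_coverage(g, hic)
  cl <- out$classes
  expect_equal(cl$fraction_mean[cl$exon_class == "first"], 0)
  expect_equal(cl$fraction_mean[cl$exon_class == "second"], 1)
  expect_equal(cl$fraction_mean[cl$exon_class == "last"], 1)
})

test_that("repeat fractions match a per-base oracle on random tracks", {
  set.seed(51)
  hic <- random_region_df(60)
  tracks <- list(a = random_region_df(40), b = random_region_df(40))
  out <- repeat_fraction_in_hiconf(tracks, hic)
  for (cls in names(tracks)) {
    ptrack <- oracle_positions(tracks[[cls]])
    phic <- oracle_positions(hic)
    n_in <- sum(lengths(oracle_binop(tracks[[cls]], hic, intersect)))
    expect_equal(out$fraction[out$repeat_class == cls],
                 n_in / sum(lengths(ptrack)))
  }
  expect_true(is.na(
    repeat_fraction_in_hiconf(list(e = normalize_regions(NULL)),
                              hic)$fraction))
})

test_that("low-confidence reasons attribute by precedence without double counting", {
  low <- regions("chr1", 0, 100)
  tracks <- list(first = regions("chr1", 0, 60),
                 second = regions("chr1", 40, 90))  # overlaps 'first'
  out <- lowconf_reasons(low, tracks)
  expect_equal(out$bases[out$reason == "first"], 60L)
  expect_equal(out$bases[out$reason == "second"], 30L)  # 60..90 only
  expect_equal(out$bases[out$reason == "unattributed"], 10L)
  expect_equal(sum(out$percent), 100)
  # single track covering everything -> 100%
  out2 <- lowconf_reasons(low, list(all = regions("chr1", 0, 100)))
  expect_equal(out2$percent[out2$reason == "all"], 100)
})

test_that("planted low-confidence reason percentages are recovered", {
  b <- shared_bundle()
  chrom_spans <- regions(names(b$reference), 0, nchar(b$reference))
  lc <- lowconf_reasons(region_subtract(chrom_spans, b$hiconf),
                        b$reason_tracks)
  exp <- expected_metrics(b)$lowconf_reasons
  got <- lc[match(exp$reason, lc$reason), ]
  expect_equal(got$bases, exp$bases)
  expect_equal(got$percent, exp$percent)
  expect_equal(lc$bases[lc$reason == "unattributed"], 0L)
})

test_that("planted gene coverage fractions are recovered from bookkeeping", {
  b <- shared_bundle()
  out <- gene_coverage(b$gene_models, b$gene_sets, b$hiconf)
  exp <- expected_metrics(b)
  expect_equal(out$genes$gene, exp$gene_coverage$gene)
  expect_equal(out$genes$exonic_bases, exp$gene_coverage$exonic_bases)
  expect_equal(out$genes$covered_bases, exp$gene_coverage$covered_bases)
  setc <- merge(out$sets, exp$set_coverage, by = "gene_set")
  expect_equal(setc$fraction_base_weighted.x,
               setc$fraction_base_weighted.y)
  expect_equal(setc$n_fully_covered.x, setc$n_fully_covered.y)
  expect_equal(setc$n_below_half.x, setc$n_below_half.y)
})
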