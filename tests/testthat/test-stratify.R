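make_gene <- function(chrom = "chr1", strand = "+",
                      exon_start = c(100L, 400L),
                      exon_end = c(250L, 550L),
                      cds_start = 130L, cds_end = 520L) {
  g <- data.frame(gene = "G1", transcript_id = "T1", chrom = chrom,
                  strand = strand, cds_start = cds_start,
                  cds_end = cds_end, stringsAsFactors = FALSE)
  g$exon_start <- list(exon_start)
  g$exon_end <- list(exon_end)
  g
}

# reference whose CDS is a clean ORF for the gene above
orf_reference <- function(gene, seed = 1) {
  set.seed(seed)
  L <- max(gene$exon_end[[1]]) + 200L
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cdsp <- varbench:::cds_positions(gene)
  n_codon <- length(cdsp) %/% 3L
  codons <- names(Biostrings::GENETIC_CODE)
  sense_pool <- setdiff(codons, c("TAA", "TAG", "TGA"))
  sense <- paste0("ATG",
                  paste(sample(sense_pool, n_codon - 2L, replace = TRUE),
                        collapse = ""), "TAA")
  bases <- strsplit(sense, "")[[1]]
  if (gene$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  chars[cdsp + 1L] <- bases
  out <- paste(chars, collapse = "")
  names(out) <- gene$chrom
  out
}

test_that("coding SNVs classify by codon effect on both strands", {
  g <- make_gene()
  ref <- orf_reference(g)
  cdsp <- varbench:::cds_positions(g)
  seq <- ref[[1]]
  # third base of codon 2: force a synonymous Leu change CTG->CTA style
  # instead of hand-picking, scan for known cases via the genetic code
  found <- c(synonymous = FALSE, `non-synonymous` = FALSE,
             truncating = FALSE)
  for (ci in 2:((length(cdsp) %/% 3L) - 1L)) {
    cpos <- cdsp[(3 * ci - 2):(3 * ci)]
    codon <- paste(substring(seq, cpos + 1L, cpos + 1L), collapse = "")
    if (g$strand == "-") codon <- chartr("ACGT", "TGCA", codon)
    for (j in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(codon, j, j))) {
        mut <- codon; substr(mut, j, j) <- b
        aa0 <- Biostrings::GENETIC_CODE[[codon]]
        aa1 <- Biostrings::GENETIC_CODE[[mut]]
        want <- if (aa1 == "*") "truncating"
                else if (aa1 == aa0) "synonymous" else "non-synonymous"
        if (found[[want]]) next
        gpos <- cpos[j]
        alt <- if (g$strand == "-") chartr("ACGT", "TGCA", b) else b
        got <- classify_function(gpos + 1L,
                                 substr(seq, gpos + 1L, gpos + 1L),
                                 alt, g, ref)
        expect_equal(got, want)
        found[[want]] <- TRUE
      }
    }
    if (all(found)) break
  }
  expect_true(all(found))
})

test_that("splicing, UTR, intronic and frameshift rules apply", {
  g <- make_gene()
  ref <- orf_reference(g)
  seq <- ref[[1]]
  snv_at <- function(pos0) {
    b <- substr(seq, pos0 + 1L, pos0 + 1L)
    classify_function(pos0 + 1L, b,
                      setdiff(c("A", "C", "G", "T"), b)[1], g, ref)
  }
  expect_equal(snv_at(250L), "splicing")  # intron base +1 after exon 1
  expect_equal(snv_at(251L), "splicing")  # +2
  expect_equal(snv_at(252L), "other")     # +3: deep intronic
  expect_equal(snv_at(399L), "splicing")  # -1 before exon 2
  expect_equal(snv_at(110L), "other")     # 5' UTR exon base
  # frameshift vs in-frame deletion inside the CDS
  del <- function(width) {
    p <- 160L
    refal <- substr(seq, p, p + width)
    classify_function(p, refal, substr(refal, 1, 1), g, ref)
  }
  expect_equal(del(1L), "truncating")
  expect_equal(del(2L), "truncating")
  expect_equal(del(3L), "other")  # in-frame
  expect_error(classify_function(5L, substr(seq, 5, 5), "A", g, ref),
               "outside gene")
})

test_that("classifier agrees with a whole-CDS translation oracle", {
  set.seed(21)
  n_checked <- 0L
  for (rep in 1:6) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:4, 1)
    es <- integer(n_ex); ee <- integer(n_ex)
    cursor <- 100L
    for (j in seq_len(n_ex)) {
      es[j] <- cursor
      ee[j] <- cursor + sample(seq(90L, 180L, by = 3L), 1)
      cursor <- ee[j] + sample(100:200, 1)
    }
    g <- make_gene(strand = strand, exon_start = es, exon_end = ee,
                   cds_start = es[1] + 30L, cds_end = ee[n_ex] - 30L)
    # make the CDS length a multiple of 3
    cdsp <- varbench:::cds_positions(g)
    drop <- length(cdsp) %% 3L
    g$cds_end <- g$cds_end - if (strand == "+") drop else 0L
    g$cds_start <- g$cds_start + if (strand == "-") drop else 0L
    ref <- orf_reference(g, seed = 100 + rep)
    seq <- ref[[1]]
    cdsp <- varbench:::cds_positions(g)
    translate_cds <- function(sq) {
      bases <- substring(sq, cdsp + 1L, cdsp + 1L)
      if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
      as.character(Biostrings::translate(
        Biostrings::DNAString(paste(bases, collapse = "")),
        if.fuzzy.codon = "X"))
    }
    aa_ref <- translate_cds(seq)
    for (i in 1:40) {
      p0 <- sample(cdsp[4:(length(cdsp) - 3L)], 1)
      b <- substr(seq, p0 + 1L, p0 + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
      mutated <- seq
      substr(mutated, p0 + 1L, p0 + 1L) <- alt
      aa_alt <- translate_cds(mutated)
      diff_pos <- which(strsplit(aa_ref, "")[[1]] !=
                          strsplit(aa_alt, "")[[1]])
      want <- if (length(diff_pos) == 0) "synonymous"
              else if (substr(aa_alt, diff_pos[1], diff_pos[1]) == "*")
                "truncating" else "non-synonymous"
      got <- classify_function(p0 + 1L, b, alt, g, ref)
      expect_equal(got, want,
                   info = sprintf("strand=%s pos0=%d %s>%s", strand,
                                  p0, b, alt))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("Wilson interval matches closed forms and prop.test", {
  ci <- binomial_ci(43, 47)
  expect_equal(round(ci$low, 3), 0.801)
  expect_equal(round(ci$high, 3), 0.966)
  expect_equal(round(binomial_ci(7, 7)$low, 3), 0.646)
  expect_equal(round(binomial_ci(47, 47)$low, 3), 0.924)
  z <- qnorm(0.975)
  expect_equal(binomial_ci(0, 10)$low, 0)
  expect_equal(binomial_ci(0, 10)$high, z^2 / (10 + z^2))
  expect_equal(binomial_ci(7, 7)$low, 7 / (7 + z^2))
  # cross-check against the independent stats implementation
  for (xn in list(c(3, 10), c(43, 47), c(25, 50), c(199, 200))) {
    pt <- prop.test(xn[1], xn[2], correct = FALSE)$conf.int
    ci <- binomial_ci(xn[1], xn[2])
    expect_equal(c(ci$low, ci$high), as.numeric(pt), tolerance = 1e-10)
  }
  expect_error(binomial_ci(1, 0), "n >= 1")
  expect_error(binomial_ci(5, 3), "0 <= x <= n")
})

test_that("Wilson interval has nominal coverage on simulated draws", {
  set.seed(31)
  n <- 50L; p <- 0.7
  x <- rbinom(2000, n, p)
  ci <- binomial_ci(x, n)
  cover <- mean(ci$low <= p & p <= ci$high)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("stratified sensitivity reproduces bookkeeping counts per stratum", {
  b <- shared_bundle()
  m <- shared_match()
  got <- stratified_sensitivity(m, b$gene_models, b$gene_sets,
                                b$reference)
  exp <- expected_metrics(b)$strata
  cmp <- merge(got, exp, by = c("fn_class", "gene_set"),
               suffixes = c("_got", "_exp"))
  expect_equal(nrow(cmp), nrow(exp))
  expect_equal(cmp$tp_got, cmp$tp_exp)
  expect_equal(cmp$fn_got, cmp$fn_exp)
  # CI columns honour the invariant low <= sensitivity <= high
  ok <- !is.na(got$sensitivity)
  expect_true(all(got$ci_low[ok] <= got$sensitivity[ok] + 1e-12))
  expect_true(all(got$sensitivity[ok] <= got$ci_high[ok] + 1e-12))
  # a fully-detected stratum carries the closed-form lower bound
  full <- got[!is.na(got$sensitivity) & got$sensitivity == 1 &
                got$tp > 0, ]
  if (nrow(full)) {
    z <- qnorm(0.975)
    expect_equal(full$ci_low, full$tp / (full$tp + z^2))
  }
})

test_that("FN causes follow the depth, filter, GC and repeat rules", {
  b <- shared_bundle()
  m <- shared_match()
  fc <- attribute_fn_causes(m, depth_source = b$depth_track,
                            repeat_tracks = b$repeat_tracks["sine"],
                            reference = b$reference)
  exp <- expected_metrics(b)$fn_causes
  expect_equal(unname(fc$summary["filtered"]), unname(exp["filtered"]))
  expect_equal(unname(fc$summary["low_coverage"]),
               unname(exp["low_coverage"]))
  expect_equal(unname(fc$summary["high_gc"]), unname(exp["high_gc"]))
  expect_equal(unname(fc$summary["repeat_sine"]),
               unname(exp["repeat_sine"]))
  # rule edges: depth 9 is low coverage, depth 10 is not
  expect_true(all(fc$causes$low_coverage == (fc$causes$depth < 10)))
  # filtered flag iff labels present
  expect_equal(fc$causes$filtered, nzchar(fc$causes$filter_labels))
})

test_that("a 100 bp window with 80% G/C bases triggers the GC cause", {
  set.seed(41)
  at <- c(rep(c("G", "C"), 40), sample(c("A", "T"), 20, replace = TRUE))
  chars <- c(sample(c("A", "T"), 200, replace = TRUE), sample(at),
             sample(c("A", "T"), 200, replace = TRUE))
  ref <- c(chr1 = paste(chars, collapse = ""))
  pos <- 250L
  bse <- substr(ref, pos, pos)
  truth <- call_set(data.frame(chrom = "chr1", pos = pos, ref = bse,
                               alt = setdiff(c("A", "C", "G", "T"),
                                             bse)[1],
                               gt1 = 0L, gt2 = 1L,
                               stringsAsFactors = FALSE))
  m <- classify_calls(call_set(NULL), truth, regions("chr1", 0, 500),
                      ref)
  fc <- attribute_fn_causes(m, reference = ref)
  expect_true(fc$causes$high_gc[1])
})

test_that("filter specificity recovers the planted false-call fraction", {
  b <- shared_bundle()
  m <- shared_match()
  fs <- filter_specificity(m)
  exp <- expected_metrics(b)
  all_row <- fs[fs$filter_combo == "<all filtered>", ]
  expect_equal(all_row$fraction_fp, exp$filtered_fp_fraction)
  # a fully-false-planted combination reports fraction 1.0, and an
  # unfiltered call set reports an empty table
  m0 <- classify_calls(b$truth, b$truth, b$hiconf, b$reference)
  expect_equal(nrow(filter_specificity(m0)), 0L)
  single <- fs[fs$filter_combo == "<any single>", ]
  multi <- fs[fs$filter_combo == "<multiple>", ]
  expect_equal(single$n_sites + multi$n_sites, all_row$n_sites)
})
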