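test_that("normalize_variant trims and left-aligns per the exhaustive oracle", {
  # worked deletion in a homopolymer context
  expect_equal(normalize_variant(4, "AA", "A", "GCAAAT"),
               list(pos = 2L, ref = "CA", alt = "C"))
  # SNV is unchanged
  expect_equal(normalize_variant(3, "A", "G", "GCAAAT"),
               list(pos = 3L, ref = "A", alt = "G"))
  # shared-prefix/suffix trimming of an MNV-like record
  seq <- paste0(random_dna_string(9), "ATGCC")
  expect_equal(normalize_variant(10, "ATG", "ATC", seq),
               list(pos = 12L, ref = "G", alt = "C"))

  set.seed(11)
  for (i in 1:120) {
    seq <- random_dna_string(40)
    pos <- sample(3:30, 1)
    kind <- sample(c("snv", "del", "ins", "mnv"), 1)
    if (kind == "snv") {
      ref <- substr(seq, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (kind == "del") {
      w <- sample(1:3, 1)
      ref <- substr(seq, pos, pos + w)
      alt <- substr(seq, pos, pos)
    } else if (kind == "ins") {
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, random_dna_string(sample(1:3, 1)))
    } else {
      ref <- substr(seq, pos, pos + 1)
      alt <- paste0(sample(c("A", "C", "G", "T"), 1),
                    sample(c("A", "C", "G", "T"), 1))
      if (alt == ref) next
    }
    got <- normalize_variant(pos, ref, alt, seq)
    exp <- oracle_normalize(pos, ref, alt, seq)
    expect_equal(got, list(pos = exp$pos, ref = exp$ref, alt = exp$alt),
                 info = sprintf("%s pos=%d ref=%s alt=%s seq=%s",
                                kind, pos, ref, alt, seq))
  }
})

test_that("multi-allelic records split into per-alt records with projected genotypes", {
  cs <- call_set(data.frame(chrom = "chr1", pos = 10L, ref = "A",
                            alt = "G,T", gt1 = 1L, gt2 = 2L,
                            stringsAsFactors = FALSE))
  sp <- split_multiallelic(cs)$records
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$alt, c("G", "T"))
  expect_equal(sp$gt1, c(1L, 0L))
  expect_equal(sp$gt2, c(0L, 1L))
})

test_that("haplotype matcher agrees with an exhaustive enumeration oracle", {
  set.seed(12)
  ref <- c(chr1 = random_dna_string(300))
  alts_of <- function(b) setdiff(c("A", "C", "G", "T"), b)
  for (i in 1:40) {
    n_t <- sample(1:3, 1); n_q <- sample(1:3, 1)
    mk <- function(n) {
      pos <- sort(sample(100:140, n))
      data.frame(pos = pos,
                 ref = substring(ref, pos, pos),
                 alt = vapply(pos, function(p)
                   sample(alts_of(substr(ref, p, p)), 1), character(1)),
                 gt1 = sample(0:1, n, replace = TRUE),
                 gt2 = sample(0:1, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    truth <- mk(n_t); query <- mk(n_q)
    truth <- truth[truth$gt1 + truth$gt2 > 0, , drop = FALSE]
    query <- query[query$gt1 + query$gt2 > 0, , drop = FALSE]
    w <- list(chrom = "chr1", start = 90L, end = 150L)
    got <- haplotype_match(truth, query, w, ref)$match
    exp <- oracle_haplotype_match(truth, query, w, ref)
    expect_equal(got, exp, info = paste("case", i))
  }
})

test_that("phased SNV pairs match their MNV rewrite; genotype flips do not", {
  set.seed(13)
  ref <- c(chr1 = random_dna_string(200))
  r1 <- substr(ref, 100, 100); r2 <- substr(ref, 101, 101)
  a1 <- setdiff(c("A", "C", "G", "T"), r1)[1]
  a2 <- setdiff(c("A", "C", "G", "T"), r2)[1]
  truth <- data.frame(pos = c(100L, 101L), ref = c(r1, r2),
                      alt = c(a1, a2), gt1 = 0L, gt2 = 1L,
                      stringsAsFactors = FALSE)
  mnv <- data.frame(pos = 100L, ref = paste0(r1, r2),
                    alt = paste0(a1, a2), gt1 = 0L, gt2 = 1L,
                    stringsAsFactors = FALSE)
  w <- list(chrom = "chr1", start = 80L, end = 120L)
  expect_true(haplotype_match(truth, mnv, w, ref)$match)
  expect_true(haplotype_match(truth, truth, w, ref)$match)
  hom <- mnv; hom$gt1 <- 1L
  expect_false(haplotype_match(truth, hom, w, ref)$match)
})

mini_sets <- function(ref, truth_df, query_df, hiconf) {
  list(truth = call_set(truth_df, sample_id = "S"),
       query = call_set(query_df, sample_id = "S"),
       hiconf = normalize_regions(hiconf), ref = ref)
}

test_that("classify partitions truth and query records and honours regions", {
  set.seed(14)
  ref <- c(chr1 = random_dna_string(5000))
  pos <- seq(100L, 4000L, by = 130L)
  refs <- substring(ref, pos, pos)
  alts <- vapply(refs, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  truth_df <- data.frame(chrom = "chr1", pos = pos, ref = refs,
                         alt = alts, gt1 = 0L, gt2 = 1L, phased = TRUE,
                         stringsAsFactors = FALSE)
  hiconf <- regions("chr1", 0, 3000)

  # identity: query == truth
  s <- mini_sets(ref, truth_df, truth_df, hiconf)
  m <- classify_calls(s$query, s$truth, s$hiconf, ref)
  expect_equal(m$counts$fnv, 0L)
  expect_equal(m$counts$qv, 0L)
  expect_equal(m$counts$tp_truth, sum(pos < 3000))
  expect_equal(m$counts$truth_outside, sum(pos >= 3000))

  # dropping one in-region call creates exactly one FNV
  q2 <- truth_df[-3, ]
  m2 <- classify_calls(call_set(q2, sample_id = "S"), s$truth, s$hiconf,
                       ref)
  expect_equal(m2$counts$fnv, 1L)
  expect_equal(m2$counts$tp_truth, sum(pos < 3000) - 1L)

  # one extra query call is a QV; partition identities hold
  extra <- data.frame(chrom = "chr1", pos = 550L,
                      ref = substr(ref, 550, 550),
                      alt = setdiff(c("A", "C", "G", "T"),
                                    substr(ref, 550, 550))[1],
                      gt1 = 0L, gt2 = 1L, phased = FALSE,
                      stringsAsFactors = FALSE)
  m3 <- classify_calls(call_set(rbind(truth_df, extra), sample_id = "S"),
                       s$truth, s$hiconf, ref)
  expect_equal(m3$counts$qv, 1L)
  expect_equal(m3$counts$truth_in_region,
               m3$counts$tp_truth + m3$counts$fnv)
  expect_equal(m3$counts$query_in_region,
               m3$counts$tp_query + m3$counts$qv)
})

test_that("genotype-discordant allele matches are TP-with-flag, or split under strict mode", {
  set.seed(15)
  ref <- c(chr1 = random_dna_string(500))
  b <- substr(ref, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  truth <- data.frame(chrom = "chr1", pos = 200L, ref = b, alt = alt,
                      gt1 = 0L, gt2 = 1L, stringsAsFactors = FALSE)
  query <- truth; query$gt1 <- 1L  # hom-alt instead of het
  hc <- regions("chr1", 0, 500)
  m <- classify_calls(call_set(query), call_set(truth), hc, ref)
  expect_equal(m$counts$tp_truth, 1L)
  expect_equal(m$counts$qv, 0L)
  expect_equal(nrow(m$qv_genotype), 1L)
  ms <- classify_calls(call_set(query), call_set(truth), hc, ref,
                       genotype_strict = TRUE)
  expect_equal(ms$counts$fnv, 1L)
  expect_equal(ms$counts$qv, 1L)
})

test_that("filtered query records are excluded from matching but retained", {
  set.seed(16)
  ref <- c(chr1 = random_dna_string(500))
  b <- substr(ref, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  truth <- data.frame(chrom = "chr1", pos = 200L, ref = b, alt = alt,
                      gt1 = 0L, gt2 = 1L, stringsAsFactors = FALSE)
  query <- truth; query$filters <- "strandBias"
  hc <- regions("chr1", 0, 500)
  m <- classify_calls(call_set(query), call_set(truth), hc, ref)
  expect_equal(m$counts$fnv, 1L)  # called but removed by filtering
  expect_equal(m$counts$query_filtered, 1L)
  expect_equal(m$counts$qv, 0L)
  filt <- m$calls[m$calls$role == "query", ]
  expect_equal(filt$class, "FILTERED")
})

test_that("edge flags mark variants within 50 bp of the inside edge", {
  set.seed(17)
  ref <- c(chr1 = random_dna_string(1000))
  mk <- function(p) data.frame(chrom = "chr1", pos = p,
                               ref = substr(ref, p, p),
                               alt = setdiff(c("A", "C", "G", "T"),
                                             substr(ref, p, p))[1],
                               gt1 = 0L, gt2 = 1L,
                               stringsAsFactors = FALSE)
  truth <- rbind(mk(150L), mk(500L))
  hc <- regions("chr1", 100, 900)
  m <- classify_calls(call_set(truth), call_set(truth), hc, ref)
  tcalls <- m$calls[m$calls$role == "truth", ]
  expect_equal(tcalls$edge_flag[tcalls$pos == 150], TRUE)   # 49 bp in
  expect_equal(tcalls$edge_flag[tcalls$pos == 500], FALSE)
})

test_that("representation invariance: shuffled complex records keep all counts", {
  b <- shared_bundle()
  m <- shared_match()
  v <- b$bookkeeping$variants
  # every MNV-shuffled truth pair still matches as TP
  shuf <- v[!is.na(v$mnv_pair), ]
  tcalls <- m$calls[m$calls$role == "truth", ]
  # match on coordinates (the classifier renumbers records)
  key <- paste(tcalls$chrom, tcalls$pos, tcalls$ref, tcalls$alt)
  skey <- paste(shuf$chrom, shuf$pos, shuf$ref, shuf$alt)
  expect_true(all(tcalls$class[match(skey, key)] ==
                    ifelse(shuf$in_hiconf, "TP", "OUTSIDE")))
  expect_true(all(tcalls$match_type[match(skey, key)] %in%
                    c("haplotype", NA)))
})
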