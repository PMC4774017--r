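panel_fixture <- function(counts, ref, pos = 500L, qual = 30) {
  # counts: named integer vector platform -> datasets with evidence, as
  # "evid/total"
  b <- substr(ref[[1]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  panels <- list()
  for (platform in names(counts)) {
    total <- counts[[platform]][2]
    evid <- counts[[platform]][1]
    panels[[platform]] <- lapply(seq_len(total), function(d) {
      recs <- if (d <= evid)
        data.frame(chrom = "chr1", pos = pos, ref = b, alt = alt,
                   qual = qual, gt1 = 0L, gt2 = 1L,
                   stringsAsFactors = FALSE)
      else NULL
      call_set(recs, sample_id = "S",
               source_label = paste0(platform, "_ds", d))
    })
  }
  panels
}

test_that("platform flag rule: all datasets, or more than two", {
  set.seed(71)
  ref <- c(chr1 = random_dna_string(1000))
  hr <- regions("chr1", 0, 1000)
  flagged <- function(counts) {
    nrow(detect_systematic_errors(hr, panel_fixture(counts, ref), ref))
  }
  expect_equal(flagged(list(p1 = c(3L, 4L))), 1L)  # >2 of 4
  expect_equal(flagged(list(p1 = c(2L, 4L))), 0L)  # neither all nor >2
  expect_equal(flagged(list(p1 = c(2L, 2L))), 1L)  # all of 2
  expect_equal(flagged(list(p1 = c(1L, 2L))), 0L)
  expect_equal(flagged(list(p1 = c(1L, 1L))), 1L)  # trivially all
  expect_equal(flagged(list(p1 = c(4L, 4L))), 1L)
  # evidence below the quality threshold does not count
  ref2 <- ref
  panels <- panel_fixture(list(p1 = c(3L, 4L)), ref2, qual = 2)
  expect_equal(nrow(detect_systematic_errors(hr, panels, ref2)), 0L)
  # sites outside the homozygous-reference regions are ignored
  hr2 <- regions("chr1", 600, 1000)
  panels <- panel_fixture(list(p1 = c(3L, 4L)), ref, pos = 500L)
  expect_equal(nrow(detect_systematic_errors(hr2, panels, ref)), 0L)
})

test_that("detection is monotone in added evidence", {
  set.seed(72)
  ref <- c(chr1 = random_dna_string(1000))
  hr <- regions("chr1", 0, 1000)
  base <- panel_fixture(list(p1 = c(3L, 4L)), ref)
  n0 <- nrow(detect_systematic_errors(hr, base, ref))
  more <- panel_fixture(list(p1 = c(4L, 4L)), ref)
  expect_gte(nrow(detect_systematic_errors(hr, more, ref)), n0)
})

test_that("database intersection is allele-aware and deduplicated", {
  set.seed(73)
  ref <- c(chr1 = random_dna_string(1000))
  hr <- regions("chr1", 0, 1000)
  sites <- detect_systematic_errors(hr,
                                    panel_fixture(list(p1 = c(2L, 2L)),
                                                  ref), ref)
  expect_equal(nrow(sites), 1L)
  other_alt <- setdiff(c("A", "C", "G", "T"),
                       c(sites$ref, sites$alt))[1]
  mk_db <- function(alt) call_set(data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = alt,
    stringsAsFactors = FALSE), sample_id = "db")
  # different alternative allele -> no match
  res <- db_intersect(sites, list(d1 = mk_db(other_alt)), ref)
  expect_equal(res$counts$n_sites[res$counts$database == "d1"], 0L)
  # identical record in two databases counts once in the any-db total
  res2 <- db_intersect(sites, list(d1 = mk_db(sites$alt),
                                   d2 = mk_db(sites$alt)), ref)
  expect_equal(res2$counts$n_sites[res2$counts$database == "d1"], 1L)
  expect_equal(res2$counts$n_sites[res2$counts$database == "d2"], 1L)
  expect_equal(
    res2$counts$n_sites[res2$counts$database == "<any database>"], 1L)
})

test_that("shifted indel representations still intersect after normalization", {
  # homopolymer insertion recorded at two equivalent positions
  seq <- paste0("GATT", strrep("A", 8), "CGGA", random_dna_string(80))
  ref <- c(chr1 = seq)
  hr <- regions("chr1", 0, nchar(seq))
  # panel calls the insertion right-shifted inside the homopolymer
  panels <- list(p1 = lapply(1:2, function(d) call_set(
    data.frame(chrom = "chr1", pos = 8L, ref = "A", alt = "AA",
               qual = 30, gt1 = 0L, gt2 = 1L, stringsAsFactors = FALSE),
    sample_id = "S", source_label = paste0("ds", d))))
  sites <- detect_systematic_errors(hr, panels, ref)
  expect_equal(sites$pos, 4L)  # left-aligned to the T/A boundary anchor
  db <- call_set(data.frame(chrom = "chr1", pos = 6L, ref = "A",
                            alt = "AA", stringsAsFactors = FALSE),
                 sample_id = "db")
  res <- db_intersect(sites, list(d = db), ref)
  expect_equal(res$counts$n_sites[res$counts$database == "d"], 1L)
})

test_that("planted systematic sites are recovered exactly, noise stays silent", {
  b <- shared_bundle()
  det <- detect_systematic_errors(b$homref, b$panels, b$reference)
  exp <- expected_metrics(b)$syserr_sites
  expect_equal(paste(det$chrom, det$pos, det$ref, det$alt),
               paste(exp$chrom, exp$pos, exp$ref, exp$alt))
  expect_equal(det$platforms, exp$platforms)
  dbx <- db_intersect(det, b$databases, b$reference)
  expect_equal(dbx$counts, expected_metrics(b)$db_counts,
               ignore_attr = TRUE)
  # every emitted site is inside the homozygous-reference regions
  expect_true(all(region_contains(normalize_regions(b$homref),
                                  det$chrom, det$pos)))
})

test_that("panel validation rejects empty platforms and duplicate datasets", {
  ref <- c(chr1 = strrep("ACGT", 50))
  hr <- regions("chr1", 0, 200)
  expect_error(detect_systematic_errors(hr, list(p1 = list()), ref),
               "zero datasets")
  ds <- call_set(NULL, source_label = "same")
  expect_error(detect_systematic_errors(hr, list(p1 = list(ds, ds)),
                                        ref), "duplicate dataset")
})
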