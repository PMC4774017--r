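#' Detect platform-systematic error sites at homozygous-reference positions
#'
#' Scans per-platform panels of raw call sets for sites where the
#' benchmark asserts a homozygous-reference genotype but a platform's
#' datasets repeatedly call a variant. Evidence for an incorrect
#' genotype at a site is any call whose genotype contains a
#' non-reference allele with quality above `min_qual` (2, the
#' deliberately permissive threshold). A platform flags a site when all
#' of its datasets have evidence, or when more than two do; a site is
#' emitted when at least one platform flags it. Calls are normalized
#' first so shifted indel representations (homopolymers) land on one
#' position.
#'
#' @param homref Homozygous-reference benchmark regions (anything
#'   [normalize_regions()] accepts).
#' @param panels Named list (platform label -> list of [call_set()]s,
#'   at least one dataset per platform).
#' @param reference Named character vector of chromosome sequences (for
#'   normalization).
#' @param min_qual Quality threshold; evidence requires `qual > min_qual`.
#' @return `data.frame` with one row per site: `chrom`, `pos`, `ref`,
#'   `alt` (majority alt per site; ties resolved to the
#'   lexicographically smallest), `alts_seen` (all alts, comma-joined),
#'   `platforms` (comma-joined flagged platforms), `n_datasets`
#'   (evidence calls across all platforms).
#' @export
detect_systematic_errors <- function(homref, panels, reference,
                                     min_qual = 2) {
  homref <- normalize_regions(homref)
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    stop("panels must be a named list keyed by platform label")
  evid <- list()
  for (platform in names(panels)) {
    datasets <- panels[[platform]]
    if (length(datasets) == 0)
      stop("platform '", platform, "' has zero datasets")
    labels <- vapply(datasets, function(d) d$source_label, character(1))
    if (anyDuplicated(labels))
      stop("duplicate dataset source_labels within platform '",
           platform, "'")
    for (d in datasets) {
      r <- normalize_callset(d, reference)$records
      keep <- gt_is_variant(r$gt1, r$gt2) & !is.na(r$qual) &
        r$qual > min_qual & region_contains(homref, r$chrom, r$pos)
      r <- r[keep, , drop = FALSE]
      if (nrow(r) == 0) next
      evid[[length(evid) + 1L]] <-
        data.frame(platform = platform, dataset = d$source_label,
                   chrom = r$chrom, pos = r$pos, ref = r$ref,
                   alt = r$alt, stringsAsFactors = FALSE)
    }
  }
  if (length(evid) == 0) return(empty_syserr())
  ev <- do.call(rbind, evid)
  ev$site <- paste(ev$chrom, ev$pos, ev$ref, sep = ":")
  n_per_platform <- vapply(panels, length, integer(1))

  rows <- lapply(split(ev, ev$site), function(s) {
    flagged <- character(0)
    for (platform in unique(s$platform)) {
      nd <- length(unique(s$dataset[s$platform == platform]))
      if (nd == n_per_platform[[platform]] || nd > 2L)
        flagged <- c(flagged, platform)
    }
    if (length(flagged) == 0) return(NULL)
    alt_tab <- sort(table(s$alt), decreasing = TRUE)
    top <- names(alt_tab)[alt_tab == max(alt_tab)]
    data.frame(chrom = s$chrom[1], pos = s$pos[1], ref = s$ref[1],
               alt = sort(top)[1],
               alts_seen = paste(sort(unique(s$alt)), collapse = ","),
               platforms = paste(sort(flagged), collapse = ","),
               n_datasets = nrow(s), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_syserr())
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(region_contains(homref, out$chrom, out$pos)))
  out
}

empty_syserr <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), alts_seen = character(),
             platforms = character(), n_datasets = integer(),
             stringsAsFactors = FALSE)
}

#' Allele-aware intersection of systematic-error sites with databases
#'
#' A site matches a database record iff chromosome, normalized position,
#' REF and at least one ALT allele agree; records with only different
#' alternative alleles are filtered out. Reports per-database hit counts
#' and a deduplicated any-database total.
#'
#' @param sites Output of [detect_systematic_errors()].
#' @param databases Named list of [call_set()]s of database variants.
#' @param reference Named character vector of chromosome sequences (for
#'   normalizing database records).
#' @return List with `counts` (`database`, `n_sites`; first rows are
#'   `<total>` and `<any database>`) and `sites` (input plus one logical
#'   `in_<db>` column per database and `in_any_db`).
#' @export
db_intersect <- function(sites, databases, reference) {
  site_alts <- strsplit(sites$alts_seen, ",", fixed = TRUE)
  any_hit <- rep(FALSE, nrow(sites))
  count_rows <- list()
  for (db in names(databases)) {
    r <- normalize_callset(databases[[db]], reference)$records
    db_keys <- unlist(lapply(seq_len(nrow(r)), function(i)
      paste(r$chrom[i], r$pos[i], r$ref[i],
            strsplit(r$alt[i], ",", fixed = TRUE)[[1]], sep = ":")))
    hit <- vapply(seq_len(nrow(sites)), function(i)
      any(paste(sites$chrom[i], sites$pos[i], sites$ref[i],
                site_alts[[i]], sep = ":") %in% db_keys), logical(1))
    sites[[paste0("in_", db)]] <- hit
    any_hit <- any_hit | hit
    count_rows[[db]] <- data.frame(database = db, n_sites = sum(hit),
                                   stringsAsFactors = FALSE)
  }
  sites$in_any_db <- any_hit
  counts <- rbind(
    data.frame(database = "<total>", n_sites = nrow(sites),
               stringsAsFactors = FALSE),
    data.frame(database = "<any database>", n_sites = sum(any_hit),
               stringsAsFactors = FALSE),
    do.call(rbind, count_rows))
  rownames(counts) <- NULL
  list(counts = counts, sites = sites)
}
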