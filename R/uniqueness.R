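#' Exact k-mer uniqueness track
#'
#' For every position p of every chromosome, the flag is `TRUE` iff the
#' k-mer starting at p occurs at exactly one start position on the
#' forward strand genome-wide. K-mers containing `N` are never unique
#' (undefined sequence cannot certify uniqueness). Occurrences are
#' counted on the forward strand, matching the construction of the
#' standard browser uniqueness tracks; `both_strands = TRUE` also counts
#' reverse-complement occurrences.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param k K-mer length in bp (35 for the classic uniqueness track).
#' @param both_strands Count reverse-complement occurrences too.
#' @return A `UniquenessTrack`: list with `k`, `mode` and per-chromosome
#'   logical vectors `flags` over 0-based start positions
#'   `0 .. len - k`.
#' @export
exact_uniqueness <- function(reference, k = 35L, both_strands = FALSE) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > max(nchar(reference)))
    stop("k exceeds the longest chromosome")
  kmers <- lapply(reference, chrom_kmers, k = k)
  all_k <- unlist(kmers, use.names = FALSE)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(all_k)))
    lev <- unique(c(all_k, rc))
    fwd_count <- tabulate(match(all_k, lev), nbins = length(lev))
    n_fwd <- fwd_count[match(all_k, lev)]
    n_rc <- fwd_count[match(rc, lev)]
    # a palindromic k-mer sees itself once on each strand of the same
    # location; do not double-count it
    uniq <- n_fwd == 1L & ifelse(rc == all_k, TRUE, n_rc == 0L)
  } else {
    uniq <- !(duplicated(all_k) | duplicated(all_k, fromLast = TRUE))
  }
  has_n <- grepl("N", all_k, fixed = TRUE)
  flag_all <- uniq & !has_n
  flags <- relist_flags(flag_all, kmers)
  structure(list(k = k, mode = "exact", flags = flags),
            class = "UniquenessTrack")
}

chrom_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

relist_flags <- function(flag_all, kmers) {
  n <- vapply(kmers, length, integer(1))
  ends <- cumsum(n)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- lapply(seq_along(kmers), function(i)
    if (n[i] == 0) logical(0) else flag_all[starts[i]:ends[i]])
  names(out) <- names(kmers)
  out
}

#' Mismatch-tolerant alignability track
#'
#' The flag at position p is `TRUE` iff no other genomic start position
#' carries a k-mer within Hamming distance `max_mismatch` of the k-mer
#' at p (gapless comparison, forward strand). With `max_mismatch = 0`
#' this equals [exact_uniqueness()]. Candidate pairs are found by the
#' pigeonhole principle — two k-mers within distance m share at least
#' one of m+1 equal-length chunks — so only colliding chunk groups are
#' verified, keeping the scan far below the quadratic worst case on
#' realistic sequence.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param k Fragment length (100 for the classic alignability track).
#' @param max_mismatch Maximum Hamming distance tolerated (default 2).
#' @return A `UniquenessTrack` with mode `"mismatch(m)"`.
#' @export
alignability <- function(reference, k = 100L, max_mismatch = 2L) {
  k <- as.integer(k); m <- as.integer(max_mismatch)
  if (k < 1) stop("k must be >= 1")
  if (m < 0) stop("max_mismatch must be >= 0")
  if (k > max(nchar(reference)))
    stop("k exceeds the longest chromosome")
  kmers_by <- lapply(reference, chrom_kmers, k = k)
  all_k <- unlist(kmers_by, use.names = FALSE)
  np <- length(all_k)
  has_n <- grepl("N", all_k, fixed = TRUE)
  ok <- !has_n

  if (m == 0) {
    dup <- duplicated(all_k) | duplicated(all_k, fromLast = TRUE)
    flags <- relist_flags(ok & !dup, kmers_by)
    return(structure(list(k = k, mode = "mismatch(0)", flags = flags),
                     class = "UniquenessTrack"))
  }

  # chunk bounds: m+1 near-equal pieces of the k-mer
  n_chunk <- m + 1L
  bounds <- floor(seq(0, k, length.out = n_chunk + 1L))
  hamming <- function(i, j) sum(charToRaw(all_k[i]) != charToRaw(all_k[j]))
  not_unique <- rep(FALSE, np)
  checked <- new.env(hash = TRUE)
  for (c_i in seq_len(n_chunk)) {
    off <- bounds[c_i]; len <- bounds[c_i + 1L] - bounds[c_i]
    chunks <- substring(all_k, off + 1L, off + len)
    coll <- duplicated(chunks) | duplicated(chunks, fromLast = TRUE)
    grp <- split(which(coll), chunks[coll])
    for (g in grp) {
      for (a in seq_along(g)[-length(g)]) {
        for (b in (a + 1L):length(g)) {
          i <- g[a]; j <- g[b]
          if (not_unique[i] && not_unique[j]) next
          key <- paste0(i, "_", j)
          if (!is.null(checked[[key]])) next
          checked[[key]] <- TRUE
          if (hamming(i, j) <= m) {
            not_unique[i] <- TRUE; not_unique[j] <- TRUE
          }
        }
      }
    }
  }
  flags <- relist_flags(ok & !not_unique, kmers_by)
  structure(list(k = k, mode = sprintf("mismatch(%d)", m), flags = flags),
            class = "UniquenessTrack")
}

#' @export
print.UniquenessTrack <- function(x, ...) {
  cat(sprintf("UniquenessTrack k=%d mode=%s; %d position(s), %.1f%% true\n",
              x$k, x$mode, sum(lengths(x$flags)),
              100 * mean(unlist(x$flags))))
  invisible(x)
}

#' Look up track flags at 1-based positions
#'
#' @param track A `UniquenessTrack`.
#' @param chrom,pos Vectors of sequence names and 1-based positions.
#' @return Logical vector; `NA` where the position is beyond the track
#'   range.
#' @export
track_flag <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  out <- rep(NA, n)
  for (cn in unique(chrom)) {
    f <- track$flags[[cn]]
    if (is.null(f)) next
    sel <- chrom == cn
    idx <- pos[sel]
    valid <- idx >= 1L & idx <= length(f)
    out[sel][valid] <- f[idx[valid]]
  }
  out
}

#' Convert the TRUE runs of a track to regions (for BED export)
#'
#' @param track A `UniquenessTrack`.
#' @return Region `data.frame` of maximal runs of `TRUE` start positions
#'   (0-based half-open over starts).
#' @export
track_true_regions <- function(track) {
  rows <- lapply(names(track$flags), function(cn) {
    f <- track$flags[[cn]]
    if (length(f) == 0 || !any(f)) return(NULL)
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    regions(rep(cn, sum(keep)), starts[keep], ends[keep])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_regions() else out
}

#' Genomic-context flags for variants
#'
#' Annotates each variant with whether it falls in high-confidence
#' regions and whether its 0-based start position begins a unique 35 bp
#' sequence and an alignable 100 bp sequence, then summarizes the
#' percentage of variants with each flag (2 decimals), overall and per
#' subset label when one is supplied.
#'
#' @param variants A [call_set()] or records `data.frame` with `chrom`,
#'   `pos`; an optional `subset` column defines reporting subsets.
#' @param hiconf High-confidence region set.
#' @param track35 Exact-uniqueness track (any k; named for the classic
#'   35 bp track).
#' @param track100 Alignability track.
#' @return List with `contexts` (per-variant flags) and `summary`
#'   (`subset`, `flag`, `n`, `n_true`, `percent`).
#' @export
variant_context <- function(variants, hiconf, track35, track100) {
  r <- if (inherits(variants, "CallSet")) variants$records else variants
  hiconf <- normalize_regions(hiconf)
  ctx <- data.frame(chrom = r$chrom, pos = r$pos, stringsAsFactors = FALSE)
  ctx$subset <- if ("subset" %in% names(r)) r$subset else NA_character_
  ctx$in_hiconf <- region_contains(hiconf, r$chrom, r$pos)
  ctx$unique35 <- track_flag(track35, r$chrom, r$pos)
  ctx$alignable100 <- track_flag(track100, r$chrom, r$pos)
  flags <- c("in_hiconf", "unique35", "alignable100")
  summarize <- function(sub, label) {
    do.call(rbind, lapply(flags, function(fl) {
      v <- sub[[fl]]
      data.frame(subset = label, flag = fl, n = length(v),
                 n_true = sum(v, na.rm = TRUE),
                 percent = if (length(v))
                   round(100 * sum(v, na.rm = TRUE) / length(v), 2)
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  summary <- summarize(ctx, "<all>")
  for (lab in sort(unique(stats::na.omit(ctx$subset)))) {
    summary <- rbind(summary, summarize(ctx[!is.na(ctx$subset) &
                                              ctx$subset == lab, ], lab))
  }
  rownames(summary) <- NULL
  list(contexts = ctx, summary = summary)
}
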