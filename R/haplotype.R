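#' Haplotype-aware equivalence of two variant sets over a window
#'
#' Decides whether a set of truth records and a set of query records
#' describe the same pair of diploid haplotype sequences over a genomic
#' window, regardless of how the edits are represented (nearby SNVs,
#' MNVs, indels, complex records). For each side, every assignment of
#' heterozygous records to the two haplotypes is enumerated (2^h for h
#' heterozygous records; homozygous-alt records apply to both), each
#' consistent assignment is reconstructed into an unordered pair of
#' window sequences, and the two sides match iff they share at least one
#' reconstructable pair. Half-calls (`./1`) are treated as heterozygous.
#' Assignments that place overlapping records on one haplotype are
#' discarded as unreconstructable.
#'
#' @param truth,query `data.frame`s of normalized single-alt records
#'   (columns `pos`, `ref`, `alt`, `gt1`, `gt2`), all within the window.
#' @param window `list(chrom, start, end)` with 0-based half-open bounds.
#' @param reference Named character vector of chromosome sequences.
#' @param max_het Cap on heterozygous records per side (cost 2^h).
#' @return `list(match = logical, reason = character)`.
#' @export
haplotype_match <- function(truth, query, window, reference,
                            max_het = 12L) {
  seq <- reference[[window$chrom]]
  if (is.null(seq)) stop("reference lacks chromosome ", window$chrom)
  ws <- max(0L, as.integer(window$start))
  we <- min(nchar(seq), as.integer(window$end))
  tp <- hap_pairs(truth, ws, we, seq, max_het)
  qp <- hap_pairs(query, ws, we, seq, max_het)
  if (!tp$ok) return(list(match = FALSE, reason = tp$reason))
  if (!qp$ok) return(list(match = FALSE, reason = qp$reason))
  ok <- length(intersect(tp$pairs, qp$pairs)) > 0
  list(match = ok,
       reason = if (ok) "haplotype sequences identical" else
         "no phasing yields identical haplotype pairs")
}

# All reconstructable unordered haplotype-sequence pairs for one side,
# encoded as "seqA\x01seqB" with the pair sorted. Returns
# list(ok, pairs) or list(ok = FALSE, reason) on failure.
hap_pairs <- function(recs, ws, we, seq, max_het) {
  if (is.null(recs) || nrow(recs) == 0) {
    base <- substr(seq, ws + 1L, we)
    return(list(ok = TRUE, pairs = paste(base, base, sep = "\x01")))
  }
  recs <- recs[order(recs$pos), , drop = FALSE]
  # half-calls: missing side treated as reference (heterozygous policy)
  g1 <- ifelse(is.na(recs$gt1), 0L, recs$gt1)
  g2 <- ifelse(is.na(recs$gt2), 0L, recs$gt2)
  het <- which(g1 != g2)
  if (length(het) > max_het)
    return(list(ok = FALSE, reason =
                  sprintf("cluster has %d heterozygous records (cap %d)",
                          length(het), max_het)))
  out <- character(0)
  n_assign <- 2L^length(het)
  for (mask in seq_len(n_assign) - 1L) {
    a1 <- g1; a2 <- g2
    if (length(het)) {
      flip <- het[bitwAnd(bitwShiftR(mask, seq_along(het) - 1L), 1L) == 1L]
      a1[flip] <- g2[flip]; a2[flip] <- g1[flip]
    }
    h1 <- apply_haplotype(recs, a1, ws, we, seq)
    h2 <- apply_haplotype(recs, a2, ws, we, seq)
    if (is.na(h1) || is.na(h2)) next
    pair <- sort(c(h1, h2))
    out <- c(out, paste(pair[1], pair[2], sep = "\x01"))
  }
  if (length(out) == 0)
    return(list(ok = FALSE, reason =
                  "no assignment reconstructs without overlapping alleles"))
  list(ok = TRUE, pairs = unique(out))
}

# Apply the records whose allele on this haplotype is non-reference to
# the window sequence; NA if two applied records overlap.
apply_haplotype <- function(recs, allele, ws, we, seq) {
  use <- which(allele > 0L)
  cursor <- ws  # 0-based offset of next unconsumed reference base
  parts <- character(0)
  for (i in use) {
    p0 <- recs$pos[i] - 1L
    if (p0 < cursor) return(NA_character_)
    if (p0 + nchar(recs$ref[i]) > we) return(NA_character_)
    if (p0 > cursor) parts <- c(parts, substr(seq, cursor + 1L, p0))
    parts <- c(parts, recs$alt[i])
    cursor <- p0 + nchar(recs$ref[i])
  }
  if (cursor < we) parts <- c(parts, substr(seq, cursor + 1L, we))
  paste(parts, collapse = "")
}
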