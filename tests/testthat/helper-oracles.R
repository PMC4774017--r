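# Independent brute-force oracles. These deliberately use different
# representations (integer position sets, character matrices) from the
# implementations they check.

# -- region sets as per-chromosome integer position sets --------------
oracle_positions <- function(df) {
  if (nrow(df) == 0) return(list())
  out <- list()
  for (i in seq_len(nrow(df))) {
    cn <- df$chrom[i]
    out[[cn]] <- union(out[[cn]], seq.int(df$start[i], df$end[i] - 1L))
  }
  out <- lapply(out, sort)
  out[order(names(out))]
}

oracle_binop <- function(a, b, fun) {
  pa <- oracle_positions(a); pb <- oracle_positions(b)
  chroms <- union(names(pa), names(pb))
  out <- lapply(chroms, function(cn)
    sort(fun(if (is.null(pa[[cn]])) integer(0) else pa[[cn]],
             if (is.null(pb[[cn]])) integer(0) else pb[[cn]])))
  names(out) <- chroms
  out <- out[vapply(out, length, integer(1)) > 0]
  out[order(names(out))]
}

regionset_positions <- function(rs) oracle_positions(as.data.frame(rs))

random_region_df <- function(n, chroms = c("chrA", "chrB"), len = 1000L) {
  start <- sample.int(len - 20L, n, replace = TRUE) - 1L
  width <- sample.int(15L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = pmin(start + width, len), stringsAsFactors = FALSE)
}

# -- k-mer uniqueness / alignability via full pairwise Hamming scan ---
oracle_track <- function(reference, k, max_mismatch = 0L) {
  kmers <- unlist(lapply(reference, function(seq) {
    L <- nchar(seq)
    if (L < k) return(character(0))
    substring(seq, 1:(L - k + 1L), k:L)
  }), use.names = FALSE)
  n <- length(kmers)
  mat <- do.call(rbind, strsplit(kmers, ""))
  flags <- logical(n)
  for (i in seq_len(n)) {
    d <- rowSums(mat != rep(mat[i, ], each = n))
    flags[i] <- sum(d <= max_mismatch) == 1L && !any(mat[i, ] == "N")
  }
  # reassemble per chromosome
  lens <- vapply(reference, function(s) max(0L, nchar(s) - k + 1L),
                 integer(1))
  ends <- cumsum(lens); starts <- c(1L, head(ends, -1) + 1L)
  out <- lapply(seq_along(reference), function(i)
    if (lens[i] == 0) logical(0) else flags[starts[i]:ends[i]])
  names(out) <- names(reference)
  out
}

# -- variant normalization: leftmost-minimal equivalent triple --------
oracle_normalize <- function(pos, ref, alt, seq) {
  mutated <- paste0(substr(seq, 1, pos - 1L), alt,
                    substr(seq, pos + nchar(ref), nchar(seq)))
  best <- NULL
  for (lr in 1:(nchar(ref) + nchar(alt))) {
    for (p in 1:(nchar(seq) - lr + 1L)) {
      pre <- substr(seq, 1, p - 1L)
      suf <- substr(seq, p + lr, nchar(seq))
      la <- nchar(mutated) - nchar(pre) - nchar(suf)
      if (la < 1) next
      if (substr(mutated, 1, nchar(pre)) != pre) next
      if (substr(mutated, nchar(mutated) - nchar(suf) + 1L,
                 nchar(mutated)) != suf) next
      cand_alt <- substr(mutated, p, p + la - 1L)
      cand_ref <- substr(seq, p, p + lr - 1L)
      if (cand_ref == cand_alt) next
      cand <- list(pos = p, ref = cand_ref, alt = cand_alt)
      if (is.null(best) ||
          nchar(cand$ref) < nchar(best$ref) ||
          (nchar(cand$ref) == nchar(best$ref) &&
             nchar(cand$alt) < nchar(best$alt)) ||
          (nchar(cand$ref) == nchar(best$ref) &&
             nchar(cand$alt) == nchar(best$alt) && cand$pos < best$pos))
        best <- cand
    }
    if (!is.null(best) && nchar(best$ref) == lr) break
  }
  best
}

# -- haplotype equivalence via char-vector enumeration ----------------
oracle_hap_pairs <- function(recs, ws, we, seq_chars) {
  if (nrow(recs) == 0) {
    h <- paste(seq_chars[(ws + 1L):we], collapse = "")
    return(paste(h, h, sep = "|"))
  }
  g1 <- ifelse(is.na(recs$gt1), 0L, recs$gt1)
  g2 <- ifelse(is.na(recs$gt2), 0L, recs$gt2)
  het <- which(g1 != g2)
  grids <- if (length(het))
    expand.grid(rep(list(c(FALSE, TRUE)), length(het)))
  else data.frame(row.names = 1)
  build <- function(allele) {
    # per-position list of replacements on a char vector
    keep <- rep(TRUE, we - ws)
    ins <- rep("", we - ws)
    for (i in order(recs$pos)) {
      if (allele[i] == 0L) next
      p0 <- recs$pos[i] - 1L
      span <- (p0 - ws + 1L):(p0 - ws + nchar(recs$ref[i]))
      if (any(span < 1) || any(span > we - ws)) return(NA_character_)
      if (any(!keep[span] | nzchar(ins[span]))) return(NA_character_)
      keep[span] <- FALSE
      ins[span[1]] <- recs$alt[i]
    }
    base <- seq_chars[(ws + 1L):we]
    paste(ifelse(nzchar(ins), paste0(ins, ifelse(keep, base, "")),
                 ifelse(keep, base, "")), collapse = "")
  }
  pairs <- character(0)
  for (r in seq_len(nrow(grids))) {
    a1 <- g1; a2 <- g2
    if (length(het)) {
      flip <- het[unlist(grids[r, ])]
      a1[flip] <- g2[flip]; a2[flip] <- g1[flip]
    }
    h1 <- build(a1); h2 <- build(a2)
    if (is.na(h1) || is.na(h2)) next
    p <- sort(c(h1, h2))
    pairs <- c(pairs, paste(p[1], p[2], sep = "|"))
  }
  unique(pairs)
}

oracle_haplotype_match <- function(truth, query, window, reference) {
  seq_chars <- strsplit(reference[[window$chrom]], "")[[1]]
  tp <- oracle_hap_pairs(truth, window$start, window$end, seq_chars)
  qp <- oracle_hap_pairs(query, window$start, window$end, seq_chars)
  length(intersect(tp, qp)) > 0
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
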