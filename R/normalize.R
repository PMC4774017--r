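#' Normalize a variant representation against the reference
#'
#' Canonicalizes one (pos, ref, alt) triple: shared trailing then leading
#' bases are trimmed (keeping at least one base on each allele for
#' indels), and indels are left-aligned — shifted to the lowest 1-based
#' position at which the representation is irreducible, extending with
#' reference bases as needed. SNVs pass through unchanged. Two variants
#' describing the same sequence edit therefore normalize to the same
#' triple.
#'
#' @param pos 1-based position of the first REF base.
#' @param ref,alt Uppercase allele strings (single alt).
#' @param seq The chromosome sequence as a single character string.
#' @return `list(pos, ref, alt)` in canonical form.
#' @export
normalize_variant <- function(pos, ref, alt, seq) {
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref)
    stop("REF allele '", ref, "' does not match the reference at position ",
         pos)
  if (ref == alt) stop("ref and alt alleles are identical")
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    # trim a shared trailing base; refill from the reference when an
    # allele would become empty (classic left-align step)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos > 1L) {
          pos <- pos - 1L
          prev <- substr(seq, pos, pos)
          ref <- paste0(prev, ref)
          alt <- paste0(prev, alt)
        } else {
          # already at the chromosome start: pad on the right instead
          nxt_at <- pos + nchar(ref)
          if (nxt_at > nchar(seq))
            stop("cannot normalize variant spanning the whole sequence")
          nxt <- substr(seq, nxt_at, nxt_at)
          ref <- paste0(ref, nxt)
          alt <- paste0(alt, nxt)
          break
        }
      }
      next
    }
    break
  }
  # trim shared leading bases, keeping >= 1 base per allele
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Split multi-allelic records into per-alt records
#'
#' Each ALT allele of a multi-allelic record becomes its own record; the
#' genotype is projected onto that allele (indices equal to the allele
#' become 1, all others 0, missing stays missing). Bi-allelic records
#' pass through.
#'
#' @param x A [call_set()].
#' @return A `CallSet` with single-alt records only.
#' @export
split_multiallelic <- function(x) {
  r <- x$records
  if (nrow(r) == 0) return(x)
  alts <- strsplit(r$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  if (all(n_alt == 1L)) return(x)
  idx <- rep(seq_len(nrow(r)), n_alt)
  k <- unlist(lapply(n_alt, seq_len))
  out <- r[idx, , drop = FALSE]
  out$alt <- unlist(alts)
  proj <- function(g) ifelse(is.na(g), NA_integer_, ifelse(g == k, 1L, 0L))
  out$gt1 <- proj(r$gt1[idx])
  out$gt2 <- proj(r$gt2[idx])
  call_set(out, sample_id = x$sample_id, source_label = x$source_label)
}

#' Normalize every record of a CallSet
#'
#' Splits multi-allelic records, then applies [normalize_variant()] to
#' each record. Records are re-sorted after position shifts.
#'
#' @param x A [call_set()].
#' @param reference Named character vector of chromosome sequences.
#' @return A normalized `CallSet`.
#' @export
normalize_callset <- function(x, reference) {
  x <- split_multiallelic(x)
  r <- x$records
  if (nrow(r) == 0) return(x)
  missing_chrom <- setdiff(unique(r$chrom), names(reference))
  if (length(missing_chrom))
    stop("reference lacks chromosome(s): ",
         paste(missing_chrom, collapse = ", "))
  for (i in seq_len(nrow(r))) {
    nv <- normalize_variant(r$pos[i], r$ref[i], r$alt[i],
                            reference[[r$chrom[i]]])
    r$pos[i] <- nv$pos; r$ref[i] <- nv$ref; r$alt[i] <- nv$alt
  }
  call_set(r, sample_id = x$sample_id, source_label = x$source_label)
}
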