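#' Construct a table of genomic regions
#'
#' Regions are half-open intervals `[start, end)` in 0-based coordinates
#' (BED convention) on a named sequence. This is the atom of all region
#' arithmetic in the package.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector of 0-based inclusive start offsets.
#' @param end Integer vector of 0-based exclusive end offsets.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
regions <- function(chrom = character(), start = integer(), end = integer()) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    chrom <- rep_len(chrom, n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("region chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end)))
    stop("region bounds must be non-missing")
  if (any(start < 0))
    stop("region start must be >= 0")
  if (any(end <= start))
    stop("region end must be > start (half-open, non-empty)")
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Normalize a region list into a RegionSet
#'
#' Sorts regions by (chrom, start) and merges overlapping and abutting
#' intervals, yielding the canonical base-set representation used by all
#' set operations. Abutting intervals merge because the pipeline reasons
#' in covered bases, not in bookkeeping intervals.
#'
#' @param x A region `data.frame` (see [regions()]), possibly unsorted and
#'   overlapping. An already-normalized `RegionSet` passes through.
#' @return A `RegionSet`: a sorted, merged, non-overlapping region table.
#' @examples
#' normalize_regions(regions(c("chr1", "chr1"), c(0, 5), c(10, 15)))
#' @export
normalize_regions <- function(x) {
  if (inherits(x, "RegionSet")) return(x)
  if (is.null(x) || nrow(x) == 0) {
    out <- empty_regions()
    class(out) <- c("RegionSet", class(out))
    return(out)
  }
  x <- regions(x$chrom, x$start, x$end)
  parts <- split(x, x$chrom)
  merged <- lapply(names(parts), function(cn) {
    p <- parts[[cn]]
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    data.frame(chrom = cn, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RegionSet", class(out))
  out
}

is_region_set <- function(x) inherits(x, "RegionSet")

as_ranges_by_chrom <- function(x) {
  parts <- split(x, x$chrom)
  lapply(parts, function(p) IRanges::IRanges(start = p$start + 1L, end = p$end))
}

ranges_to_regions <- function(by_chrom) {
  keep <- vapply(by_chrom, length, integer(1)) > 0
  by_chrom <- by_chrom[keep]
  if (length(by_chrom) == 0) return(normalize_regions(empty_regions()))
  out <- do.call(rbind, lapply(names(by_chrom), function(cn) {
    ir <- by_chrom[[cn]]
    data.frame(chrom = cn, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  normalize_regions(out)
}

region_binop <- function(a, b, fun) {
  a <- normalize_regions(a)
  b <- normalize_regions(b)
  ra <- as_ranges_by_chrom(a)
  rb <- as_ranges_by_chrom(b)
  chroms <- union(names(ra), names(rb))
  res <- lapply(chroms, function(cn) {
    ia <- if (cn %in% names(ra)) ra[[cn]] else IRanges::IRanges()
    ib <- if (cn %in% names(rb)) rb[[cn]] else IRanges::IRanges()
    fun(ia, ib)
  })
  names(res) <- chroms
  ranges_to_regions(res)
}

#' Region-set algebra
#'
#' Base-set semantics over genomic positions: `region_intersect` keeps
#' positions in both sets, `region_subtract` removes positions of `b` from
#' `a`, `region_union` combines them. All three normalize their inputs and
#' return a normalized `RegionSet`. The conservation identity
#' `total_length(a) == total_length(region_intersect(a, b)) +
#' total_length(region_subtract(a, b))` holds for all inputs.
#'
#' @param a,b Region tables or `RegionSet`s.
#' @return A `RegionSet`.
#' @export
region_intersect <- function(a, b) region_binop(a, b, IRanges::intersect)

#' @rdname region_intersect
#' @export
region_subtract <- function(a, b) region_binop(a, b, IRanges::setdiff)

#' @rdname region_intersect
#' @export
region_union <- function(a, b) region_binop(a, b, IRanges::union)

#' Total number of bases covered by a region set
#'
#' @param x A region table or `RegionSet`.
#' @return Non-negative integer count of covered bases.
#' @export
total_length <- function(x) {
  x <- normalize_regions(x)
  if (nrow(x) == 0) return(0L)
  as.integer(sum(x$end - x$start))
}

#' Fraction of a target region set covered by another set
#'
#' @param target Region set whose bases are counted in the denominator;
#'   must be non-empty.
#' @param cover Region set providing the covering bases.
#' @return Fraction in `[0, 1]`:
#'   `total_length(intersect(target, cover)) / total_length(target)`.
#' @export
covered_fraction <- function(target, cover) {
  target <- normalize_regions(target)
  if (total_length(target) == 0)
    stop("covered_fraction is undefined for an empty target")
  total_length(region_intersect(target, cover)) / total_length(target)
}

#' Point membership and edge distance in a region set
#'
#' `region_contains` tests whether 1-based positions fall inside the set
#' (half-open semantics after conversion to 0-based). `edge_distance`
#' returns, for positions inside the set, the distance in bases from the
#' position to the nearest boundary of its enclosing region; a position on
#' the first or last base of a region has distance 0, so "within `w` bp of
#' the inside edge" is the inclusive test `edge_distance <= w - 1`.
#' Positions outside the set get `NA`.
#'
#' @param set A `RegionSet`.
#' @param chrom Character vector of sequence names (recycled against `pos`).
#' @param pos Integer vector of 1-based positions.
#' @return `region_contains`: logical vector. `edge_distance`: integer
#'   vector with `NA` outside the set.
#' @export
region_contains <- function(set, chrom, pos) {
  !is.na(edge_distance(set, chrom, pos))
}

#' @rdname region_contains
#' @export
edge_distance <- function(set, chrom, pos) {
  set <- normalize_regions(set)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos0 <- rep_len(as.integer(pos), n) - 1L
  out <- rep(NA_integer_, n)
  if (nrow(set) == 0 || n == 0) return(out)
  parts <- split(seq_len(n), chrom)
  by_chrom <- split(set, set$chrom)
  for (cn in names(parts)) {
    p <- by_chrom[[cn]]
    if (is.null(p)) next
    idx <- parts[[cn]]
    # findInterval over sorted starts locates the candidate enclosing region
    j <- findInterval(pos0[idx], p$start)
    inside <- j >= 1L & pos0[idx] < p$end[pmax(j, 1L)]
    hit <- idx[inside]
    jj <- j[inside]
    out[hit] <- pmin(pos0[hit] - p$start[jj], p$end[jj] - 1L - pos0[hit])
  }
  out
}
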