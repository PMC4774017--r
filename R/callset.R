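#' Construct a CallSet
#'
#' A `CallSet` holds one sample's variant calls as a records table sorted
#' by (chrom, pos). Multi-allelic sites are kept as one record with a
#' comma-separated `alt`; the genotype is a pair of allele indices
#' (0 = reference) in `gt1`/`gt2`, with `phased` recording whether the
#' genotype separator was `|`. `filters` is a semicolon-joined label set;
#' the empty string means PASS. Missing QUAL/DP/GT fields are `NA`.
#'
#' @param records A `data.frame` with columns `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`, `qual`, `filters`, `gt1`, `gt2`, `phased`,
#'   `depth`. Missing optional columns are filled with `NA`.
#' @param sample_id Sample label.
#' @param source_label Free-text provenance label (platform/dataset name).
#' @return An object of class `CallSet`.
#' @export
call_set <- function(records, sample_id = "sample", source_label = "") {
  cols <- c("chrom", "pos", "id", "ref", "alt", "qual", "filters",
            "gt1", "gt2", "phased", "depth")
  if (is.null(records) || nrow(records) == 0) {
    records <- data.frame(chrom = character(), pos = integer(),
                          id = character(), ref = character(),
                          alt = character(), qual = numeric(),
                          filters = character(), gt1 = integer(),
                          gt2 = integer(), phased = logical(),
                          depth = integer(), stringsAsFactors = FALSE)
  }
  defaults <- list(id = ".", qual = NA_real_, filters = "",
                   gt1 = NA_integer_, gt2 = NA_integer_, phased = FALSE,
                   depth = NA_integer_)
  for (nm in names(defaults)) {
    if (!nm %in% names(records)) records[[nm]] <- defaults[[nm]]
  }
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt"), names(records))
  if (length(missing_cols))
    stop("call_set records lack columns: ", paste(missing_cols, collapse = ", "))
  records <- records[, cols, drop = FALSE]
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$id <- as.character(records$id)
  records$ref <- toupper(as.character(records$ref))
  records$alt <- toupper(as.character(records$alt))
  records$qual <- as.numeric(records$qual)
  records$filters <- as.character(records$filters)
  records$gt1 <- as.integer(records$gt1)
  records$gt2 <- as.integer(records$gt2)
  records$phased <- as.logical(records$phased)
  records$depth <- as.integer(records$depth)
  validate_records(records)
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(sample_id = sample_id, source_label = source_label,
                 records = records),
            class = "CallSet")
}

validate_records <- function(r) {
  if (nrow(r) == 0) return(invisible(TRUE))
  if (any(is.na(r$pos) | r$pos < 1L))
    stop("variant pos must be >= 1")
  bad_ref <- !grepl("^[ACGTN]+$", r$ref)
  if (any(bad_ref))
    stop("non-DNA REF allele at record ", which(bad_ref)[1])
  alts <- strsplit(r$alt, ",", fixed = TRUE)
  symbolic <- vapply(alts, function(a)
    any(grepl("[][<>]", a)) || any(a == "*"), logical(1))
  if (any(symbolic))
    stop("symbolic or breakend ALT alleles are not supported ",
         "(structural variants are outside the benchmark scope); record ",
         which(symbolic)[1])
  bad_alt <- vapply(alts, function(a)
    length(a) == 0 || any(!grepl("^[ACGTN]+$", a)), logical(1))
  if (any(bad_alt))
    stop("non-DNA ALT allele at record ", which(bad_alt)[1])
  n_alt <- lengths(alts)
  bad_gt <- (!is.na(r$gt1) & r$gt1 > n_alt) | (!is.na(r$gt2) & r$gt2 > n_alt)
  if (any(bad_gt))
    stop("genotype allele index exceeds ALT count at record ",
         which(bad_gt)[1])
  invisible(TRUE)
}

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("CallSet '%s' (%s): %d record(s)\n", x$sample_id,
              x$source_label, nrow(x$records)))
  if (nrow(x$records)) print(utils::head(x$records, 10))
  invisible(x)
}

n_records <- function(x) nrow(x$records)

#' Split filter label strings into label sets
#'
#' @param filters Character vector of semicolon-joined filter labels;
#'   `""`, `"PASS"` and `"."` all denote the empty (passing) set.
#' @return List of character vectors.
#' @export
filter_labels <- function(filters) {
  lapply(strsplit(filters, ";", fixed = TRUE), function(f) {
    f <- f[nzchar(f) & f != "PASS" & f != "."]
    sort(unique(f))
  })
}

#' @rdname filter_labels
#' @export
is_pass <- function(filters) lengths(filter_labels(filters)) == 0

# Genotype carries at least one non-reference allele
gt_is_variant <- function(gt1, gt2) {
  (!is.na(gt1) & gt1 > 0L) | (!is.na(gt2) & gt2 > 0L)
}

# Heterozygous under the half-call-as-het policy: the two alleles differ,
# or one side is missing
gt_is_het <- function(gt1, gt2) {
  ifelse(is.na(gt1) | is.na(gt2), TRUE, gt1 != gt2)
}

variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}
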