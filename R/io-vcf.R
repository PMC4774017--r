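#' Read a VCF file into a CallSet
#'
#' Interprets CHROM, POS, ID, REF, ALT, QUAL, FILTER and one sample's
#' GT/DP; all other fields are ignored. Multi-allelic lines are retained
#' as one record. FILTER values `PASS` and `.` map to the empty filter
#' set. Records are returned sorted by (chrom, pos). Chromosome names are
#' taken verbatim (no "chr" aliasing).
#'
#' @param path Path to a VCF 4.x file (plain or bgzip).
#' @param sample Sample name to extract. May be omitted for single-sample
#'   or site-only VCFs; required when the file has several samples.
#' @param source_label Free-text label stored on the CallSet.
#' @return A [call_set()].
#' @export
read_vcf <- function(path, sample = NULL, source_label = basename(path)) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  n_header <- length(v@meta) + 1L  # meta lines plus the #CHROM line
  if (is.null(fix) || nrow(fix) == 0) {
    sid <- if (is.null(sample)) "sample" else sample
    return(call_set(NULL, sample_id = sid, source_label = source_label))
  }
  gt <- v@gt
  sample_names <- if (is.null(gt)) character() else colnames(gt)[-1]
  if (length(sample_names) == 0) {
    sid <- if (is.null(sample)) "sample" else sample
    gt_col <- NULL
  } else if (is.null(sample)) {
    if (length(sample_names) > 1)
      stop("multi-sample VCF; name one of: ",
           paste(sample_names, collapse = ", "))
    sid <- sample_names[1]
    gt_col <- 1L
  } else {
    gt_col <- match(sample, sample_names)
    if (is.na(gt_col))
      stop("sample '", sample, "' not found; VCF has: ",
           paste(sample_names, collapse = ", "))
    sid <- sample
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (any(is.na(pos)))
    stop("malformed POS at VCF line ", n_header + which(is.na(pos))[1])
  alt <- fix[, "ALT"]
  if (any(is.na(alt) | alt == "."))
    stop("missing ALT allele at VCF line ",
         n_header + which(is.na(alt) | alt == ".")[1])
  filters <- fix[, "FILTER"]
  filters[is.na(filters) | filters == "." | filters == "PASS"] <- ""
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  gt1 <- rep(NA_integer_, nrow(fix))
  gt2 <- rep(NA_integer_, nrow(fix))
  phased <- rep(FALSE, nrow(fix))
  depth <- rep(NA_integer_, nrow(fix))
  if (!is.null(gt_col) && !is.null(gt)) {
    gts <- vcfR::extract.gt(v, element = "GT")[, gt_col]
    g <- parse_gt(gts)
    gt1 <- g$gt1; gt2 <- g$gt2; phased <- g$phased
    fmt_has_dp <- grepl("(^|:)DP(:|$)", gt[, 1])
    if (any(fmt_has_dp)) {
      dps <- suppressWarnings(vcfR::extract.gt(v, element = "DP"))[, gt_col]
      depth <- suppressWarnings(as.integer(dps))
    }
  }

  rec <- data.frame(chrom = as.character(fix[, "CHROM"]), pos = pos,
                    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                    ref = toupper(fix[, "REF"]), alt = toupper(alt),
                    qual = qual, filters = filters, gt1 = g_or(gt1),
                    gt2 = g_or(gt2), phased = phased, depth = depth,
                    stringsAsFactors = FALSE)
  tryCatch(call_set(rec, sample_id = sid, source_label = source_label),
           error = function(e) {
             stop("while reading ", path, ": ", conditionMessage(e),
                  call. = FALSE)
           })
}

g_or <- function(x) if (is.null(x)) NA_integer_ else x

# "0/1", "0|1", "./1", ".", "1" -> allele index pair + phased flag
parse_gt <- function(gts) {
  n <- length(gts)
  gt1 <- rep(NA_integer_, n); gt2 <- rep(NA_integer_, n)
  phased <- grepl("|", gts, fixed = TRUE)
  phased[is.na(phased)] <- FALSE
  parts <- strsplit(ifelse(is.na(gts), ".", gts), "[/|]")
  a1 <- vapply(parts, function(p) p[1], character(1))
  a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".",
               character(1))
  gt1 <- suppressWarnings(as.integer(a1))
  gt2 <- suppressWarnings(as.integer(a2))
  list(gt1 = gt1, gt2 = gt2, phased = phased)
}

format_gt <- function(records) {
  a1 <- ifelse(is.na(records$gt1), ".", as.character(records$gt1))
  a2 <- ifelse(is.na(records$gt2), ".", as.character(records$gt2))
  sep <- ifelse(records$phased, "|", "/")
  gt <- paste0(a1, sep, a2)
  gt[is.na(records$gt1) & is.na(records$gt2)] <- "./."
  gt
}

#' Write a CallSet as a minimal VCF 4.2 file
#'
#' Emits CHROM POS ID REF ALT QUAL FILTER INFO FORMAT and one sample
#' column with GT:DP. The output round-trips through [read_vcf()]
#' field-by-field.
#'
#' @param x A [call_set()].
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contigs = NULL) {
  stopifnot(inherits(x, "CallSet"))
  r <- x$records
  header <- c("##fileformat=VCFv4.2",
              "##source=varbench",
              '##FILTER=<ID=PASS,Description="All filters passed">',
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(contigs)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contigs), as.integer(contigs)))
  }
  header <- c(header, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER",
                             "\tINFO\tFORMAT\t", x$sample_id))
  if (nrow(r) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  qual <- ifelse(is.na(r$qual), ".", formatC(r$qual, format = "g", digits = 6))
  filt <- ifelse(nzchar(r$filters), r$filters, "PASS")
  dp <- ifelse(is.na(r$depth), ".", as.character(r$depth))
  body <- paste(r$chrom, r$pos, r$id, r$ref, r$alt, qual, filt, ".",
                "GT:DP", paste0(format_gt(r), ":", dp), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
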