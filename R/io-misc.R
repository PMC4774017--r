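#' Read and write BED3 interval files
#'
#' BED intervals are 0-based half-open. `read_bed` returns the intervals
#' sorted by (chrom, start) but does not merge overlaps; normalization is
#' a separate, explicit step ([normalize_regions()]).
#'
#' @param path Path to a tab-separated file with at least 3 columns.
#' @return A region `data.frame` (see [regions()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) return(normalize_regions(empty_regions())[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("BED line ", bad[1], " has fewer than 3 tab-separated columns")
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  if (any(is.na(start) | is.na(end)))
    stop("BED line ", which(is.na(start) | is.na(end))[1],
         " has non-integer coordinates")
  if (any(end <= start))
    stop("BED line ", which(end <= start)[1], " has end <= start")
  out <- regions(chrom, start, end)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_bed
#' @param x A region `data.frame` or `RegionSet`.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(paste(x$chrom, x$start, x$end, sep = "\t"), path)
  invisible(path)
}

#' Read gene models from a refFlat-style table
#'
#' Expects the standard 11 refFlat columns (geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds) with 0-based half-open bounds and comma-terminated exon
#' lists. Exons are stored in genomic order regardless of strand; a
#' transcript with cdsStart == cdsEnd is non-coding (`NA` CDS bounds).
#'
#' @param path Path to the table (no header line).
#' @return A `data.frame` with one row per transcript: `gene`,
#'   `transcript_id`, `chrom`, `strand`, `cds_start`, `cds_end` and
#'   list-columns `exon_start`, `exon_end`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model table not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) < 11)
    stop("refFlat table needs 11 columns, found ", ncol(raw))
  parse_list <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  n <- nrow(raw)
  exon_start <- vector("list", n)
  exon_end <- vector("list", n)
  for (i in seq_len(n)) {
    es <- parse_list(raw[i, 10]); ee <- parse_list(raw[i, 11])
    cnt <- as.integer(raw[i, 9])
    if (length(es) != cnt || length(ee) != cnt)
      stop("exonCount inconsistent with exon lists for transcript '",
           raw[i, 2], "'")
    if (any(ee <= es) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop("exons must be sorted and non-overlapping for transcript '",
           raw[i, 2], "'")
    exon_start[[i]] <- es; exon_end[[i]] <- ee
  }
  cds_start <- as.integer(raw[, 7]); cds_end <- as.integer(raw[, 8])
  noncoding <- cds_start == cds_end
  cds_start[noncoding] <- NA_integer_; cds_end[noncoding] <- NA_integer_
  out <- data.frame(gene = raw[, 1], transcript_id = raw[, 2],
                    chrom = raw[, 3], strand = raw[, 4],
                    cds_start = cds_start, cds_end = cds_end,
                    stringsAsFactors = FALSE)
  out$exon_start <- exon_start
  out$exon_end <- exon_end
  if (!all(out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  out[order(out$chrom, vapply(out$exon_start, min, integer(1))), ,
      drop = FALSE]
}

#' @rdname read_gene_models
#' @param x A gene-model `data.frame` as returned by `read_gene_models`.
#' @export
write_gene_models <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    es <- x$exon_start[[i]]; ee <- x$exon_end[[i]]
    cs <- x$cds_start[i]; ce <- x$cds_end[i]
    if (is.na(cs)) { cs <- min(es); ce <- min(es) }
    paste(x$gene[i], x$transcript_id[i], x$chrom[i], x$strand[i],
          min(es), max(ee), cs, ce, length(es),
          paste0(paste(es, collapse = ","), ","),
          paste0(paste(ee, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene-set membership lists
#'
#' Simple two-column tab-separated format: set label, gene symbol.
#'
#' @param path Path to the table.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set table not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("gene set table needs 2 columns: set, gene")
  lapply(split(raw[, 2], raw[, 1]), function(g) sort(unique(g)))
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- unlist(lapply(names(sets), function(nm)
    paste(nm, sort(unique(sets[[nm]])), sep = "\t")), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA reference into named uppercase sequences
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Write a deterministic report table
#'
#' Columns whose names contain `sensitivity` or start with `ci_` are
#' fixed to 3 decimals; columns containing `percent`, `pct` or
#' `fraction` to 2 decimals. Row and column order are preserved, so a
#' rerun on identical inputs is byte-identical.
#'
#' @param rows A `data.frame`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  for (nm in names(rows)) {
    if (!is.numeric(rows[[nm]])) next
    if (grepl("sensitivity|^ci_", nm)) {
      rows[[nm]] <- ifelse(is.na(rows[[nm]]), NA,
                           sprintf("%.3f", rows[[nm]]))
    } else if (grepl("percent|pct|fraction", nm)) {
      rows[[nm]] <- ifelse(is.na(rows[[nm]]), NA,
                           sprintf("%.2f", rows[[nm]]))
    }
  }
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", na = "string",
                         pretty = TRUE)
  }
  invisible(path)
}
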