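#' Functional classification of a variant against one gene model
#'
#' Simplified transcript-aware annotation into the classes used for
#' stratified sensitivity: `splicing` (SNV within 2 bp of an internal
#' exon-intron boundary, on the intron side), `truncating` (stop-gained
#' SNV or frameshift indel in the CDS), `non-synonymous` (amino-acid
#' changing coding SNV, including stop-loss), `synonymous` (silent
#' coding SNV) and `other` (UTR, deep intronic, non-coding, in-frame
#' indel). Coding SNVs are translated on the codon containing the
#' variant, reverse-complemented for minus-strand genes.
#'
#' @param pos 1-based variant position (normalized representation).
#' @param ref,alt Single allele strings.
#' @param gene One row of a gene-model table (see [read_gene_models()]).
#' @param reference Named character vector of chromosome sequences.
#' @param splice_bp Intronic distance from an internal exon boundary that
#'   counts as splicing (default 2).
#' @return One of `"non-synonymous"`, `"synonymous"`, `"truncating"`,
#'   `"splicing"`, `"other"`.
#' @export
classify_function <- function(pos, ref, alt, gene, reference,
                              splice_bp = 2L) {
  es <- gene$exon_start[[1]]; ee <- gene$exon_end[[1]]
  span_lo <- min(es); span_hi <- max(ee)
  pos0 <- pos - 1L
  if (pos0 < span_lo - splice_bp || pos0 >= span_hi + splice_bp)
    stop("variant at ", gene$chrom, ":", pos, " lies outside gene ",
         gene$gene)
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  n_ex <- length(es)

  if (is_snv) {
    # internal junctions only: donor after every exon but the last,
    # acceptor before every exon but the first (genomic orientation)
    donors <- if (n_ex > 1) ee[-n_ex] else integer(0)
    acceptors <- if (n_ex > 1) es[-1] else integer(0)
    near_donor <- any(pos0 >= donors & pos0 < donors + splice_bp)
    near_acceptor <- any(pos0 >= acceptors - splice_bp & pos0 < acceptors)
    in_exon <- any(pos0 >= es & pos0 < ee)
    if (!in_exon && (near_donor || near_acceptor)) return("splicing")
  }

  if (is.na(gene$cds_start)) return("other")
  cdsp <- cds_positions(gene)

  if (!is_snv) {
    span <- pos0:(pos0 + nchar(ref) - 1L)
    indel_len <- abs(nchar(ref) - nchar(alt))
    touches_cds <- any(span %in% cdsp) ||
      (nchar(ref) == 1L && nchar(alt) > 1L && pos0 %in% cdsp)
    if (touches_cds && indel_len %% 3L != 0L) return("truncating")
    return("other")
  }

  i <- match(pos0, cdsp)
  if (is.na(i)) return("other")
  codon_idx <- (i - 1L) %/% 3L
  cpos <- cdsp[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  if (anyNA(cpos)) return("other")  # trailing partial codon
  seq <- reference[[gene$chrom]]
  bases <- substring(seq, cpos + 1L, cpos + 1L)
  mut <- bases
  mut[match(pos0, cpos)] <- alt
  if (gene$strand == "-") {
    bases <- chartr("ACGT", "TGCA", bases)
    mut <- chartr("ACGT", "TGCA", mut)
  }
  codon_ref <- paste(bases, collapse = "")
  codon_alt <- paste(mut, collapse = "")
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (is.null(aa_ref) || is.null(aa_alt)) return("other")
  if (aa_alt == "*" && aa_ref != "*") return("truncating")
  if (aa_alt == aa_ref) return("synonymous")
  "non-synonymous"
}

# 0-based genomic positions of CDS bases in translation order (reversed
# for minus-strand genes, so position 1..3 is the start codon)
cds_positions <- function(gene) {
  es <- gene$exon_start[[1]]; ee <- gene$exon_end[[1]]
  cs <- gene$cds_start; ce <- gene$cds_end
  pos <- unlist(lapply(seq_along(es), function(i) {
    lo <- max(es[i], cs); hi <- min(ee[i], ce)
    if (hi > lo) seq.int(lo, hi - 1L) else integer(0)
  }))
  if (gene$strand == "-") rev(pos) else pos
}

# translation of a gene's full CDS from a reference (used by the
# generator to validate planted genes; tests use Biostrings directly)
cds_sequence <- function(gene, reference) {
  cdsp <- cds_positions(gene)
  seq <- reference[[gene$chrom]]
  bases <- substring(seq, cdsp + 1L, cdsp + 1L)
  if (gene$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  paste(bases, collapse = "")
}
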