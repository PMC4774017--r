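#' Choose one transcript per gene
#'
#' When several transcripts are supplied for a gene, the one with the
#' longest CDS is used (ties broken by transcript_id) so that downstream
#' stratification is deterministic; the others are returned as
#' alternates.
#'
#' @param gene_models Transcript table from [read_gene_models()].
#' @return List with `primary` (one row per gene) and `alternates`.
#' @export
pick_transcripts <- function(gene_models) {
  cds_len <- vapply(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, , drop = FALSE]
    if (is.na(g$cds_start)) 0L else length(cds_positions(g))
  }, integer(1))
  ord <- order(gene_models$gene, -cds_len, gene_models$transcript_id)
  gm <- gene_models[ord, , drop = FALSE]
  primary <- gm[!duplicated(gm$gene), , drop = FALSE]
  alternates <- gm[duplicated(gm$gene), , drop = FALSE]
  list(primary = primary, alternates = alternates)
}

# function class + gene for each truth record of a MatchResult
annotate_truth_function <- function(match, gene_models, reference,
                                    splice_bp = 2L) {
  t_calls <- match$calls[match$calls$role == "truth", , drop = FALSE]
  gm <- pick_transcripts(gene_models)$primary
  span_lo <- vapply(gm$exon_start, min, integer(1))
  span_hi <- vapply(gm$exon_end, max, integer(1))
  fn <- rep("other", nrow(t_calls))
  gene <- rep(NA_character_, nrow(t_calls))
  for (i in seq_len(nrow(t_calls))) {
    pos0 <- t_calls$pos[i] - 1L
    hits <- which(gm$chrom == t_calls$chrom[i] & pos0 >= span_lo &
                    pos0 < span_hi)
    if (length(hits) == 0) next
    g <- hits[1]
    gene[i] <- gm$gene[g]
    fn[i] <- classify_function(t_calls$pos[i], t_calls$ref[i],
                               t_calls$alt[i], gm[g, , drop = FALSE],
                               reference, splice_bp = splice_bp)
  }
  t_calls$fn_class <- fn
  t_calls$gene <- gene
  t_calls
}

#' Stratified sensitivity table with Wilson 95% confidence intervals
#'
#' Builds the per-(functional class x gene set) sensitivity table plus a
#' whole-genome row. Sensitivity is TP / (TP + FNV) over truth variants
#' inside high-confidence regions; each cell carries a Wilson score
#' interval ([binomial_ci()]). A stratum with no truth variants is
#' emitted with missing sensitivity. Genotype-discordant allele matches
#' count as TP here (they are reported separately as genotype
#' diagnostics by [classify_calls()]).
#'
#' @param match A `MatchResult` from [classify_calls()].
#' @param gene_models Transcript table ([read_gene_models()]).
#' @param gene_sets Named list of gene-symbol vectors.
#' @param reference Named character vector of chromosome sequences.
#' @param level Confidence level for the intervals.
#' @param splice_bp Splicing distance passed to [classify_function()].
#' @return `data.frame` with columns `fn_class`, `gene_set`, `tp`, `fn`,
#'   `sensitivity`, `ci_low`, `ci_high`.
#' @export
stratified_sensitivity <- function(match, gene_models, gene_sets,
                                   reference, level = 0.95,
                                   splice_bp = 2L) {
  ann <- annotate_truth_function(match, gene_models, reference,
                                 splice_bp = splice_bp)
  ann <- ann[ann$class %in% c("TP", "FNV"), , drop = FALSE]
  classes <- c("non-synonymous", "synonymous", "truncating", "splicing",
               "other")
  rows <- list()
  for (set_name in names(gene_sets)) {
    members <- gene_sets[[set_name]]
    for (cl in classes) {
      sub <- ann[!is.na(ann$gene) & ann$gene %in% members &
                   ann$fn_class == cl, , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        stratum_row(cl, set_name, sum(sub$class == "TP"),
                    sum(sub$class == "FNV"), level)
    }
  }
  rows[[length(rows) + 1L]] <-
    stratum_row("whole-genome", "N/A", sum(ann$class == "TP"),
                sum(ann$class == "FNV"), level)
  do.call(rbind, rows)
}

stratum_row <- function(cl, set_name, tp, fn, level) {
  if (tp + fn > 0) {
    ci <- binomial_ci(tp, tp + fn, level)
    data.frame(fn_class = cl, gene_set = set_name, tp = tp, fn = fn,
               sensitivity = ci$estimate, ci_low = ci$low,
               ci_high = ci$high, stringsAsFactors = FALSE)
  } else {
    data.frame(fn_class = cl, gene_set = set_name, tp = 0L, fn = 0L,
               sensitivity = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, stringsAsFactors = FALSE)
  }
}

#' Attribute causes to false negative variants
#'
#' Causes are assigned non-exclusively to every FNV: `filtered` when the
#' query contains a matching raw call with a non-empty filter set;
#' `low_coverage` when site depth is below `depth_threshold` (10, the
#' read-coverage rule); `high_gc` when the reference GC fraction in a
#' centered window exceeds `gc_threshold` (0.75); `repeat_<class>` for
#' each repeat track containing the site; `unexplained` when none apply.
#'
#' @param match A `MatchResult`; its query side must be the raw
#'   (pre-filtered) call set, as produced by [classify_calls()] on a
#'   query that retains filtered records.
#' @param depth_source Optional `data.frame(chrom, pos, depth)` giving
#'   site depth; when absent, the matching raw query call's DP is used.
#' @param repeat_tracks Named list of region tables, one per repeat
#'   class.
#' @param reference Named character vector of chromosome sequences
#'   (needed for the GC window).
#' @param gc_window Width in bp of the GC window centered on the site.
#' @param depth_threshold,gc_threshold Rule cutoffs.
#' @return List with `causes` (one row per FNV, logical cause columns)
#'   and `summary` (fraction of FNVs per cause).
#' @export
attribute_fn_causes <- function(match, depth_source = NULL,
                                repeat_tracks = list(), reference = NULL,
                                gc_window = 100L, depth_threshold = 10L,
                                gc_threshold = 0.75) {
  calls <- match$calls
  fnv <- calls[calls$role == "truth" & calls$class == "FNV", , drop = FALSE]
  qraw <- calls[calls$role == "query", , drop = FALSE]
  out <- data.frame(variant_id = fnv$variant_id, chrom = fnv$chrom,
                    pos = fnv$pos, ref = fnv$ref, alt = fnv$alt,
                    stringsAsFactors = FALSE)
  n <- nrow(fnv)
  fk <- variant_key(fnv)
  qk <- variant_key(qraw)
  mi <- match(fk, qk)
  raw_filters <- ifelse(is.na(mi), "", qraw$filters[mi])
  out$filter_labels <- raw_filters
  out$filtered <- nzchar(raw_filters)

  depth <- rep(NA_integer_, n)
  if (!is.null(depth_source)) {
    dk <- paste(depth_source$chrom, depth_source$pos)
    depth <- depth_source$depth[match(paste(fnv$chrom, fnv$pos), dk)]
  }
  depth[is.na(depth) & !is.na(mi)] <- qraw$depth[mi[is.na(depth) & !is.na(mi)]]
  out$depth <- depth
  out$low_coverage <- !is.na(depth) & depth < depth_threshold

  out$high_gc <- rep(FALSE, n)
  if (!is.null(reference) && n > 0) {
    half <- gc_window %/% 2L
    for (i in seq_len(n)) {
      seq <- reference[[fnv$chrom[i]]]
      lo <- max(1L, fnv$pos[i] - half)
      hi <- min(nchar(seq), fnv$pos[i] + half - 1L)
      win <- substr(seq, lo, hi)
      gc <- nchar(gsub("[^GC]", "", win)) / nchar(win)
      out$high_gc[i] <- gc > gc_threshold
    }
  }

  rep_cols <- character(0)
  for (cls in names(repeat_tracks)) {
    col <- paste0("repeat_", cls)
    out[[col]] <- region_contains(normalize_regions(repeat_tracks[[cls]]),
                                  fnv$chrom, fnv$pos)
    rep_cols <- c(rep_cols, col)
  }
  cause_cols <- c("filtered", "low_coverage", "high_gc", rep_cols)
  explained <- Reduce(`|`, lapply(cause_cols, function(cc) out[[cc]]),
                      rep(FALSE, n))
  out$unexplained <- !explained
  summary <- vapply(c(cause_cols, "unexplained"), function(cc) {
    if (n == 0) NA_real_ else mean(out[[cc]])
  }, numeric(1))
  list(causes = out, summary = summary)
}

#' Specificity of filter labels against the truth set
#'
#' For every combination of filter labels observed on in-region filtered
#' query calls, counts the sites and the fraction whose filtered allele
#' is absent from the truth set (likely false positives; the complement
#' are wrongly filtered true variants). Aggregate rows summarize sites
#' carrying exactly one filter, more than one filter, and all filtered
#' sites.
#'
#' @param match A `MatchResult` whose query side retained filtered
#'   records (the default behaviour of [classify_calls()]).
#' @return `data.frame` with columns `filter_combo`, `n_sites`, `n_fp`,
#'   `fraction_fp`; aggregates use combo labels `<any single>`,
#'   `<multiple>`, `<all filtered>`. Empty when nothing was filtered.
#' @export
filter_specificity <- function(match) {
  calls <- match$calls
  filt <- calls[calls$role == "query" & calls$class == "FILTERED", ,
                drop = FALSE]
  if (nrow(filt) == 0) {
    return(data.frame(filter_combo = character(), n_sites = integer(),
                      n_fp = integer(), fraction_fp = numeric(),
                      stringsAsFactors = FALSE))
  }
  truth_keys <- variant_key(calls[calls$role == "truth", , drop = FALSE])
  labels <- filter_labels(filt$filters)
  combo <- vapply(labels, paste, character(1), collapse = ";")
  is_fp <- !(variant_key(filt) %in% truth_keys)
  n_labels <- lengths(labels)
  one_combo <- function(name, sel) {
    data.frame(filter_combo = name, n_sites = sum(sel),
               n_fp = sum(is_fp[sel]),
               fraction_fp = if (sum(sel)) mean(is_fp[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(combo)), function(cb) one_combo(cb, combo == cb))
  rows <- c(rows, list(one_combo("<any single>", n_labels == 1),
                       one_combo("<multiple>", n_labels > 1),
                       one_combo("<all filtered>", rep(TRUE, nrow(filt)))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
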