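#' Classify query calls against truth calls within high-confidence regions
#'
#' Haplotype-aware benchmarking of one query call set against a truth
#' call set, restricted to high-confidence regions. Both call sets are
#' representation-normalized ([normalize_callset()]); records are matched
#' first exactly on (chrom, pos, ref, alt) and then, for the remainder,
#' by clustering nearby variants and testing haplotype-sequence
#' equivalence ([haplotype_match()]). Each truth record inside the
#' regions ends up `TP` or `FNV`; each passing query record inside the
#' regions ends up `TP` or `QV`; records outside the regions are
#' `OUTSIDE`; non-PASS query records are excluded from matching and
#' labelled `FILTERED` (they participate in false-negative cause
#' attribution, not in the sensitivity partition).
#'
#' An allele-exact match with a discordant genotype counts as `TP` with
#' `genotype_match = FALSE` and is additionally reported in the
#' `qv_genotype` diagnostic table; with `genotype_strict = TRUE` such
#' pairs are instead left unmatched (FNV + QV).
#'
#' @param query,truth [call_set()]s for the same sample.
#' @param hiconf High-confidence regions (anything [normalize_regions()]
#'   accepts).
#' @param reference Named character vector of chromosome sequences.
#' @param edge_bp Width of the "near the inside edge" flag: a variant is
#'   edge-flagged when its distance to the enclosing region boundary is
#'   at most `edge_bp - 1` bases (inclusive "within 50 bp" reading).
#' @param cluster_bp Maximum gap between variants clustered for
#'   haplotype comparison, and the window padding around each cluster.
#' @param genotype_strict Treat genotype-discordant allele matches as
#'   unmatched instead of TP-with-flag.
#' @param max_het Heterozygosity cap per cluster side (cost is 2^h).
#' @return A `MatchResult`: list with `calls` (per-variant table),
#'   `counts` (partition tallies), `qv_genotype` (genotype-discordant
#'   diagnostics) and `params`.
#' @export
classify_calls <- function(query, truth, hiconf, reference, edge_bp = 50L,
                           cluster_bp = 50L, genotype_strict = FALSE,
                           max_het = 12L) {
  hiconf <- normalize_regions(hiconf)
  tn <- normalize_callset(truth, reference)$records
  qn <- normalize_callset(query, reference)$records

  t_df <- annotate_side(tn, "truth", hiconf, edge_bp)
  q_df <- annotate_side(qn, "query", hiconf, edge_bp)
  q_df$pass <- is_pass(q_df$filters)

  t_pool <- which(t_df$in_region)
  q_pool <- which(q_df$in_region & q_df$pass)

  init_cols <- function(df) {
    n <- nrow(df)
    df$matched <- rep(FALSE, n)
    df$genotype_match <- rep(NA, n)
    df$partner <- rep(NA_character_, n)
    df$match_type <- rep(NA_character_, n)
    df
  }
  t_df <- init_cols(t_df)
  q_df <- init_cols(q_df)

  # -- pass 1: exact allele matching, paired by multiplicity ------------
  tk <- variant_key(t_df[t_pool, , drop = FALSE])
  qk <- variant_key(q_df[q_pool, , drop = FALSE])
  for (key in intersect(tk, qk)) {
    ti <- t_pool[tk == key]; qi <- q_pool[qk == key]
    m <- min(length(ti), length(qi))
    for (j in seq_len(m)) {
      it <- ti[j]; iq <- qi[j]
      gm <- same_genotype(t_df$gt1[it], t_df$gt2[it],
                          q_df$gt1[iq], q_df$gt2[iq])
      if (genotype_strict && !gm) next
      t_df$matched[it] <- TRUE; q_df$matched[iq] <- TRUE
      t_df$genotype_match[it] <- gm; q_df$genotype_match[iq] <- gm
      t_df$partner[it] <- q_df$variant_id[iq]
      q_df$partner[iq] <- t_df$variant_id[it]
      t_df$match_type[it] <- "exact"; q_df$match_type[iq] <- "exact"
    }
  }

  # -- pass 2: haplotype-aware rescue of clustered representations ------
  un_t <- t_pool[!t_df$matched[t_pool]]
  un_q <- q_pool[!q_df$matched[q_pool]]
  if (length(un_t) + length(un_q) > 0) {
    side_pts <- function(side, idx, df) {
      if (length(idx) == 0) return(NULL)
      data.frame(side = side, idx = idx, chrom = df$chrom[idx],
                 pos = df$pos[idx],
                 end = df$pos[idx] + nchar(df$ref[idx]) - 1L,
                 stringsAsFactors = FALSE)
    }
    pts <- rbind(side_pts("t", un_t, t_df), side_pts("q", un_q, q_df))
    pts <- pts[order(pts$chrom, pts$pos), , drop = FALSE]
    cl <- integer(nrow(pts))
    cl[1] <- 1L
    chain_end <- pts$end[1]
    for (i in seq_len(nrow(pts))[-1]) {
      if (pts$chrom[i] != pts$chrom[i - 1L] ||
          pts$pos[i] - chain_end > cluster_bp) {
        cl[i] <- cl[i - 1L] + 1L
        chain_end <- pts$end[i]
      } else {
        cl[i] <- cl[i - 1L]
        chain_end <- max(chain_end, pts$end[i])
      }
    }
    for (cid in unique(cl)) {
      members <- pts[cl == cid, , drop = FALSE]
      ws <- max(0L, min(members$pos) - 1L - cluster_bp)
      we <- max(members$end) + cluster_bp
      cn <- members$chrom[1]
      tt <- t_df[t_pool, , drop = FALSE]
      tt <- tt[tt$chrom == cn & tt$pos - 1L < we &
                 tt$pos - 1L + nchar(tt$ref) > ws, , drop = FALSE]
      qq <- q_df[q_pool, , drop = FALSE]
      qq <- qq[qq$chrom == cn & qq$pos - 1L < we &
                 qq$pos - 1L + nchar(qq$ref) > ws, , drop = FALSE]
      hm <- haplotype_match(tt, qq, list(chrom = cn, start = ws, end = we),
                            reference, max_het = max_het)
      if (hm$match) {
        mt <- members$idx[members$side == "t"]
        mq <- members$idx[members$side == "q"]
        t_df$matched[mt] <- TRUE; t_df$genotype_match[mt] <- TRUE
        t_df$match_type[mt] <- "haplotype"
        t_df$partner[mt] <- paste(qq$variant_id, collapse = ",")
        q_df$matched[mq] <- TRUE; q_df$genotype_match[mq] <- TRUE
        q_df$match_type[mq] <- "haplotype"
        q_df$partner[mq] <- paste(tt$variant_id, collapse = ",")
      }
    }
  }

  t_df$class <- ifelse(!t_df$in_region, "OUTSIDE",
                       ifelse(t_df$matched, "TP", "FNV"))
  q_df$class <- ifelse(!q_df$in_region, "OUTSIDE",
                       ifelse(!q_df$pass, "FILTERED",
                              ifelse(q_df$matched, "TP", "QV")))

  counts <- list(
    truth_in_region = sum(t_df$in_region),
    query_in_region = sum(q_df$in_region & q_df$pass),
    tp_truth = sum(t_df$class == "TP"),
    fnv = sum(t_df$class == "FNV"),
    tp_query = sum(q_df$class == "TP"),
    qv = sum(q_df$class == "QV"),
    truth_outside = sum(!t_df$in_region),
    query_outside = sum(!q_df$in_region),
    query_filtered = sum(q_df$class == "FILTERED"))
  stopifnot(counts$truth_in_region == counts$tp_truth + counts$fnv,
            counts$query_in_region == counts$tp_query + counts$qv)

  qv_genotype <- q_df[q_df$class == "TP" & !is.na(q_df$genotype_match) &
                        !q_df$genotype_match, , drop = FALSE]

  keep <- c("variant_id", "role", "chrom", "pos", "ref", "alt", "gt1",
            "gt2", "filters", "depth", "class", "genotype_match",
            "edge_flag", "match_type", "partner")
  calls <- rbind(t_df[, keep, drop = FALSE], q_df[, keep, drop = FALSE])
  rownames(calls) <- NULL
  structure(list(calls = calls, counts = counts,
                 qv_genotype = qv_genotype[, keep, drop = FALSE],
                 params = list(edge_bp = edge_bp, cluster_bp = cluster_bp,
                               genotype_strict = genotype_strict,
                               max_het = max_het)),
            class = "MatchResult")
}

annotate_side <- function(r, role, hiconf, edge_bp) {
  r$role <- rep(role, nrow(r))
  r$variant_id <- if (nrow(r)) paste0(substr(role, 1, 1), seq_len(nrow(r)))
                  else character(0)
  ed <- edge_distance(hiconf, r$chrom, r$pos)
  r$in_region <- !is.na(ed)
  r$edge_flag <- !is.na(ed) & ed <= edge_bp - 1L
  r
}

same_genotype <- function(t1, t2, q1, q2) {
  norm <- function(a, b) sort(c(ifelse(is.na(a), 0L, a),
                                ifelse(is.na(b), 0L, b)))
  identical(norm(t1, t2), norm(q1, q2))
}

#' @export
print.MatchResult <- function(x, ...) {
  c <- x$counts
  cat(sprintf(paste0("MatchResult: truth in-region %d (TP %d, FNV %d); ",
                     "query in-region %d (TP %d, QV %d); filtered %d\n"),
              c$truth_in_region, c$tp_truth, c$fnv, c$query_in_region,
              c$tp_query, c$qv, c$query_filtered))
  invisible(x)
}
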