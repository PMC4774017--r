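#' Expected pipeline outputs from bundle bookkeeping
#'
#' Recomputes, by direct counting over the generator's bookkeeping
#' tables — without touching the comparison, interval or stratification
#' code — the tables the pipeline should reproduce on the bundle:
#' Table-1-style stratum counts, FN-cause fractions, per-gene and
#' per-set coverage, low-confidence reason percentages, and the
#' systematic-error site list with database counts. Tests compare
#' pipeline output against these oracles.
#'
#' @param bundle A `TruthBundle` from [generate_bundle()].
#' @return List of reference tables: `strata`, `fn_causes`,
#'   `gene_coverage`, `set_coverage`, `lowconf_reasons`, `syserr_sites`,
#'   `db_counts`, `qv_expected`, `filtered_fp_fraction`.
#' @export
expected_metrics <- function(bundle) {
  v <- bundle$bookkeeping$variants
  fc <- bundle$bookkeeping$false_calls
  sets <- bundle$gene_sets
  classes <- c("non-synonymous", "synonymous", "truncating", "splicing")

  strata <- list()
  for (set_name in names(sets)) {
    members <- sets[[set_name]]
    for (cl in classes) {
      sel <- v$in_hiconf & !is.na(v$gene) & v$gene %in% members &
        v$class == cl
      strata[[length(strata) + 1L]] <- data.frame(
        fn_class = cl, gene_set = set_name,
        tp = sum(sel & v$fate == "kept"),
        fn = sum(sel & v$fate != "kept"), stringsAsFactors = FALSE)
    }
  }
  strata[[length(strata) + 1L]] <- data.frame(
    fn_class = "whole-genome", gene_set = "N/A",
    tp = sum(v$in_hiconf & v$fate == "kept"),
    fn = sum(v$in_hiconf & v$fate != "kept"), stringsAsFactors = FALSE)
  strata <- do.call(rbind, strata)
  strata$sensitivity <- ifelse(strata$tp + strata$fn > 0,
                               strata$tp / (strata$tp + strata$fn),
                               NA_real_)

  miss <- v[v$in_hiconf & v$fate != "kept", , drop = FALSE]
  fn_causes <- c(
    filtered = mean(miss$fate == "miss_filtered"),
    low_coverage = mean(miss$fate == "miss_lowcov"),
    high_gc = mean(miss$gc_flag),
    repeat_sine = mean(miss$sine_flag))

  gcov <- bundle$bookkeeping$gene_coverage
  set_cov <- do.call(rbind, lapply(names(sets), function(set_name) {
    sub <- gcov[gcov$gene %in% sets[[set_name]], , drop = FALSE]
    data.frame(gene_set = set_name,
               fraction_base_weighted =
                 sum(sub$covered_bases) / sum(sub$exonic_bases),
               n_fully_covered = sum(sub$fraction == 1),
               n_below_half = sum(sub$fraction < 0.5),
               stringsAsFactors = FALSE)
  }))

  db_names <- names(bundle$databases)
  ss <- bundle$bookkeeping$syserr_sites
  in_cols <- paste0("in_", db_names)
  any_db <- Reduce(`|`, lapply(in_cols, function(cc) ss[[cc]]),
                   rep(FALSE, nrow(ss)))
  db_counts <- rbind(
    data.frame(database = "<total>", n_sites = nrow(ss)),
    data.frame(database = "<any database>", n_sites = sum(any_db)),
    do.call(rbind, lapply(db_names, function(db)
      data.frame(database = db, n_sites = sum(ss[[paste0("in_", db)]])))))

  n_filtered_true <- sum(v$in_hiconf & v$fate == "miss_filtered")
  n_filtered_fp <- sum(nzchar(fc$filters))
  list(strata = strata,
       fn_causes = fn_causes,
       gene_coverage = gcov,
       set_coverage = set_cov,
       lowconf_reasons = bundle$bookkeeping$lowconf_reasons,
       syserr_sites = ss,
       db_counts = db_counts,
       qv_expected = sum(!nzchar(fc$filters)),
       filtered_fp_fraction =
         n_filtered_fp / (n_filtered_fp + n_filtered_true))
}
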