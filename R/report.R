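#' Write a TruthBundle to a directory of standard-format files
#'
#' Emits the bundle in the formats the pipeline readers consume:
#' FASTA reference, truth/query/panel/database VCFs, high-confidence
#' and homozygous-reference BEDs, refFlat gene models, gene-set lists,
#' per-class repeat and reason BEDs, a depth track and the bookkeeping
#' TSVs. Output is deterministic: the same bundle writes byte-identical
#' files.
#'
#' @param bundle A `TruthBundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  contigs <- nchar(bundle$reference)
  write_fasta(bundle$reference, p("reference.fa"))
  write_vcf(bundle$truth, p("truth.vcf"), contigs)
  write_vcf(bundle$query, p("query.vcf"), contigs)
  write_bed(bundle$hiconf, p("hiconf.bed"))
  write_bed(bundle$homref, p("homref.bed"))
  write_gene_models(bundle$gene_models, p("genes.refflat"))
  write_gene_sets(bundle$gene_sets, p("gene_sets.tsv"))
  dir.create(p("repeats"), showWarnings = FALSE)
  for (cls in names(bundle$repeat_tracks))
    write_bed(bundle$repeat_tracks[[cls]],
              p("repeats", paste0(cls, ".bed")))
  dir.create(p("reasons"), showWarnings = FALSE)
  for (i in seq_along(bundle$reason_tracks))
    write_bed(bundle$reason_tracks[[i]],
              p("reasons", sprintf("%02d_%s.bed", i,
                                   names(bundle$reason_tracks)[i])))
  dir.create(p("panels"), showWarnings = FALSE)
  for (platform in names(bundle$panels)) {
    for (d in bundle$panels[[platform]]) {
      write_vcf(d, p("panels", paste0(platform, "__",
                                      d$source_label, ".vcf")), contigs)
    }
  }
  for (db in names(bundle$databases))
    write_vcf(bundle$databases[[db]], p(paste0("db_", db, ".vcf")),
              contigs)
  utils::write.table(bundle$depth_track, p("depth_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(p("bookkeeping"), showWarnings = FALSE)
  for (nm in c("variants", "false_calls", "gene_coverage",
               "lowconf_reasons", "syserr_sites")) {
    utils::write.table(bundle$bookkeeping[[nm]],
                       p("bookkeeping", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a written bundle back through the standard readers
#'
#' Reconstructs the pipeline inputs from a [write_bundle()] directory
#' using the package's format readers (the bookkeeping tables are also
#' reloaded for testing convenience).
#'
#' @param dir Directory written by [write_bundle()].
#' @return List of pipeline inputs mirroring the bundle fields.
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  repeats <- list()
  for (f in sort(list.files(p("repeats"), full.names = TRUE))) {
    repeats[[tools::file_path_sans_ext(basename(f))]] <- read_bed(f)
  }
  reasons <- list()
  for (f in sort(list.files(p("reasons"), full.names = TRUE))) {
    nm <- sub("^[0-9]+_", "", tools::file_path_sans_ext(basename(f)))
    reasons[[nm]] <- read_bed(f)
  }
  panel_files <- sort(list.files(p("panels"), full.names = TRUE))
  platforms <- unique(sub("__.*$", "", basename(panel_files)))
  panels <- lapply(platforms, function(platform) {
    fs <- panel_files[startsWith(basename(panel_files),
                                 paste0(platform, "__"))]
    lapply(fs, function(f)
      read_vcf(f, source_label =
                 sub("^.*__", "", tools::file_path_sans_ext(basename(f)))))
  })
  names(panels) <- platforms
  dbs <- list()
  for (f in sort(list.files(dir, pattern = "^db_.*\\.vcf$",
                            full.names = TRUE))) {
    nm <- sub("^db_", "", tools::file_path_sans_ext(basename(f)))
    dbs[[nm]] <- read_vcf(f, source_label = nm)
  }
  list(reference = read_fasta(p("reference.fa")),
       truth = read_vcf(p("truth.vcf"), source_label = "truth"),
       query = read_vcf(p("query.vcf"), source_label = "query"),
       hiconf = read_bed(p("hiconf.bed")),
       homref = read_bed(p("homref.bed")),
       gene_models = read_gene_models(p("genes.refflat")),
       gene_sets = read_gene_sets(p("gene_sets.tsv")),
       repeat_tracks = repeats,
       reason_tracks = reasons,
       panels = panels,
       databases = dbs,
       depth_track = utils::read.table(p("depth_track.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
}

#' Run the full benchmarking report on a bundle directory
#'
#' End-to-end orchestration: comparison (classification), stratified
#' sensitivity, FN-cause attribution, filter specificity, region
#' characterization, uniqueness/alignability context, and
#' systematic-error detection with database intersection. Each table is
#' written as a deterministic TSV in `out_dir` plus a JSON summary of
#' the headline numbers. A failing stage aborts with the stage name and
#' removes partial outputs.
#'
#' @param config List with `dir` (bundle directory), `out_dir`, and
#'   optional parameter overrides: `edge_bp`, `cluster_bp`,
#'   `genotype_strict`, `gc_window`, `k_unique`, `k_align`,
#'   `max_mismatch`, `min_qual`, `ci_level`. Unknown keys are rejected.
#' @param quiet Suppress per-stage record-count logging.
#' @return List with every computed table (invisibly also written to
#'   `out_dir`).
#' @export
run_report <- function(config, quiet = FALSE) {
  allowed <- c("dir", "out_dir", "edge_bp", "cluster_bp",
               "genotype_strict", "gc_window", "k_unique", "k_align",
               "max_mismatch", "min_qual", "ci_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$dir) || !dir.exists(config$dir))
    stop("config$dir must name an existing bundle directory")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  defaults <- list(edge_bp = 50L, cluster_bp = 50L,
                   genotype_strict = FALSE, gc_window = 100L,
                   k_unique = 35L, k_align = 100L, max_mismatch = 2L,
                   min_qual = 2, ci_level = 0.95)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    write_report(tab, path, "tsv")
    written <<- c(written, path)
  }

  inp <- stage("load", read_bundle(config$dir))
  log("load: %d truth, %d query records", n_records(inp$truth),
      n_records(inp$query))

  match <- stage("compare", classify_calls(
    inp$query, inp$truth, inp$hiconf, inp$reference,
    edge_bp = config$edge_bp, cluster_bp = config$cluster_bp,
    genotype_strict = config$genotype_strict))
  log("compare: TP %d FNV %d QV %d", match$counts$tp_truth,
      match$counts$fnv, match$counts$qv)
  emit(match$calls, "match.tsv")

  strata <- stage("stratify", stratified_sensitivity(
    match, inp$gene_models, inp$gene_sets, inp$reference,
    level = config$ci_level))
  emit(strata, "table1_sensitivity.tsv")
  fn_causes <- stage("fn_causes", attribute_fn_causes(
    match, depth_source = inp$depth_track,
    repeat_tracks = inp$repeat_tracks, reference = inp$reference,
    gc_window = config$gc_window))
  emit(fn_causes$causes, "fn_causes.tsv")
  fspec <- stage("filter_specificity", filter_specificity(match))
  emit(fspec, "filter_specificity.tsv")

  gcov <- stage("regionchar", gene_coverage(
    inp$gene_models, inp$gene_sets, inp$hiconf))
  emit(gcov$genes, "gene_coverage.tsv")
  emit(gcov$sets, "gene_set_coverage.tsv")
  excov <- stage("regionchar", exon_position_coverage(
    inp$gene_models, inp$hiconf))
  emit(excov$classes, "exon_class_coverage.tsv")
  repfrac <- stage("regionchar", repeat_fraction_in_hiconf(
    inp$repeat_tracks, inp$hiconf))
  emit(repfrac, "repeat_fractions.tsv")
  chrom_spans <- regions(names(inp$reference), 0,
                         nchar(inp$reference))
  lowconf <- stage("regionchar", lowconf_reasons(
    region_subtract(chrom_spans, inp$hiconf), inp$reason_tracks))
  emit(lowconf, "table3_lowconf_reasons.tsv")

  track35 <- stage("uniqueness", exact_uniqueness(
    inp$reference, k = config$k_unique))
  track100 <- stage("uniqueness", alignability(
    inp$reference, k = config$k_align,
    max_mismatch = config$max_mismatch))
  truth_norm <- stage("uniqueness",
                      normalize_callset(inp$truth, inp$reference))
  ctx <- stage("uniqueness", variant_context(
    truth_norm, inp$hiconf, track35, track100))
  emit(ctx$summary, "table4_context.tsv")

  syserr <- stage("syserr", detect_systematic_errors(
    inp$homref, inp$panels, inp$reference, min_qual = config$min_qual))
  dbx <- stage("syserr", db_intersect(syserr, inp$databases,
                                      inp$reference))
  emit(dbx$counts, "table2_syserr.tsv")
  emit(dbx$sites, "syserr_sites.tsv")

  wg <- strata[strata$fn_class == "whole-genome", ]
  summary <- list(
    truth_in_region = match$counts$truth_in_region,
    tp = match$counts$tp_truth, fnv = match$counts$fnv,
    qv = match$counts$qv,
    whole_genome_sensitivity = wg$sensitivity[1],
    syserr_sites = nrow(syserr),
    syserr_in_any_db =
      dbx$counts$n_sites[dbx$counts$database == "<any database>"])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(match = match, strata = strata, fn_causes = fn_causes,
                 filter_specificity = fspec, gene_coverage = gcov,
                 exon_coverage = excov, repeat_fractions = repfrac,
                 lowconf = lowconf, context = ctx, syserr = syserr,
                 db = dbx, summary = summary))
}
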