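#' Configuration for the synthetic benchmarking bundle
#'
#' Defines every parameter of the generator: genome size, planted
#' difficult features, gene structure, per-stratum truth-variant counts
#' and target sensitivities, error-mode rates, the low-confidence
#' reason plan, and the platform-panel / database specification.
#' Identical seed and configuration yield a byte-identical bundle.
#'
#' @param seed Integer seed for the single pseudo-random stream.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_genes Number of genes placed outside difficult features.
#' @param exon_count_range,exon_length_range,intron_length_range Gene
#'   structure draws (uniform integer ranges).
#' @param n_homopolymers,homopolymer_length_range Planted homopolymer
#'   runs (all exceed the 10 bp "long homopolymer" rule, so all are
#'   excluded from the high-confidence regions).
#' @param n_tandem_repeats,tandem_unit_range,tandem_copies_range Planted
#'   tandem repeats.
#' @param n_duplications,duplication_length,duplication_mismatches
#'   Duplicated blocks (segmental-duplication analogue); copies differ
#'   at the given number of positions.
#' @param n_gc_windows,gc_window_length,gc_fraction GC-rich windows
#'   (kept inside high-confidence regions; they model coverage dropout,
#'   not exclusion).
#' @param feature_margin Exclusion margin in bp around planted features.
#' @param exon_exclusion_prob,exon_exclusion_span Per-gene probability
#'   of masking one exon stretch out of the high-confidence regions, and
#'   the fraction range of the exon masked.
#' @param lowconf_reason_plan Named numeric vector of target fractions
#'   of low-confidence bases per reason, in precedence order.
#' @param n_variants Named list of truth-variant counts per stratum
#'   (`non-synonymous`, `synonymous`, `truncating`, `splicing`,
#'   `intergenic`).
#' @param sensitivity Named list of per-stratum detection probabilities
#'   for the query call set.
#' @param het_fraction Fraction of heterozygous truth genotypes.
#' @param miss_filtered_fraction Of missed variants, the fraction that
#'   are present in the query but removed by filtering (the rest are
#'   absent with low coverage).
#' @param filter_label_pool,multi_filter_fraction Filter labels drawn
#'   for filtered records and the fraction carrying two labels.
#' @param genotype_error_rate Fraction of kept variants whose query
#'   genotype is wrong (het/hom flip) despite a correct allele.
#' @param n_mnv_pairs Adjacent phased SNV pairs whose query
#'   representation is rewritten as a single MNV (representation
#'   invariance plant).
#' @param n_fp_pass,n_fp_filtered Planted false calls: passing (become
#'   QVs) and filtered (exercise filter specificity).
#' @param indel_fraction Fraction of intergenic variants planted as
#'   1-3 bp indels.
#' @param truncating_indel_fraction Fraction of truncating variants
#'   planted as frameshift indels rather than stop-gain SNVs.
#' @param depth_mean Negative-binomial mean depth for called sites.
#' @param sine_fraction Fraction of the genome covered by the planted
#'   SINE-like repeat track (inside high-confidence regions).
#' @param platforms Named integer vector: datasets per platform.
#' @param n_syserr_sites,syserr_indel_fraction Planted systematic-error
#'   sites and the fraction that are homopolymer-style 1 bp indels.
#' @param n_noise_sites Sites with sub-threshold evidence (at most two
#'   datasets of a platform) that must not be detected.
#' @param db_fractions Named numeric vector: fraction of systematic
#'   sites present (with matching alt) in each synthetic database.
#' @param n_db_decoys Database records at systematic sites with a
#'   *different* alt allele (must not match) per database.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 500000L,
                       n_genes = 60L,
                       exon_count_range = c(2L, 9L),
                       exon_length_range = c(120L, 240L),
                       intron_length_range = c(200L, 1200L),
                       n_homopolymers = 20L,
                       homopolymer_length_range = c(12L, 30L),
                       n_tandem_repeats = 15L,
                       tandem_unit_range = c(2L, 6L),
                       tandem_copies_range = c(8L, 30L),
                       n_duplications = 4L,
                       duplication_length = 800L,
                       duplication_mismatches = 3L,
                       n_gc_windows = 10L,
                       gc_window_length = 150L,
                       gc_fraction = 0.85,
                       feature_margin = 10L,
                       exon_exclusion_prob = 0.35,
                       exon_exclusion_span = c(0.3, 0.7),
                       lowconf_reason_plan = c(dbvar_sv = 0.47,
                                               str_repseq = 0.34,
                                               segdup = 0.15,
                                               simple_repeat = 0.04),
                       n_variants = list(`non-synonymous` = 400L,
                                         synonymous = 400L,
                                         truncating = 47L,
                                         splicing = 60L,
                                         intergenic = 2000L),
                       sensitivity = list(`non-synonymous` = 0.95,
                                          synonymous = 0.97,
                                          truncating = 0.9,
                                          splicing = 0.9,
                                          intergenic = 0.95),
                       het_fraction = 0.6,
                       miss_filtered_fraction = 0.87,
                       filter_label_pool = c("strandBias", "Q20",
                                             "badReads", "MQ",
                                             "HapScore", "SC"),
                       multi_filter_fraction = 0.3,
                       genotype_error_rate = 0.02,
                       n_mnv_pairs = 15L,
                       n_fp_pass = 25L,
                       n_fp_filtered = 30L,
                       indel_fraction = 0.15,
                       truncating_indel_fraction = 0.3,
                       depth_mean = 30,
                       sine_fraction = 0.13,
                       platforms = c(ionproton = 4L, hiseq = 3L,
                                     solid = 2L),
                       n_syserr_sites = 25L,
                       syserr_indel_fraction = 0.2,
                       n_noise_sites = 8L,
                       db_fractions = c(db_common = 0.4, db_clin = 0.12),
                       n_db_decoys = 6L) {
  cfg <- as.list(environment())
  rates <- c(unlist(cfg$sensitivity), cfg$miss_filtered_fraction,
             cfg$multi_filter_fraction, cfg$genotype_error_rate,
             cfg$het_fraction, cfg$db_fractions, cfg$sine_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(unlist(cfg$n_variants) < 0)) stop("variant counts must be >= 0")
  if (!setequal(names(cfg$n_variants), names(cfg$sensitivity)))
    stop("n_variants and sensitivity must cover the same strata")
  if (abs(sum(cfg$lowconf_reason_plan) - 1) > 1e-9)
    stop("lowconf_reason_plan fractions must sum to 1")
  structure(cfg, class = "SimConfig")
}

BASES <- c("A", "C", "G", "T")
comp_base <- function(b) chartr("ACGT", "TGCA", b)

with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# ---------------------------------------------------------------------
# generate_bundle: the generator entry point
# ---------------------------------------------------------------------

#' Generate a synthetic benchmarking bundle
#'
#' Builds, from a seeded configuration, every input the pipeline needs —
#' reference, truth and query call sets, high-confidence and
#' homozygous-reference regions, gene models, gene sets, repeat and
#' reason tracks, platform panels and databases — together with
#' ground-truth bookkeeping tables computed by direct per-base counting
#' during construction (independent of the pipeline's interval and
#' matching code), which serve as oracles in tests.
#'
#' @param config A [sim_config()].
#' @return A `TruthBundle` list; see the fields in the implementation or
#'   the package vignette. `bundle$bookkeeping` holds the oracle tables.
#' @export
generate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  with_sim_seed(config$seed, build_bundle(config))
}

build_bundle <- function(cfg) {
  L <- cfg$chrom_length
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  chars <- lapply(chrom_names, function(cn) sample(BASES, L, replace = TRUE))
  names(chars) <- chrom_names
  # occupied intervals (features, genes) per chrom for placement
  occ <- lapply(chrom_names, function(cn) rep(FALSE, L))
  names(occ) <- chrom_names
  hic <- lapply(chrom_names, function(cn) rep(TRUE, L))
  names(hic) <- chrom_names

  alloc <- function(len, margin = cfg$feature_margin, tries = 500L) {
    for (t in seq_len(tries)) {
      cn <- sample(chrom_names, 1)
      start <- sample.int(L - len - 2L * margin, 1) + margin  # 0-based
      span <- (start - margin + 1L):(start + len + margin)
      if (!any(occ[[cn]][span])) {
        occ[[cn]][span] <<- TRUE
        return(list(chrom = cn, start = start))
      }
    }
    stop("infeasible config: no room left for a feature of length ", len)
  }

  features <- list()
  add_feature <- function(cn, start, end, type) {
    features[[length(features) + 1L]] <<-
      data.frame(chrom = cn, start = start, end = end, type = type,
                 stringsAsFactors = FALSE)
    lo <- max(0L, start - cfg$feature_margin)
    hi <- min(L, end + cfg$feature_margin)
    hic[[cn]][(lo + 1L):hi] <<- FALSE
  }

  # ---- difficult features ------------------------------------------
  for (i in seq_len(cfg$n_homopolymers)) {
    len <- sample(cfg$homopolymer_length_range[1]:
                    cfg$homopolymer_length_range[2], 1)
    a <- alloc(len)
    chars[[a$chrom]][(a$start + 1L):(a$start + len)] <- sample(BASES, 1)
    add_feature(a$chrom, a$start, a$start + len, "homopolymer")
  }
  for (i in seq_len(cfg$n_tandem_repeats)) {
    unit <- sample(BASES, sample(cfg$tandem_unit_range[1]:
                                   cfg$tandem_unit_range[2], 1),
                   replace = TRUE)
    copies <- sample(cfg$tandem_copies_range[1]:
                       cfg$tandem_copies_range[2], 1)
    len <- length(unit) * copies
    a <- alloc(len)
    chars[[a$chrom]][(a$start + 1L):(a$start + len)] <-
      rep(unit, copies)
    add_feature(a$chrom, a$start, a$start + len, "tandem")
  }
  for (i in seq_len(cfg$n_duplications)) {
    len <- cfg$duplication_length
    src <- alloc(len)
    dst <- alloc(len)
    block <- chars[[src$chrom]][(src$start + 1L):(src$start + len)]
    if (cfg$duplication_mismatches > 0) {
      mm <- sample.int(len, cfg$duplication_mismatches)
      for (m in mm) block[m] <- sample(setdiff(BASES, block[m]), 1)
    }
    chars[[dst$chrom]][(dst$start + 1L):(dst$start + len)] <- block
    add_feature(src$chrom, src$start, src$start + len, "segdup")
    add_feature(dst$chrom, dst$start, dst$start + len, "segdup")
  }
  gc_windows <- list()
  for (i in seq_len(cfg$n_gc_windows)) {
    len <- cfg$gc_window_length
    a <- alloc(len)
    n_gc <- round(cfg$gc_fraction * len)
    win <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), len - n_gc, replace = TRUE))
    chars[[a$chrom]][(a$start + 1L):(a$start + len)] <- sample(win)
    gc_windows[[length(gc_windows) + 1L]] <-
      data.frame(chrom = a$chrom, start = a$start, end = a$start + len,
                 stringsAsFactors = FALSE)
  }
  gc_windows <- if (length(gc_windows)) do.call(rbind, gc_windows)
                else empty_regions()
  features <- if (length(features)) do.call(rbind, features)
              else data.frame(chrom = character(), start = integer(),
                              end = integer(), type = character())

  # ---- genes --------------------------------------------------------
  genes <- place_genes(cfg, chrom_names, L, chars, occ, alloc)
  chars <- genes$chars
  gene_models <- genes$gene_models

  # ---- exon exclusions (low-confidence stretches over exons) -------
  for (i in seq_len(nrow(gene_models))) {
    if (stats::runif(1) >= cfg$exon_exclusion_prob) next
    es <- gene_models$exon_start[[i]]; ee <- gene_models$exon_end[[i]]
    j <- sample.int(length(es), 1)
    span <- stats::runif(1, cfg$exon_exclusion_span[1],
                         cfg$exon_exclusion_span[2])
    len <- max(10L, as.integer(span * (ee[j] - es[j])))
    start <- es[j] + sample.int(max(1L, ee[j] - es[j] - len), 1) - 1L
    hic[[gene_models$chrom[i]]][(start + 1L):(start + len)] <- FALSE
  }

  # ---- low-confidence reason partition ------------------------------
  lowconf_alloc <- partition_lowconf(hic, cfg$lowconf_reason_plan)

  # ---- SINE-like repeat track (inside high-confidence sequence) ----
  sine <- lapply(chrom_names, function(cn) rep(FALSE, L))
  names(sine) <- chrom_names
  target_sine <- cfg$sine_fraction * L * cfg$n_chromosomes
  covered <- 0
  while (covered < target_sine) {
    len <- sample(150:400, 1)
    cn <- sample(chrom_names, 1)
    start <- sample.int(L - len, 1)
    idx <- (start + 1L):(start + len)
    covered <- covered + sum(!sine[[cn]][idx])
    sine[[cn]][idx] <- TRUE
  }

  # ---- truth variants ----------------------------------------------
  plan <- plant_variants(cfg, chrom_names, L, chars, occ, gene_models,
                         genes$aux, hic, sine, gc_windows)
  variants <- plan$variants
  false_calls <- plan$false_calls

  # ---- sequences frozen from here on -------------------------------
  reference <- vapply(chars, paste, character(1), collapse = "")

  # ---- truth / query call sets -------------------------------------
  truth <- call_set(data.frame(
    chrom = variants$chrom, pos = variants$pos, id = variants$variant_id,
    ref = variants$ref, alt = variants$alt, qual = 50,
    filters = "", gt1 = variants$gt1, gt2 = variants$gt2,
    phased = TRUE, depth = NA_integer_, stringsAsFactors = FALSE),
    sample_id = "SYNTH1", source_label = "truth")
  query <- build_query(cfg, variants, false_calls, plan$mnv_records)

  # ---- homozygous-reference regions --------------------------------
  homref <- lapply(chrom_names, function(cn) hic[[cn]])
  names(homref) <- chrom_names
  for (i in seq_len(nrow(variants))) {
    cn <- variants$chrom[i]
    lo <- max(1L, variants$pos[i] - 5L)
    hi <- min(L, variants$pos[i] + nchar(variants$ref[i]) + 4L)
    homref[[cn]][lo:hi] <- FALSE
  }

  # ---- platform panels, systematic sites, databases ----------------
  pan <- build_panels(cfg, chrom_names, L, chars, homref, false_calls,
                      reference)

  # ---- bookkeeping --------------------------------------------------
  gene_cov <- gene_coverage_bookkeeping(gene_models, hic)
  bundle <- list(
    config = cfg,
    reference = reference,
    truth = truth,
    query = query,
    hiconf = vec_to_regions(hic),
    homref = vec_to_regions(homref),
    gene_models = gene_models,
    gene_sets = genes$gene_sets,
    repeat_tracks = c(list(sine = vec_to_regions(sine)),
                      feature_tracks(features)),
    reason_tracks = lowconf_alloc$tracks,
    gc_windows = gc_windows,
    panels = pan$panels,
    databases = pan$databases,
    depth_track = plan$depth_track,
    bookkeeping = list(
      variants = variants,
      false_calls = false_calls,
      gene_coverage = gene_cov,
      lowconf_reasons = lowconf_alloc$table,
      syserr_sites = pan$syserr_bk,
      features = features))
  class(bundle) <- "TruthBundle"
  bundle
}

vec_to_regions <- function(vecs) {
  rows <- lapply(names(vecs), function(cn) {
    r <- rle(vecs[[cn]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = cn, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty_regions()
  normalize_regions(out)
}

feature_tracks <- function(features) {
  if (nrow(features) == 0) return(list())
  out <- lapply(split(features, features$type), function(f)
    normalize_regions(regions(f$chrom, f$start, f$end)))
  out
}

# Walk low-confidence bases in genomic order and cut them into reason
# chunks of exact planned sizes (highest precedence first).
partition_lowconf <- function(hic, plan) {
  pos_by_chrom <- lapply(names(hic), function(cn) which(!hic[[cn]]))
  names(pos_by_chrom) <- names(hic)
  total <- sum(lengths(pos_by_chrom))
  sizes <- floor(plan * total)
  sizes[length(sizes)] <- total - sum(sizes[-length(sizes)])
  bounds <- cumsum(sizes)
  tracks <- list()
  tab <- data.frame(reason = names(plan), bases = as.integer(sizes),
                    percent = 100 * sizes / total,
                    stringsAsFactors = FALSE)
  seen <- 0L
  take_from <- 1L
  flat <- do.call(rbind, lapply(names(pos_by_chrom), function(cn)
    if (length(pos_by_chrom[[cn]]))
      data.frame(chrom = cn, pos1 = pos_by_chrom[[cn]]) else NULL))
  for (i in seq_along(plan)) {
    lo <- if (i == 1) 1L else bounds[i - 1L] + 1L
    hi <- bounds[i]
    sel <- flat[seq.int(lo, hi), , drop = FALSE]
    vecs <- lapply(names(hic), function(cn) {
      v <- rep(FALSE, length(hic[[cn]]))
      v[sel$pos1[sel$chrom == cn]] <- TRUE
      v
    })
    names(vecs) <- names(hic)
    tracks[[names(plan)[i]]] <- vec_to_regions(vecs)
  }
  list(tracks = tracks, table = tab)
}

gene_coverage_bookkeeping <- function(gene_models, hic) {
  per_gene <- split(seq_len(nrow(gene_models)), gene_models$gene)
  rows <- lapply(names(per_gene), function(g) {
    pos <- unique(unlist(lapply(per_gene[[g]], function(i) {
      es <- gene_models$exon_start[[i]]; ee <- gene_models$exon_end[[i]]
      unlist(lapply(seq_along(es), function(j) seq.int(es[j], ee[j] - 1L)))
    })))
    cn <- gene_models$chrom[per_gene[[g]][1]]
    covered <- sum(hic[[cn]][pos + 1L])
    data.frame(gene = g, exonic_bases = length(pos),
               covered_bases = covered,
               fraction = covered / length(pos), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$gene), , drop = FALSE]
}
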