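# Desk-scale generator configuration shared across test files; the
# memoized bundle avoids regenerating identical fixtures per file.

small_config <- function(seed = 7, ...) {
  base <- list(
    seed = seed, n_chromosomes = 1L, chrom_length = 150000L,
    n_genes = 8L, intron_length_range = c(150L, 500L),
    n_homopolymers = 4L, n_tandem_repeats = 3L, n_duplications = 1L,
    duplication_length = 300L, n_gc_windows = 3L,
    n_variants = list(`non-synonymous` = 40L, synonymous = 40L,
                      truncating = 10L, splicing = 10L,
                      intergenic = 150L),
    n_mnv_pairs = 5L, n_fp_pass = 8L, n_fp_filtered = 8L,
    n_syserr_sites = 10L, n_noise_sites = 4L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

.bundle_cache <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.bundle_cache$b))
    .bundle_cache$b <- generate_bundle(small_config())
  .bundle_cache$b
}

shared_match <- function() {
  if (is.null(.bundle_cache$m)) {
    b <- shared_bundle()
    .bundle_cache$m <- classify_calls(b$query, b$truth, b$hiconf,
                                      b$reference)
  }
  .bundle_cache$m
}
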