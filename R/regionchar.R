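#' Per-gene high-confidence coverage of exonic bases
#'
#' For each gene, exons are merged across its transcripts (exonic bases
#' are a per-gene base set) and intersected with the high-confidence
#' regions. Per-set summaries are base-weighted: covered exonic bases
#' over total exonic bases across the member genes, not a mean of
#' per-gene fractions; the gene-averaged mean is also reported.
#'
#' @param gene_models Transcript table ([read_gene_models()]).
#' @param gene_sets Named list of gene-symbol vectors.
#' @param hiconf High-confidence region set.
#' @return List with `genes` (`gene`, `exonic_bases`, `covered_bases`,
#'   `fraction`, one logical membership column per set) and `sets`
#'   (`gene_set`, `exonic_bases`, `covered_bases`,
#'   `fraction_base_weighted`, `fraction_gene_mean`, `n_genes`,
#'   `n_fully_covered`, `n_below_half`).
#' @export
gene_coverage <- function(gene_models, gene_sets, hiconf) {
  hiconf <- normalize_regions(hiconf)
  per_gene <- split(seq_len(nrow(gene_models)), gene_models$gene)
  rows <- lapply(names(per_gene), function(g) {
    idx <- per_gene[[g]]
    ex <- do.call(rbind, lapply(idx, function(i)
      regions(gene_models$chrom[i], gene_models$exon_start[[i]],
              gene_models$exon_end[[i]])))
    merged <- normalize_regions(ex)
    exonic <- total_length(merged)
    if (exonic == 0) {
      warning("gene ", g, " has zero exonic bases; excluded")
      return(NULL)
    }
    covered <- total_length(region_intersect(merged, hiconf))
    data.frame(gene = g, exonic_bases = exonic, covered_bases = covered,
               fraction = covered / exonic, stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  for (set_name in names(gene_sets)) {
    genes[[paste0("in_", set_name)]] <- genes$gene %in% gene_sets[[set_name]]
  }
  sets <- do.call(rbind, lapply(names(gene_sets), function(set_name) {
    sub <- genes[genes$gene %in% gene_sets[[set_name]], , drop = FALSE]
    data.frame(gene_set = set_name,
               exonic_bases = sum(sub$exonic_bases),
               covered_bases = sum(sub$covered_bases),
               fraction_base_weighted =
                 sum(sub$covered_bases) / sum(sub$exonic_bases),
               fraction_gene_mean = mean(sub$fraction),
               n_genes = nrow(sub),
               n_fully_covered = sum(sub$fraction == 1),
               n_below_half = sum(sub$fraction < 0.5),
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, sets = sets)
}

#' Positional exon classes of a gene
#'
#' Strand-aware ordinal classes: the 5' exon is `first`; classes are
#' assigned with precedence first > last > second > penultimate >
#' middle, so short genes still get a deterministic partition (a 2-exon
#' gene is first + last; a 3-exon gene first + second + last).
#'
#' @param n_exons Number of exons.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of classes in genomic order.
#' @export
exon_classes <- function(n_exons, strand) {
  cls <- rep("middle", n_exons)
  ord <- seq_len(n_exons)  # transcription order index
  cls[ord == n_exons] <- "last"
  if (n_exons >= 4) cls[ord == n_exons - 1L] <- "penultimate"
  if (n_exons >= 3) cls[ord == 2L] <- "second"
  cls[ord == 1L] <- "first"
  if (strand == "-") cls <- rev(cls)
  cls
}

#' High-confidence coverage by positional exon class
#'
#' Computes, for every exon of every gene (one transcript per gene), the
#' fraction of its bases inside the high-confidence regions, grouped by
#' positional class ([exon_classes()]).
#'
#' @param gene_models Transcript table.
#' @param hiconf High-confidence region set.
#' @return List with `exons` (per-exon rows: `gene`, `exon_class`,
#'   `bases`, `covered`, `fraction`) and `classes` (per-class mean and
#'   base-weighted fractions).
#' @export
exon_position_coverage <- function(gene_models, hiconf) {
  hiconf <- normalize_regions(hiconf)
  gm <- pick_transcripts(gene_models)$primary
  rows <- list()
  for (i in seq_len(nrow(gm))) {
    es <- gm$exon_start[[i]]; ee <- gm$exon_end[[i]]
    cls <- exon_classes(length(es), gm$strand[i])
    for (j in seq_along(es)) {
      ex <- normalize_regions(regions(gm$chrom[i], es[j], ee[j]))
      covered <- total_length(region_intersect(ex, hiconf))
      rows[[length(rows) + 1L]] <-
        data.frame(gene = gm$gene[i], exon_class = cls[j],
                   bases = ee[j] - es[j], covered = covered,
                   fraction = covered / (ee[j] - es[j]),
                   stringsAsFactors = FALSE)
    }
  }
  exons <- do.call(rbind, rows)
  lv <- c("first", "second", "middle", "penultimate", "last")
  classes <- do.call(rbind, lapply(lv, function(cl) {
    sub <- exons[exons$exon_class == cl, , drop = FALSE]
    data.frame(exon_class = cl, n_exons = nrow(sub),
               fraction_mean = if (nrow(sub)) mean(sub$fraction) else NA_real_,
               fraction_base_weighted =
                 if (nrow(sub)) sum(sub$covered) / sum(sub$bases) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(exons = exons, classes = classes)
}

#' Fraction of each repeat class inside high-confidence regions
#'
#' @param repeat_tracks Named list of region tables, one per repeat
#'   class.
#' @param hiconf High-confidence region set.
#' @return `data.frame` with `repeat_class`, `bases`, `covered_bases`,
#'   `fraction` (`NA` for an empty class).
#' @export
repeat_fraction_in_hiconf <- function(repeat_tracks, hiconf) {
  hiconf <- normalize_regions(hiconf)
  do.call(rbind, lapply(names(repeat_tracks), function(cls) {
    tr <- normalize_regions(repeat_tracks[[cls]])
    bases <- total_length(tr)
    if (bases == 0) {
      return(data.frame(repeat_class = cls, bases = 0L,
                        covered_bases = 0L, fraction = NA_real_,
                        stringsAsFactors = FALSE))
    }
    cov <- total_length(region_intersect(tr, hiconf))
    data.frame(repeat_class = cls, bases = bases, covered_bases = cov,
               fraction = cov / bases, stringsAsFactors = FALSE)
  }))
}

#' Attribute low-confidence bases to ordered reasons
#'
#' Each low-confidence base is attributed to the first reason track (in
#' the supplied precedence order) that contains it; remaining bases are
#' reported as `unattributed`. Percentages are over all low-confidence
#' bases.
#'
#' @param lowconf Low-confidence region set.
#' @param reason_tracks *Ordered* named list of region tables, highest
#'   precedence first.
#' @return `data.frame` with `reason`, `bases`, `percent`.
#' @export
lowconf_reasons <- function(lowconf, reason_tracks) {
  lowconf <- normalize_regions(lowconf)
  total <- total_length(lowconf)
  remaining <- lowconf
  rows <- list()
  for (reason in names(reason_tracks)) {
    hit <- region_intersect(remaining, reason_tracks[[reason]])
    rows[[length(rows) + 1L]] <-
      data.frame(reason = reason, bases = total_length(hit),
                 percent = if (total) 100 * total_length(hit) / total
                           else NA_real_,
                 stringsAsFactors = FALSE)
    remaining <- region_subtract(remaining, hit)
  }
  rows[[length(rows) + 1L]] <-
    data.frame(reason = "unattributed", bases = total_length(remaining),
               percent = if (total) 100 * total_length(remaining) / total
                         else NA_real_, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
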