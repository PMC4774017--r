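# Generator internals. All randomness draws from the single stream
# seeded by generate_bundle(); bookkeeping quantities are computed by
# direct per-base indexing so they stay independent of the pipeline's
# interval and matching code.

STOP_CODONS <- c("TAA", "TAG", "TGA")

place_genes <- function(cfg, chrom_names, L, chars, occ, alloc) {
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste,
                      collapse = "")
  sense_pool <- setdiff(all_codons, STOP_CODONS)
  rows <- list()
  aux <- list()
  for (gi in seq_len(cfg$n_genes)) {
    k <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1)
    ex_len <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2],
                     k, replace = TRUE)
    in_len <- if (k > 1)
      sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
             k - 1L, replace = TRUE) else integer(0)
    span <- sum(ex_len) + sum(in_len)
    a <- alloc(span, margin = 60L)
    es <- integer(k); ee <- integer(k)
    cursor <- a$start
    for (j in seq_len(k)) {
      es[j] <- cursor; ee[j] <- cursor + ex_len[j]
      cursor <- ee[j] + if (j < k) in_len[j] else 0L
    }
    strand <- sample(c("+", "-"), 1)
    cn <- a$chrom

    # exonic positions in transcription order (0-based)
    ep <- unlist(lapply(seq_len(k), function(j) seq.int(es[j], ee[j] - 1L)))
    if (strand == "-") ep <- rev(ep)
    utr <- 30L
    n_cds <- length(ep) - 2L * utr
    n_cds <- (n_cds %/% 3L) * 3L
    stopifnot(n_cds >= 90L)
    cds_pos <- ep[(utr + 1L):(utr + n_cds)]
    n_codon <- n_cds %/% 3L
    sense <- paste0("ATG",
                    paste(sample(sense_pool, n_codon - 2L, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1))
    bases <- strsplit(sense, "")[[1]]
    write_base <- if (strand == "+") bases else comp_base(bases)
    chars[[cn]][cds_pos + 1L] <- write_base

    gene <- sprintf("G%03d", gi)
    rows[[gi]] <- data.frame(
      gene = gene, transcript_id = sprintf("T%03d", gi), chrom = cn,
      strand = strand, cds_start = min(cds_pos),
      cds_end = max(cds_pos) + 1L, stringsAsFactors = FALSE)
    rows[[gi]]$exon_start <- list(es)
    rows[[gi]]$exon_end <- list(ee)
    aux[[gene]] <- list(chrom = cn, strand = strand, sense = sense,
                        cds_pos = cds_pos, exon_start = es, exon_end = ee)
  }
  gene_models <- do.call(rbind, rows)
  all_genes <- gene_models$gene
  acmg <- sort(sample(all_genes, min(8L, length(all_genes))))
  cvo <- sort(union(acmg, sample(all_genes,
                                 min(22L, length(all_genes)))))
  gene_sets <- list(ACMG = acmg, ClinVarOMIM = cvo, AllCoding = all_genes)
  list(chars = chars, gene_models = gene_models, gene_sets = gene_sets,
       aux = aux)
}

plant_variants <- function(cfg, chrom_names, L, chars, occ, gene_models,
                           aux, hic, sine, gc_windows) {
  vocc <- lapply(chrom_names, function(cn) rep(FALSE, L))
  names(vocc) <- chrom_names
  gspan <- lapply(chrom_names, function(cn) rep(FALSE, L))
  names(gspan) <- chrom_names
  for (i in seq_len(nrow(gene_models))) {
    cn <- gene_models$chrom[i]
    lo <- max(1L, min(gene_models$exon_start[[i]]) - 60L)
    hi <- min(L, max(gene_models$exon_end[[i]]) + 60L)
    gspan[[cn]][lo:hi] <- TRUE
  }
  span_free <- function(cn, lo1, hi1) {
    idx <- max(1L, lo1 - 2L):min(L, hi1 + 2L)
    !any(vocc[[cn]][idx])
  }
  mark <- function(cn, lo1, hi1) {
    idx <- max(1L, lo1 - 2L):min(L, hi1 + 2L)
    vocc[[cn]][idx] <<- TRUE
  }
  gc_flag_at <- function(cn, pos1, win = 100L) {
    half <- win %/% 2L
    idx <- max(1L, pos1 - half):min(L, pos1 + half - 1L)
    mean(chars[[cn]][idx] %in% c("G", "C")) > 0.75
  }

  rows <- list()
  add_row <- function(cn, pos1, ref, alt, class, gene, mnv_pair = NA) {
    id <- sprintf("tv%05d", length(rows) + 1L)
    het <- stats::runif(1) < cfg$het_fraction
    if (het) {
      if (stats::runif(1) < 0.5) { g1 <- 0L; g2 <- 1L }
      else { g1 <- 1L; g2 <- 0L }
    } else { g1 <- 1L; g2 <- 1L }
    rows[[length(rows) + 1L]] <<- data.frame(
      variant_id = id, chrom = cn, pos = pos1, ref = ref, alt = alt,
      class = class, gene = gene, gt1 = g1, gt2 = g2,
      zygosity = if (het) "het" else "hom",
      in_hiconf = hic[[cn]][pos1],
      gc_flag = gc_flag_at(cn, pos1),
      sine_flag = sine[[cn]][pos1],
      mnv_pair = mnv_pair, stringsAsFactors = FALSE)
    mark(cn, pos1, pos1 + nchar(ref) - 1L)
    id
  }

  genes_of <- names(aux)
  codon_tab <- Biostrings::GENETIC_CODE

  # coding SNV with a target consequence, via direct codon editing
  plant_coding <- function(target) {
    for (t in 1:400) {
      gene_name <- sample(genes_of, 1)
      g <- aux[[gene_name]]
      n_codon <- nchar(g$sense) %/% 3L
      ci <- sample(2:(n_codon - 1L), 1)
      codon <- substr(g$sense, 3L * ci - 2L, 3L * ci)
      cand <- list()
      for (j in 1:3) {
        for (b in setdiff(BASES, substr(codon, j, j))) {
          mut <- codon
          substr(mut, j, j) <- b
          aa0 <- codon_tab[[codon]]; aa1 <- codon_tab[[mut]]
          ok <- switch(target,
                       synonymous = aa1 == aa0,
                       `non-synonymous` = aa1 != aa0 && aa1 != "*",
                       truncating = aa1 == "*")
          if (ok) cand[[length(cand) + 1L]] <- c(j, b)
        }
      }
      if (length(cand) == 0) next
      pick <- cand[[sample.int(length(cand), 1)]]
      j <- as.integer(pick[1]); b <- pick[2]
      gpos0 <- g$cds_pos[3L * (ci - 1L) + j]
      pos1 <- gpos0 + 1L
      if (!span_free(g$chrom, pos1, pos1)) next
      ref <- chars[[g$chrom]][pos1]
      alt <- if (g$strand == "+") b else comp_base(b)
      stopifnot(ref != alt)
      add_row(g$chrom, pos1, ref, alt, target, gene_name)
      return(TRUE)
    }
    stop("infeasible config: cannot plant a ", target, " variant")
  }

  plant_frameshift <- function() {
    for (t in 1:400) {
      gname <- sample(genes_of, 1)
      g <- aux[[gname]]
      # middle of an exon's CDS stretch, away from junctions
      cds_sorted <- sort(g$cds_pos)
      runs <- split(cds_sorted, cumsum(c(1L, diff(cds_sorted) != 1L)))
      runs <- runs[vapply(runs, length, integer(1)) >= 40]
      if (length(runs) == 0) next
      run <- runs[[sample.int(length(runs), 1)]]
      p0 <- run[sample(15:(length(run) - 15L), 1)]
      pos1 <- p0 + 1L
      dlen <- sample(1:2, 1)
      ref <- paste(chars[[g$chrom]][pos1:(pos1 + dlen)], collapse = "")
      alt <- substr(ref, 1L, 1L)
      if (!span_free(g$chrom, pos1, pos1 + dlen)) next
      nv <- normalize_variant(pos1, ref, alt,
                              paste(chars[[g$chrom]], collapse = ""))
      if (nv$pos != pos1 || nv$ref != ref) next  # keep canonical plants
      add_row(g$chrom, pos1, ref, alt, "truncating", gname)
      return(TRUE)
    }
    stop("infeasible config: cannot plant a frameshift variant")
  }

  plant_splicing <- function() {
    for (t in 1:400) {
      gname <- sample(genes_of, 1)
      g <- aux[[gname]]
      k <- length(g$exon_start)
      if (k < 2) next
      donor <- stats::runif(1) < 0.5
      j <- sample.int(k - 1L, 1)
      p0 <- if (donor) g$exon_end[j] + sample(0:1, 1)
            else g$exon_start[j + 1L] - sample(1:2, 1)
      pos1 <- p0 + 1L
      if (!span_free(g$chrom, pos1, pos1)) next
      ref <- chars[[g$chrom]][pos1]
      alt <- sample(setdiff(BASES, ref), 1)
      add_row(g$chrom, pos1, ref, alt, "splicing", gname)
      return(TRUE)
    }
    stop("infeasible config: cannot plant a splicing variant")
  }

  free_intergenic_pos <- function(need, allow_occ = FALSE) {
    for (t in 1:800) {
      cn <- sample(chrom_names, 1)
      pos1 <- sample.int(L - need - 4L, 1) + 2L
      if (gspan[[cn]][pos1]) next
      if (!allow_occ && any(occ[[cn]][pos1:(pos1 + need)])) next
      if (!span_free(cn, pos1, pos1 + need - 1L)) next
      return(list(chrom = cn, pos = pos1))
    }
    stop("infeasible config: no intergenic room left")
  }

  plant_intergenic_snv <- function(at = NULL) {
    p <- if (is.null(at)) free_intergenic_pos(1L, allow_occ = TRUE) else at
    ref <- chars[[p$chrom]][p$pos]
    alt <- sample(setdiff(BASES, ref), 1)
    add_row(p$chrom, p$pos, ref, alt, "intergenic", NA_character_)
  }

  plant_intergenic_indel <- function() {
    for (t in 1:400) {
      dlen <- sample(1:3, 1)
      ins <- stats::runif(1) < 0.5
      p <- free_intergenic_pos(dlen + 1L, allow_occ = FALSE)
      seqstr <- paste(chars[[p$chrom]], collapse = "")
      if (ins) {
        ref <- chars[[p$chrom]][p$pos]
        alt <- paste0(ref, paste(sample(BASES, dlen, replace = TRUE),
                                 collapse = ""))
      } else {
        ref <- paste(chars[[p$chrom]][p$pos:(p$pos + dlen)],
                     collapse = "")
        alt <- substr(ref, 1L, 1L)
      }
      nv <- normalize_variant(p$pos, ref, alt, seqstr)
      if (nv$pos != p$pos || nv$ref != ref || nv$alt != alt) next
      add_row(p$chrom, p$pos, ref, alt, "intergenic", NA_character_)
      return(TRUE)
    }
    stop("infeasible config: cannot plant an intergenic indel")
  }

  # ---- plant per stratum -------------------------------------------
  counts <- cfg$n_variants
  for (i in seq_len(counts[["synonymous"]])) plant_coding("synonymous")
  for (i in seq_len(counts[["non-synonymous"]]))
    plant_coding("non-synonymous")
  n_tr_indel <- round(cfg$truncating_indel_fraction *
                        counts[["truncating"]])
  for (i in seq_len(counts[["truncating"]] - n_tr_indel))
    plant_coding("truncating")
  for (i in seq_len(n_tr_indel)) plant_frameshift()
  for (i in seq_len(counts[["splicing"]])) plant_splicing()

  n_inter <- counts[["intergenic"]]
  n_gc_planted <- 0L
  n_gc_target <- min(nrow(gc_windows), 12L, n_inter)
  for (i in seq_len(n_gc_target)) {
    mid <- (gc_windows$start[i] + gc_windows$end[i]) %/% 2L
    if (!span_free(gc_windows$chrom[i], mid + 1L, mid + 1L)) next
    plant_intergenic_snv(at = list(chrom = gc_windows$chrom[i],
                                   pos = mid + 1L))
    n_gc_planted <- n_gc_planted + 1L
  }
  n_indel <- min(round(cfg$indel_fraction * n_inter),
                 n_inter - n_gc_planted)
  for (i in seq_len(n_indel)) plant_intergenic_indel()
  n_snv <- n_inter - n_gc_planted - n_indel
  for (i in seq_len(n_snv)) plant_intergenic_snv()

  # ---- MNV pairs (always kept; query representation merged) --------
  mnv_records <- list()
  for (i in seq_len(cfg$n_mnv_pairs)) {
    p <- free_intergenic_pos(2L, allow_occ = FALSE)
    cn <- p$chrom
    r1 <- chars[[cn]][p$pos]; r2 <- chars[[cn]][p$pos + 1L]
    a1 <- sample(setdiff(BASES, r1), 1)
    a2 <- sample(setdiff(BASES, r2), 1)
    phase1 <- stats::runif(1) < 0.5
    g <- if (phase1) c(1L, 0L) else c(0L, 1L)
    pair_id <- sprintf("mnv%03d", i)
    for (off in 0:1) {
      id <- sprintf("tv%05d", length(rows) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = id, chrom = cn, pos = p$pos + off,
        ref = if (off == 0) r1 else r2, alt = if (off == 0) a1 else a2,
        class = "intergenic", gene = NA_character_,
        gt1 = g[1], gt2 = g[2], zygosity = "het",
        in_hiconf = hic[[cn]][p$pos + off],
        gc_flag = gc_flag_at(cn, p$pos + off),
        sine_flag = sine[[cn]][p$pos + off],
        mnv_pair = pair_id, stringsAsFactors = FALSE)
    }
    mark(cn, p$pos, p$pos + 1L)
    mnv_records[[length(mnv_records) + 1L]] <- data.frame(
      pair_id = pair_id, chrom = cn, pos = p$pos,
      ref = paste0(r1, r2), alt = paste0(a1, a2),
      gt1 = 0L, gt2 = 1L, stringsAsFactors = FALSE)
  }

  variants <- do.call(rbind, rows)

  # ---- fates --------------------------------------------------------
  n <- nrow(variants)
  sens <- unlist(cfg$sensitivity)[variants$class]
  kept <- stats::runif(n) < sens
  kept[!is.na(variants$mnv_pair)] <- TRUE
  mode <- ifelse(kept, "kept",
                 ifelse(stats::runif(n) < cfg$miss_filtered_fraction,
                        "miss_filtered", "miss_lowcov"))
  variants$fate <- mode
  draw_labels <- function(k) {
    vapply(seq_len(k), function(i) {
      nlab <- if (stats::runif(1) < cfg$multi_filter_fraction) 2L else 1L
      paste(sort(sample(cfg$filter_label_pool, nlab)), collapse = ";")
    }, character(1))
  }
  variants$filter_labels <- ""
  sel <- variants$fate == "miss_filtered"
  variants$filter_labels[sel] <- draw_labels(sum(sel))
  variants$genotype_error <- variants$fate == "kept" &
    is.na(variants$mnv_pair) &
    stats::runif(n) < cfg$genotype_error_rate
  depth_called <- function(k)
    10L + stats::rnbinom(k, mu = cfg$depth_mean - 10, size = 8)
  variants$depth <- NA_integer_
  variants$depth[variants$fate != "miss_lowcov"] <-
    depth_called(sum(variants$fate != "miss_lowcov"))
  variants$depth[variants$fate == "miss_lowcov"] <-
    sample(0:9, sum(variants$fate == "miss_lowcov"), replace = TRUE)

  # ---- false calls --------------------------------------------------
  fc <- list()
  add_fc <- function(filters) {
    p <- free_intergenic_pos(1L, allow_occ = TRUE)
    if (!hic[[p$chrom]][p$pos]) return(FALSE)  # plant inside hiconf only
    ref <- chars[[p$chrom]][p$pos]
    alt <- sample(setdiff(BASES, ref), 1)
    fc[[length(fc) + 1L]] <<- data.frame(
      fc_id = sprintf("fc%04d", length(fc) + 1L), chrom = p$chrom,
      pos = p$pos, ref = ref, alt = alt, filters = filters,
      depth = depth_called(1L), stringsAsFactors = FALSE)
    mark(p$chrom, p$pos, p$pos)
    TRUE
  }
  got <- 0L
  while (got < cfg$n_fp_pass) got <- got + add_fc("")
  got <- 0L
  while (got < cfg$n_fp_filtered) got <- got + add_fc(draw_labels(1L))
  false_calls <- if (length(fc)) do.call(rbind, fc) else
    data.frame(fc_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), filters = character(),
               depth = integer(), stringsAsFactors = FALSE)

  depth_track <- rbind(
    data.frame(chrom = variants$chrom, pos = variants$pos,
               depth = variants$depth, stringsAsFactors = FALSE),
    data.frame(chrom = false_calls$chrom, pos = false_calls$pos,
               depth = false_calls$depth, stringsAsFactors = FALSE))
  depth_track <- depth_track[order(depth_track$chrom, depth_track$pos), ,
                             drop = FALSE]
  rownames(depth_track) <- NULL

  mnv_records <- if (length(mnv_records)) do.call(rbind, mnv_records)
                 else NULL
  list(variants = variants, false_calls = false_calls,
       mnv_records = mnv_records, depth_track = depth_track)
}

build_query <- function(cfg, variants, false_calls, mnv_records) {
  recs <- list()
  plain <- variants[is.na(variants$mnv_pair), , drop = FALSE]
  kept <- plain[plain$fate == "kept", , drop = FALSE]
  if (nrow(kept)) {
    g1 <- pmin(kept$gt1, kept$gt2); g2 <- pmax(kept$gt1, kept$gt2)
    flip <- kept$genotype_error
    het <- g1 != g2
    g1[flip & het] <- 1L                 # het reported as hom-alt
    g2[flip & het] <- 1L
    g1[flip & !het] <- 0L                # hom reported as het
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = kept$chrom, pos = kept$pos, id = kept$variant_id,
      ref = kept$ref, alt = kept$alt, qual = 60, filters = "",
      gt1 = g1, gt2 = g2, phased = FALSE, depth = kept$depth,
      stringsAsFactors = FALSE)
  }
  fm <- plain[plain$fate == "miss_filtered", , drop = FALSE]
  if (nrow(fm)) {
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = fm$chrom, pos = fm$pos, id = fm$variant_id, ref = fm$ref,
      alt = fm$alt, qual = 30, filters = fm$filter_labels,
      gt1 = pmin(fm$gt1, fm$gt2), gt2 = pmax(fm$gt1, fm$gt2),
      phased = FALSE, depth = fm$depth, stringsAsFactors = FALSE)
  }
  if (!is.null(mnv_records)) {
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = mnv_records$chrom, pos = mnv_records$pos,
      id = mnv_records$pair_id, ref = mnv_records$ref,
      alt = mnv_records$alt, qual = 60, filters = "",
      gt1 = mnv_records$gt1, gt2 = mnv_records$gt2, phased = FALSE,
      depth = 30L, stringsAsFactors = FALSE)
  }
  if (nrow(false_calls)) {
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = false_calls$chrom, pos = false_calls$pos,
      id = false_calls$fc_id, ref = false_calls$ref,
      alt = false_calls$alt, qual = 40, filters = false_calls$filters,
      gt1 = 0L, gt2 = 1L, phased = FALSE, depth = false_calls$depth,
      stringsAsFactors = FALSE)
  }
  call_set(do.call(rbind, recs), sample_id = "SYNTH1",
           source_label = "query")
}

build_panels <- function(cfg, chrom_names, L, chars, homref, false_calls,
                         reference) {
  platforms <- cfg$platforms
  n_sites <- cfg$n_syserr_sites
  used <- lapply(chrom_names, function(cn) rep(FALSE, L))
  names(used) <- chrom_names

  pick_site <- function(need = 2L) {
    for (t in 1:2000) {
      cn <- sample(chrom_names, 1)
      pos1 <- sample.int(L - need - 2L, 1) + 1L
      idx <- pos1:(pos1 + need)
      if (!all(homref[[cn]][idx])) next
      if (any(used[[cn]][max(1L, pos1 - 5L):min(L, pos1 + need + 5L)]))
        next
      used[[cn]][idx] <<- TRUE
      return(list(chrom = cn, pos = pos1))
    }
    stop("infeasible config: no homozygous-reference room for error sites")
  }

  make_site_allele <- function(cn, pos1, indel) {
    ref <- chars[[cn]][pos1]
    if (!indel) {
      list(ref = ref, alt = sample(setdiff(BASES, ref), 1))
    } else {
      # 1 bp insertion; retry until the representation is canonical
      for (t in 1:50) {
        alt <- paste0(ref, sample(BASES, 1))
        nv <- normalize_variant(pos1, ref, alt, reference[[cn]])
        if (nv$pos == pos1 && nv$ref == ref && nv$alt == alt)
          return(list(ref = ref, alt = alt))
      }
      list(ref = ref, alt = paste0(ref, ref))  # still valid if shifted
    }
  }

  site_rows <- list()
  evidence <- list()  # per platform+dataset record lists
  add_evidence <- function(platform, ds, cn, pos1, ref, alt) {
    key <- paste(platform, ds, sep = "__")
    evidence[[key]][[length(evidence[[key]]) + 1L]] <<- data.frame(
      chrom = cn, pos = pos1, id = ".", ref = ref, alt = alt,
      qual = round(stats::runif(1, 3, 60), 1), filters = "",
      gt1 = 0L, gt2 = 1L, phased = FALSE, depth = 20L,
      stringsAsFactors = FALSE)
  }
  for (platform in names(platforms)) {
    for (d in seq_len(platforms[[platform]])) {
      evidence[[paste(platform, d, sep = "__")]] <- list()
    }
  }

  n_indel_sites <- round(cfg$syserr_indel_fraction * n_sites)
  for (s in seq_len(n_sites)) {
    indel <- s <= n_indel_sites
    p <- pick_site()
    al <- make_site_allele(p$chrom, p$pos, indel)
    n_flag <- if (stats::runif(1) < 0.2 && length(platforms) > 1) 2L else 1L
    flagged <- sample(names(platforms), n_flag)
    for (platform in flagged) {
      nd <- platforms[[platform]]
      n_ev <- if (nd <= 3L) nd else sample(seq.int(3L, nd), 1)
      for (d in sample.int(nd, n_ev))
        add_evidence(platform, d, p$chrom, p$pos, al$ref, al$alt)
    }
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      chrom = p$chrom, pos = p$pos, ref = al$ref, alt = al$alt,
      platforms = paste(sort(flagged), collapse = ","),
      stringsAsFactors = FALSE)
  }

  # sub-threshold noise: at most two datasets of one multi-dataset
  # platform, never "all"
  noisy <- names(platforms)[platforms >= 3L]
  for (s in seq_len(cfg$n_noise_sites)) {
    p <- pick_site()
    al <- make_site_allele(p$chrom, p$pos, FALSE)
    platform <- sample(noisy, 1)
    nd <- platforms[[platform]]
    n_ev <- min(2L, nd - 1L)
    for (d in sample.int(nd, n_ev))
      add_evidence(platform, d, p$chrom, p$pos, al$ref, al$alt)
  }

  panels <- lapply(names(platforms), function(platform) {
    lapply(seq_len(platforms[[platform]]), function(d) {
      key <- paste(platform, d, sep = "__")
      recs <- evidence[[key]]
      df <- if (length(recs)) do.call(rbind, recs) else NULL
      call_set(df, sample_id = "SYNTH1",
               source_label = sprintf("%s_ds%d", platform, d))
    })
  })
  names(panels) <- names(platforms)

  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  # databases: members share the site's alt; decoys carry a different one
  databases <- list()
  for (db in names(cfg$db_fractions)) {
    n_mem <- round(cfg$db_fractions[[db]] * nrow(sites))
    mem <- sort(sample.int(nrow(sites), n_mem))
    non_mem <- setdiff(seq_len(nrow(sites)), mem)
    dec <- sort(sample(non_mem, min(cfg$n_db_decoys, length(non_mem))))
    rows <- list()
    for (i in mem) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sites$chrom[i], pos = sites$pos[i], id = ".",
        ref = sites$ref[i], alt = sites$alt[i], qual = NA_real_,
        filters = "", gt1 = NA_integer_, gt2 = NA_integer_,
        phased = FALSE, depth = NA_integer_, stringsAsFactors = FALSE)
    }
    for (i in dec) {
      alt <- if (nchar(sites$alt[i]) == 1L)
        sample(setdiff(BASES, c(sites$ref[i], sites$alt[i])), 1)
      else paste0(sites$ref[i], "GGG")  # different inserted sequence
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sites$chrom[i], pos = sites$pos[i], id = ".",
        ref = sites$ref[i], alt = alt, qual = NA_real_, filters = "",
        gt1 = NA_integer_, gt2 = NA_integer_, phased = FALSE,
        depth = NA_integer_, stringsAsFactors = FALSE)
    }
    databases[[db]] <- call_set(do.call(rbind, rows), sample_id = "db",
                                source_label = db)
    sites[[paste0("in_", db)]] <- seq_len(nrow(sites)) %in% mem
  }
  list(panels = panels, databases = databases, syserr_bk = sites)
}
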