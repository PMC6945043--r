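# Assembly of complete synthetic datasets: species, gene copies, lesions,
# scaffold layout with planted linkage and clusters, promoters with
# planted motif sites, true alignments, and truth tables.

shiftc <- function(x, del_pos) {
  if (is.null(del_pos)) return(x)
  x - as.integer(x > del_pos)
}

# Build one gene copy of a family in one species. Coordinates in the
# returned feature list refer to the (possibly spacer-deleted) protein.
build_gene_copy <- function(gene_id, family, anc, spec, rate,
                            japonica_med = FALSE, lesion = NA_character_,
                            near_dup_of = NULL) {
  if (!is.null(near_dup_of)) {
    protein <- near_dup_of$protein
    mut_extra <- sample(anc$mutable, 1L)
    chars <- strsplit(protein, "")[[1]]
    chars[mut_extra + 1L] <- sample(setdiff(AA_BACKGROUND_POOL,
                                            chars[mut_extra + 1L]), 1L)
    protein <- paste(chars, collapse = "")
    mutated <- sort(unique(c(near_dup_of$mutated, mut_extra)))
  } else {
    m <- mutate_protein(anc$protein, rate, anc$mutable)
    protein <- m$protein
    mutated <- m$mutated
  }
  del_pos <- NULL
  if (japonica_med) {
    del_pos <- anc$cys[2] + 9L  # one residue of the inner spacer is lost
    protein <- paste0(substr(protein, 1L, del_pos),
                      substr(protein, del_pos + 2L, nchar(protein)))
  }
  sc <- function(x) shiftc(x, del_pos)
  feats <- list(
    polys = sc(anc$polys), egd = if (!is.null(anc$egd)) sc(anc$egd),
    finger = sc(anc$finger), cys = sc(anc$cys), dbd = sc(anc$dbd),
    amino_gap = anc$amino_gap,
    inner_spacing = anc$inner_spacing - as.integer(japonica_med),
    zf_intron_pos = sc(anc$zf_intron_pos)
  )
  status <- if (!is.null(near_dup_of)) "unresolved_duplicate"
            else if (!is.na(lesion)) "pseudogene" else "functional"
  # protein-level lesions
  if (identical(lesion, "missing_finger_cysteine")) {
    chars <- strsplit(protein, "")[[1]]
    chars[feats$cys[2] + 1L] <- "Y"
    protein <- paste(chars, collapse = "")
  } else if (identical(lesion, "truncated")) {
    protein <- substr(protein, 1L, floor(0.4 * nchar(protein)))
    feats$finger <- NULL; feats$cys <- NULL; feats$egd <- NULL
  }
  rt <- reverse_translate(protein, feats$polys, spec)
  cds <- rt$cds
  # CDS-level lesions
  if (identical(lesion, "internal_stop_in_dbd")) {
    at <- 3L * (feats$dbd[1] + 5L)
    cds <- paste0(substr(cds, 1L, at), "TAA",
                  substr(cds, at + 4L, nchar(cds)))
  } else if (identical(lesion, "frameshift_in_dbd")) {
    at <- 3L * (feats$dbd[1] + 3L) + 1L
    cds <- paste0(substr(cds, 1L, at - 1L), substr(cds, at + 1L, nchar(cds)))
  }
  list(gene_id = gene_id, family = family, protein = protein, cds = cds,
       feats = feats, status = status, lesion = lesion, mutated = mutated,
       polys_codons = rt$polys_codons, del_pos = del_pos)
}

intron_template <- function(gene, species_idx, spec, ancestors) {
  fam <- gene$family
  anc <- ancestors[[fam]]
  f <- gene$feats
  japonica <- species_idx <= spec$n_japonica
  tmpl <- NULL
  if (fam == "end1") {
    tmpl <- rbind(c(f$polys[2] + 6L, 0L),
                  c(anc$finger[1] - 40L, 2L),
                  c(f$zf_intron_pos, 1L))
    if (species_idx == spec$dup_species) tmpl <- tmpl[-2L, , drop = FALSE]
  } else if (fam == "end3") {
    tmpl <- rbind(c(f$polys[2] + 8L, 1L), c(f$zf_intron_pos, 1L))
    if (species_idx == 3L) {
      tmpl <- rbind(c(f$polys[2] + 16L, 0L), tmpl)
    }
  } else if (japonica) {
    tmpl <- rbind(c(f$zf_intron_pos, 1L))
    if (species_idx == 1L) tmpl <- rbind(c(8L, 0L), tmpl)
    if (species_idx == 2L) tmpl <- rbind(c(12L, 2L), tmpl)
  }
  if (is.null(tmpl)) {
    return(data.frame(protein_position = integer(0), phase = integer(0),
                      length = integer(0)))
  }
  tmpl <- tmpl[order(tmpl[, 1]), , drop = FALSE]
  keep <- (3L * tmpl[, 1] + tmpl[, 2]) < (nchar(gene$cds) - 3L) &
    tmpl[, 1] > 0L
  tmpl <- tmpl[keep, , drop = FALSE]
  data.frame(protein_position = tmpl[, 1], phase = tmpl[, 2],
             length = draw_intron_lengths(nrow(tmpl)))
}

# Scaffold builder: accumulates sequence parts and places genes with their
# promoters (promoter before a '+' gene, reverse-complemented after a '-'
# gene).
new_scaffold <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character(0)
  env$len <- 0L
  env
}
sb_append <- function(sb, seq) {
  if (nchar(seq) == 0L) return(invisible(NULL))
  sb$parts <- c(sb$parts, seq)
  sb$len <- sb$len + nchar(seq)
  invisible(NULL)
}
sb_place_gene <- function(sb, gene_seq, promoter, strand) {
  if (strand == "+") {
    sb_append(sb, promoter)
    gstart <- sb$len
    sb_append(sb, gene_seq)
  } else {
    gstart <- sb$len
    sb_append(sb, revcomp(gene_seq))
    sb_append(sb, revcomp(promoter))
  }
  gstart
}
sb_string <- function(sb) paste(sb$parts, collapse = "")

# Forward-strand exon matrix from transcribed-relative exons.
exons_forward <- function(exons_rel, gstart, glen, strand) {
  if (strand == "+") {
    cbind(gstart + exons_rel[, 1], gstart + exons_rel[, 2])
  } else {
    cbind(gstart + glen - exons_rel[, 2], gstart + glen - exons_rel[, 1])
  }
}

# Start-position range on the promoter for a site whose start must lie
# between lo_up and hi_up bp upstream of the ATG.
upstream_range <- function(w, lo_up, hi_up, window) {
  c(lo = window - hi_up, hi = window - max(lo_up, w))
}

#' Generate a complete synthetic multi-species dataset
#'
#' Produces scaffolds, gene models, CDS/protein/promoter sequences, a
#' planted motif-site listing, per-family true alignments of the
#' representative proteins, and truth tables, all deterministically from
#' the spec's seed. See [family_spec()] for the planted regime.
#'
#' @param spec A [family_spec()].
#' @param outdir Optional directory; when given, [write_dataset()] is
#'   called on the result.
#' @return A `gf_dataset` list: `spec`, `scaffolds`, `models`, `cds`,
#'   `proteins`, `promoters`, `site_listing`, `alignments`, `truth`.
#' @export
generate_dataset <- function(spec = family_spec(), outdir = NULL) {
  ds <- with_seed(spec$seed, generate_dataset_impl(spec))
  if (!is.null(outdir)) write_dataset(ds, outdir)
  ds
}

generate_dataset_impl <- function(spec) {
  n <- spec$n_species
  species <- sprintf("sp%02d", seq_len(n))
  group <- ifelse(seq_len(n) <= spec$n_japonica, "japonica", "elegans")
  comp <- spec$composition
  W <- spec$promoter_window
  ancestors <- list(med = build_ancestor("med", spec),
                    end1 = build_ancestor("end1", spec),
                    end3 = build_ancestor("end3", spec))

  # ---- copy numbers --------------------------------------------------------
  n_end3 <- 1L + rpois(n, spec$copy_lambda["end3"])
  n_med <- 1L + rpois(n, spec$copy_lambda["med"])
  n_med[spec$amplified_species] <- spec$amplified_copies
  n_med[spec$sites$panamensis_species] <- 1L
  big <- spec$clusters$big_cluster_species
  n_med[big] <- max(n_med[big], spec$clusters$big_cluster_n)

  # ---- promoter site allocation (representatives only) --------------------
  s <- spec$sites
  # cap species-count parameters at the actual species number so smaller
  # test datasets remain valid
  for (nm in c("med_tctkcac_species", "end3_deg_species", "end1_med_species",
               "end1_deg_species", "end1_ppy_species")) {
    s[[nm]] <- min(s[[nm]], n)
  }
  pan <- s$panamensis_species
  non_pan <- setdiff(seq_len(n), pan)
  med_skn1 <- integer(n)
  med_skn1[non_pan] <- allocate_counts(round(s$med_skn1_mean *
                                               length(non_pan)),
                                       length(non_pan), min_each = 1L)
  med_tct_sp <- sort(sample(seq_len(n), s$med_tctkcac_species))
  med_tct <- integer(n)
  med_tct[med_tct_sp] <- allocate_counts(round(s$med_tctkcac_mean *
                                                 s$med_tctkcac_species),
                                         s$med_tctkcac_species, 1L)
  end3_med <- allocate_counts(round(s$end3_med_mean * n), n, 1L)
  end3_deg_sp <- sort(sample(seq_len(n), s$end3_deg_species))
  end3_deg <- integer(n)
  end3_deg[end3_deg_sp] <- allocate_counts(round(s$end3_deg_mean *
                                                   s$end3_deg_species),
                                           s$end3_deg_species, 1L)
  end1_med_sp <- sort(sample(seq_len(n), s$end1_med_species))
  end1_med <- integer(n)
  end1_med[end1_med_sp] <- allocate_counts(round(s$end1_med_mean *
                                                   s$end1_med_species),
                                           s$end1_med_species, 1L)
  end1_deg_sp <- sort(sample(seq_len(n), s$end1_deg_species))
  end1_deg <- integer(n)
  end1_deg[end1_deg_sp] <- allocate_counts(round(s$end1_deg_mean *
                                                   s$end1_deg_species),
                                           s$end1_deg_species, 1L)
  end1_ppy_sp <- sort(sample(seq_len(n), s$end1_ppy_species))
  end1_ppy <- integer(n)
  end1_ppy[end1_ppy_sp] <- allocate_counts(s$end1_ppy_total,
                                           s$end1_ppy_species, 1L)
  ppy_strands <- sample(c(rep("+", s$end1_ppy_top),
                          rep("-", s$end1_ppy_total - s$end1_ppy_top)))

  # ---- linkage plan --------------------------------------------------------
  lk <- spec$linkage
  eleg_sp <- lk$elegans_like_species
  edge_sp <- lk$edge_species
  linked_pool <- setdiff(seq_len(n), c(eleg_sp, edge_sp))
  linked <- sort(c(eleg_sp, sample(linked_pool, lk$n_linked - 1L)))
  orientations <- rep(c("same_strand_ab", "same_strand_ba", "convergent",
                        "divergent"), length.out = length(linked))
  names(orientations) <- as.character(linked)
  link_dist <- setNames(
    as.integer(round(runif(length(linked), lk$dist_range[1],
                           lk$dist_range[2]))),
    as.character(linked))
  link_dist[as.character(eleg_sp)] <- lk$elegans_like_dist
  orientations[as.character(eleg_sp)] <- "same_strand_ab"

  cl <- spec$clusters

  # ---- per-gene construction ----------------------------------------------
  genes <- list()       # gene_id -> built copy + placement info
  promoters <- list()
  site_rows <- list()
  rates <- spec$substitution_rates

  add_sites <- function(gene_id, sp_i, fam, planted_df) {
    if (is.null(planted_df) || nrow(planted_df) == 0L) return(NULL)
    data.frame(gene_id = gene_id, species = species[sp_i], family = fam,
               motif = planted_df$motif, start = planted_df$start,
               end = planted_df$start + nchar(planted_df$text),
               upstream = W - planted_df$start,
               strand = planted_df$strand, site = planted_df$text,
               stringsAsFactors = FALSE)
  }

  rep_promoter <- function(sp_i, fam, gene_id) {
    planted <- NULL
    # guards insulate a quasi-palindromic site (AGTATAC + trailing T reads
    # as a second, opposite-strand core) so each planted site scans as
    # exactly one occurrence
    guards <- function(motif, strand) {
      if (motif != "med_site") return(c(NA_character_, NA_character_))
      if (strand == "+") c(NA_character_, "G") else c("C", NA_character_)
    }
    add_ranged <- function(motif, text, lo_up, hi_up, strand) {
      r <- upstream_range(nchar(text), lo_up, hi_up, W)
      g <- guards(motif, strand)
      rbind(planted,
            data.frame(motif = motif, text = text, start = NA_integer_,
                       lo = r[["lo"]], hi = r[["hi"]], strand = strand,
                       guard_before = g[1], guard_after = g[2],
                       stringsAsFactors = FALSE))
    }
    add_fixed <- function(motif, text, start, strand) {
      g <- guards(motif, strand)
      rbind(planted,
            data.frame(motif = motif, text = text, start = start,
                       lo = NA_integer_, hi = NA_integer_, strand = strand,
                       guard_before = g[1], guard_after = g[2],
                       stringsAsFactors = FALSE))
    }
    if (fam == "med" && sp_i == pan) {
      # single-med species: six isolated core SKN-1 sites, no double site
      skn1_core <- motif_definition("skn1_core", "RTCAT")
      skn1_double <- motif_definition("skn1_double", "RTCATCAT")
      for (try in seq_len(500L)) {
        planted <- NULL
        for (k in seq_len(s$panamensis_rtcat)) {
          planted <- add_ranged("skn1_core", realize_iupac("RTCAT"),
                                20L, 300L, sample(c("+", "-"), 1L))
        }
        pr <- generate_promoter(W, comp, planted)
        n_core <- nrow(scan_iupac(pr$sequence, skn1_core, "both"))
        n_dbl <- nrow(scan_iupac(pr$sequence, skn1_double, "both"))
        if (n_core == s$panamensis_rtcat && n_dbl == 0L) {
          planted$start <- pr$sites$start
          promoters[[gene_id]] <<- pr$sequence
          return(add_sites(gene_id, sp_i, fam, planted))
        }
      }
      abort("could not realize the single-med promoter in 500 attempts")
    }
    if (fam == "med") {
      for (k in seq_len(med_skn1[sp_i])) {
        planted <- add_ranged("skn1_double", realize_iupac("RTCATCAT"),
                              20L, 300L, sample(c("+", "-"), 1L))
      }
      if (med_tct[sp_i] > 0L) {
        for (k in seq_len(med_tct[sp_i])) {
          planted <- add_ranged("tctkcac", realize_iupac("TCTKCAC"),
                                20L, 300L, sample(c("+", "-"), 1L))
        }
      }
    } else if (fam == "end3") {
      for (k in seq_len(end3_med[sp_i])) {
        # ladder with ~55 bp spacing starting ~30 bp upstream of the ATG
        up <- 30L + 55L * (k - 1L) + sample.int(9L, 1L) - 1L
        planted <- add_fixed("med_site", realize_iupac("AGTATAC"), W - up,
                             sample(c("+", "-"), 1L))
      }
      if (end3_deg[sp_i] > 0L) {
        for (k in seq_len(end3_deg[sp_i])) {
          planted <- add_ranged("skn1_degenerate",
                                realize_iupac("TCATTYTCATC"),
                                20L, 550L, sample(c("+", "-"), 1L))
        }
      }
    } else {
      if (end1_med[sp_i] > 0L) {
        for (k in seq_len(end1_med[sp_i])) {
          planted <- add_ranged("med_site", realize_iupac("AGTATAC"),
                                20L, 200L, sample(c("+", "-"), 1L))
        }
      }
      if (end1_deg[sp_i] > 0L) {
        for (k in seq_len(end1_deg[sp_i])) {
          planted <- add_ranged("skn1_degenerate",
                                realize_iupac("TCATTYTCATC"),
                                20L, 550L, sample(c("+", "-"), 1L))
        }
      }
      if (end1_ppy[sp_i] > 0L) {
        for (k in seq_len(end1_ppy[sp_i])) {
          strand <- ppy_strands[1L]
          ppy_strands <<- ppy_strands[-1L]
          tract <- paste(sample(c("C", "T"), 14L, replace = TRUE),
                         collapse = "")
          planted <- add_ranged("ppy", tract, 20L, 550L, strand)
        }
      }
    }
    pr <- generate_promoter(W, comp, planted)
    promoters[[gene_id]] <<- pr$sequence
    if (!is.null(planted)) planted$start <- pr$sites$start
    add_sites(gene_id, sp_i, fam, planted)
  }

  make_copy <- function(sp_i, fam, k, n_copies, near_dup_of = NULL) {
    gene_id <- sprintf("%s_%s.%d", species[sp_i], fam, k)
    lesion <- NA_character_
    if (is.null(near_dup_of) && k > 1L &&
        runif(1) < spec$pseudogene_rate) {
      lesion <- sample(names(spec$lesion_mix), 1L, prob = spec$lesion_mix)
    }
    g <- build_gene_copy(gene_id, fam, ancestors[[fam]], spec,
                         rates[[fam]],
                         japonica_med = (fam == "med" &&
                                           sp_i <= spec$n_japonica),
                         lesion = lesion, near_dup_of = near_dup_of)
    g$species_idx <- sp_i
    g$is_representative <- (k == 1L)
    tm <- intron_template(g, sp_i, spec, ancestors)
    built <- build_gene_seq(g$cds, tm, comp)
    g$gene_seq <- built$seq
    g$exons_rel <- built$exons_rel
    g$introns <- built$introns
    if (g$is_representative) {
      site_rows[[gene_id]] <<- rep_promoter(sp_i, fam, gene_id)
    }
    if (is.null(promoters[[gene_id]])) {
      promoters[[gene_id]] <<- generate_promoter(W, comp)$sequence
    }
    genes[[gene_id]] <<- g
    g
  }

  for (sp_i in seq_len(n)) {
    make_copy(sp_i, "end1", 1L, 1L)
    if (sp_i == spec$dup_species) {
      make_copy(sp_i, "end1", 2L, 2L,
                near_dup_of = genes[[sprintf("%s_end1.1", species[sp_i])]])
      # near-duplication is symmetric: neither member of the pair can be
      # told apart from an unresolved haplotype
      genes[[sprintf("%s_end1.1", species[sp_i])]]$status <-
        "unresolved_duplicate"
    }
    for (k in seq_len(n_end3[sp_i])) make_copy(sp_i, "end3", k, n_end3[sp_i])
    for (k in seq_len(n_med[sp_i])) make_copy(sp_i, "med", k, n_med[sp_i])
  }

  # ---- scaffold layout -----------------------------------------------------
  scaffolds <- list()
  placements <- list()  # gene_id -> list(scaffold_id, gstart, strand)
  linkage_rows <- list()
  cluster_rows <- list()

  place_run <- function(scaf_id, run, lead_pad = 200L, tail_pad = 400L) {
    # run: data.frame gene_id, strand, fill_before (bp of background before
    # this gene's upstream block)
    sb <- new_scaffold()
    sb_append(sb, rand_dna(lead_pad, comp))
    for (i in seq_len(nrow(run))) {
      sb_append(sb, rand_dna(run$fill_before[i], comp))
      gid <- run$gene_id[i]
      g <- genes[[gid]]
      gstart <- sb_place_gene(sb, g$gene_seq, promoters[[gid]],
                              run$strand[i])
      placements[[gid]] <<- list(scaffold_id = scaf_id, gstart = gstart,
                                 strand = run$strand[i],
                                 glen = nchar(g$gene_seq))
    }
    sb_append(sb, rand_dna(tail_pad, comp))
    scaffolds[[scaf_id]] <<- sb_string(sb)
    invisible(NULL)
  }

  # background fill so that the extent gap between consecutive genes is G
  fill_for_gap <- function(G, prev_strand, next_strand) {
    f <- G - (prev_strand == "-") * W - (next_strand == "+") * W
    assert_that(f >= 0L, "intergenic gap ", G,
                " too small for promoter placement",
                class = "gatafam_validation_error")
    as.integer(f)
  }

  for (sp_i in seq_len(n)) {
    sp <- species[sp_i]
    e1 <- sprintf("%s_end1.1", sp)
    e3_ids <- sprintf("%s_end3.%d", sp, seq_len(n_end3[sp_i]))
    med_ids <- sprintf("%s_med.%d", sp, seq_len(n_med[sp_i]))
    is_linked <- sp_i %in% linked
    scafE <- paste0(sp, "_scafE")

    e3_linked_extra <- n_end3[sp_i] >= 2L &&
      runif(1) < cl$end3_within10k_prob
    e3_gap <- as.integer(round(runif(1, cl$end3_gap_range[1],
                                     cl$end3_gap_range[2])))

    if (is_linked) {
      ori <- orientations[as.character(sp_i)]
      G <- link_dist[as.character(sp_i)]
      run <- switch(ori,
        same_strand_ab = data.frame(gene_id = c(e1, e3_ids[1]),
                                    strand = c("+", "+")),
        same_strand_ba = data.frame(gene_id = c(e3_ids[1], e1),
                                    strand = c("+", "+")),
        convergent = data.frame(gene_id = c(e1, e3_ids[1]),
                                strand = c("+", "-")),
        divergent = data.frame(gene_id = c(e1, e3_ids[1]),
                               strand = c("-", "+")))
      run$fill_before <- c(0L,
                           fill_for_gap(G, run$strand[1], run$strand[2]))
      if (e3_linked_extra) {
        st <- sample(c("+", "-"), 1L)
        run <- rbind(run, data.frame(gene_id = e3_ids[2], strand = st,
                                     fill_before = fill_for_gap(
                                       e3_gap, run$strand[2], st)))
      }
      place_run(scafE, run)
      linkage_rows[[length(linkage_rows) + 1L]] <- data.frame(
        species = sp, gene_a = e1, gene_b = e3_ids[1], same_scaffold = TRUE,
        gap_bp = G, orientation = ori, stringsAsFactors = FALSE)
      if (e3_linked_extra) {
        cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
          species = sp, family = "end3", scaffold_id = scafE,
          n_genes = 2L, gap_bp = e3_gap,
          members = paste(e3_ids[1:2], collapse = ","),
          stringsAsFactors = FALSE)
      }
      rest_e3 <- if (e3_linked_extra) e3_ids[-(1:2)] else e3_ids[-1]
    } else {
      if (sp_i == edge_sp) {
        # end1 close to one scaffold end (possible broken linkage)
        st <- "+"
        run <- data.frame(gene_id = e1, strand = st, fill_before = 26000L)
        place_run(paste0(sp, "_scafE1"), run, lead_pad = 200L,
                  tail_pad = lk$edge_margin)
      } else {
        place_run(paste0(sp, "_scafE1"),
                  data.frame(gene_id = e1, strand = sample(c("+", "-"), 1L),
                             fill_before = 0L),
                  lead_pad = 700L)
      }
      st3 <- sample(c("+", "-"), 1L)
      run3 <- data.frame(gene_id = e3_ids[1], strand = st3, fill_before = 0L)
      if (e3_linked_extra) {
        st <- sample(c("+", "-"), 1L)
        run3 <- rbind(run3, data.frame(gene_id = e3_ids[2], strand = st,
                                       fill_before = fill_for_gap(
                                         e3_gap, st3, st)))
        cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
          species = sp, family = "end3", scaffold_id = paste0(sp, "_scafE3"),
          n_genes = 2L, gap_bp = e3_gap,
          members = paste(e3_ids[1:2], collapse = ","),
          stringsAsFactors = FALSE)
      }
      place_run(paste0(sp, "_scafE3"), run3, lead_pad = 700L)
      linkage_rows[[length(linkage_rows) + 1L]] <- data.frame(
        species = sp, gene_a = e1, gene_b = e3_ids[1], same_scaffold = FALSE,
        gap_bp = NA_integer_, orientation = "n/a", stringsAsFactors = FALSE)
      rest_e3 <- if (e3_linked_extra) e3_ids[-(1:2)] else e3_ids[-1]
    }
    for (gid in rest_e3) {
      place_run(paste0(sp, "_scaf_", sub("^.*_", "", gid)),
                data.frame(gene_id = gid, strand = sample(c("+", "-"), 1L),
                           fill_before = 0L), lead_pad = 700L)
    }

    # near-identical end1 duplicate on its own small scaffold
    if (sp_i == spec$dup_species) {
      place_run(paste0(sp, "_scaf_dup"),
                data.frame(gene_id = sprintf("%s_end1.2", sp),
                           strand = "+", fill_before = 0L),
                lead_pad = 700L, tail_pad = 300L)
    }

    # med layout
    med_rest <- med_ids
    if (sp_i == big) {
      members <- med_ids[seq_len(cl$big_cluster_n)]
      glens <- vapply(members, function(g) nchar(genes[[g]]$gene_seq),
                      integer(1))
      strands <- sample(c("+", "-"), length(members), replace = TRUE)
      span <- cl$big_cluster_span
      n_gap <- length(members) - 1L
      gap_each <- (span - sum(glens)) %/% n_gap
      gaps <- rep(gap_each, n_gap)
      gaps[n_gap] <- span - sum(glens) - sum(gaps[-n_gap])
      run <- data.frame(gene_id = members, strand = strands,
                        fill_before = c(0L, vapply(seq_len(n_gap),
                          function(j) fill_for_gap(gaps[j], strands[j],
                                                   strands[j + 1L]),
                          integer(1))))
      place_run(paste0(sp, "_scafM"), run, lead_pad = 900L)
      cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
        species = sp, family = "med", scaffold_id = paste0(sp, "_scafM"),
        n_genes = length(members), gap_bp = max(gaps),
        members = paste(members, collapse = ","), stringsAsFactors = FALSE)
      med_rest <- med_ids[-seq_len(cl$big_cluster_n)]
    } else if (n_med[sp_i] >= 2L && runif(1) < cl$med_cluster_prob) {
      members <- med_ids[1:2]
      gap <- as.integer(round(runif(1, cl$med_gap_range[1],
                                    cl$med_gap_range[2])))
      strands <- sample(c("+", "-"), 2L, replace = TRUE)
      run <- data.frame(gene_id = members, strand = strands,
                        fill_before = c(0L, fill_for_gap(gap, strands[1],
                                                         strands[2])))
      place_run(paste0(sp, "_scafM"), run, lead_pad = 900L)
      cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
        species = sp, family = "med", scaffold_id = paste0(sp, "_scafM"),
        n_genes = 2L, gap_bp = gap, members = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
      med_rest <- med_ids[-(1:2)]
    }
    for (gid in med_rest) {
      place_run(paste0(sp, "_scaf_", sub("^.*_", "", gid)),
                data.frame(gene_id = gid, strand = sample(c("+", "-"), 1L),
                           fill_before = 0L), lead_pad = 700L)
    }
  }

  # ---- assemble models and records ----------------------------------------
  models <- list()
  cds_set <- list()
  prot_set <- list()
  truth_gene_rows <- list()
  intron_truth <- list()
  for (gid in names(genes)) {
    g <- genes[[gid]]
    pl <- placements[[gid]]
    ex <- exons_forward(g$exons_rel, pl$gstart, pl$glen, pl$strand)
    models[[gid]] <- gene_model(
      gene_id = gid, species = species[g$species_idx], family = g$family,
      scaffold_id = pl$scaffold_id, strand = pl$strand, exons = ex,
      is_pseudogene_candidate = FALSE)
    cds_set[[gid]] <- seq_record(paste0(gid, "_cds"), g$cds, "dna")
    prot_set[[gid]] <- seq_record(gid, g$protein, "protein")
    f <- g$feats
    truth_gene_rows[[gid]] <- data.frame(
      gene_id = gid, species = species[g$species_idx],
      group = group[g$species_idx], family = g$family,
      scaffold_id = pl$scaffold_id, strand = pl$strand,
      status = g$status, lesion = g$lesion,
      is_representative = g$is_representative,
      protein_length = nchar(g$protein),
      polys_start = f$polys[1], polys_end = f$polys[2],
      egd_start = if (!is.null(f$egd)) f$egd[1] else NA_integer_,
      egd_end = if (!is.null(f$egd)) f$egd[2] else NA_integer_,
      finger_start = if (!is.null(f$finger)) f$finger[1] else NA_integer_,
      finger_end = if (!is.null(f$finger)) f$finger[2] else NA_integer_,
      inner_spacing = if (!is.null(f$finger)) f$inner_spacing else NA_integer_,
      amino_gap = if (!is.null(f$finger)) f$amino_gap else NA_integer_,
      dbd_start = f$dbd[1], dbd_end = f$dbd[2],
      n_introns = nrow(g$exons_rel) - 1L,
      n_polys_ser = length(g$polys_codons),
      n_polys_tcn = sum(substr(g$polys_codons, 1L, 2L) == "TC"),
      exon_starts = paste(ex[, 1], collapse = ","),
      exon_ends = paste(ex[, 2], collapse = ","),
      stringsAsFactors = FALSE)
    intron_truth[[gid]] <- g$introns
  }

  # ---- true alignments of representative proteins -------------------------
  alignments <- list()
  invariant_truth <- list()
  for (fam in c("med", "end1", "end3")) {
    reps <- sprintf("%s_%s.1", species, fam)
    anc_len <- nchar(ancestors[[fam]]$protein)
    rows <- vapply(reps, function(gid) {
      g <- genes[[gid]]
      if (!is.null(g$del_pos)) {
        paste0(substr(g$protein, 1L, g$del_pos), "-",
               substr(g$protein, g$del_pos + 1L, nchar(g$protein)))
      } else {
        g$protein
      }
    }, character(1))
    names(rows) <- reps
    alignments[[fam]] <- rows
    mut_union <- sort(unique(unlist(lapply(reps, function(gid)
      genes[[gid]]$mutated))))
    gap_cols <- unique(unlist(lapply(reps, function(gid)
      genes[[gid]]$del_pos)))
    invariant_truth[[fam]] <- setdiff(seq_len(anc_len) - 1L,
                                      c(mut_union, gap_cols))
  }

  site_listing <- do.call(rbind, unname(site_rows))
  scaffold_recs <- lapply(names(scaffolds), function(id)
    seq_record(id, scaffolds[[id]], "dna"))
  names(scaffold_recs) <- names(scaffolds)

  structure(list(
    spec = spec,
    scaffolds = structure(scaffold_recs, class = "seq_set",
                          alphabet_kind = "dna"),
    models = models,
    cds = cds_set,
    proteins = prot_set,
    promoters = promoters,
    site_listing = site_listing,
    alignments = alignments,
    truth = list(
      genes = do.call(rbind, unname(truth_gene_rows)),
      introns = intron_truth,
      linkage = do.call(rbind, linkage_rows),
      clusters = do.call(rbind, cluster_rows),
      invariant_columns = invariant_truth,
      ancestors = ancestors,
      species = data.frame(species = species, group = group,
                           n_end3 = n_end3, n_med = n_med,
                           stringsAsFactors = FALSE)
    )
  ), class = "gf_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the formats every pipeline stage consumes: scaffolds, CDS,
#' proteins and promoters as FASTA, gene models as GFF3 and TSV, the
#' planted site listing and truth tables as TSV, and per-family true
#' alignments as aligned FASTA. Output is deterministic given the dataset.
#'
#' @param ds A `gf_dataset` from [generate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_fasta(ds$scaffolds, fp("scaffolds.fasta"))
  write_fasta(ds$cds, fp("cds.fasta"))
  write_fasta(ds$proteins, fp("proteins.fasta"))
  prom <- unlist(ds$promoters)
  write_fasta(prom[order(names(prom))], fp("promoters.fasta"))
  write_gene_models(ds$models, fp("models.tsv"), dialect = "tsv")
  write_gene_models(ds$models, fp("models.gff3"), dialect = "gff3")
  st <- ds$site_listing
  names(st)[names(st) == "motif"] <- "motif"
  write.table(st, fp("sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (fam in names(ds$alignments)) {
    write_fasta(ds$alignments[[fam]],
                fp(sprintf("alignment_%s.fasta", fam)))
  }
  write.table(ds$truth$genes, fp("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$truth$linkage, fp("truth_linkage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$truth$clusters, fp("truth_clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Derive noiseless TBLASTN-like HSPs from a planted gene model
#'
#' Each exon yields one HSP trimmed to whole codons (TBLASTN reports
#' complete residues), so exon boundaries with non-zero phase lie up to
#' two bases outside the HSP edges — exactly the situation the stitcher's
#' boundary search resolves.
#'
#' @param model A [gene_model] whose CDS includes the stop codon.
#' @return List of [hsp] objects (exons shorter than two codons are
#'   skipped).
#' @export
hsps_from_model <- function(model) {
  exon_len <- model$exons[, 2] - model$exons[, 1]
  cds_len <- sum(exon_len)
  prot_len <- cds_len %/% 3L - 1L  # minus the stop codon
  c_off <- c(0L, cumsum(exon_len))
  out <- list()
  for (i in seq_len(nrow(model$exons))) {
    c0 <- c_off[i]; c1 <- c_off[i + 1L]
    q0 <- (c0 + 2L) %/% 3L          # ceiling(c0 / 3)
    q1 <- min(c1 %/% 3L, prot_len)  # floor, excluding the stop
    if (q1 - q0 < 2L) next
    lead <- 3L * q0 - c0
    if (model$strand == "+") {
      gs <- model$exons[i, 1] + lead
      out[[length(out) + 1L]] <- hsp(model$scaffold_id, "+",
                                     c(gs, gs + 3L * (q1 - q0)),
                                     c(q0, q1))
    } else {
      ge <- model$exons[i, 2] - lead
      out[[length(out) + 1L]] <- hsp(model$scaffold_id, "-",
                                     c(ge - 3L * (q1 - q0), ge),
                                     c(q0, q1))
    }
  }
  out
}
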