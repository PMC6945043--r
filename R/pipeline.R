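# End-to-end orchestration: from scaffolds + gene models to the summary
# artifacts of a family characterization — ortholog count matrix with
# pseudogene column, per-motif site tables and summaries, synteny pair and
# cluster tables, domain maps, the codon-bias report, and conservation
# profiles with a clade-purity check.

#' Default pipeline configuration
#'
#' @param promoter_window Promoter length in bp (default 600).
#' @param med_cluster_gap,end3_cluster_gap Cluster chaining thresholds.
#' @param d_atg_med,d_atg_end ATG-proximity thresholds for site summaries.
#' @param truncation_fraction,near_dup_identity Pseudogene-rule thresholds.
#' @param consensus_threshold Consensus threshold for alignment profiles.
#' @param contact_positions Named list of 0-based alignment columns to
#'   score with [contact_conservation()] (e.g., reference-structure base
#'   contacts); empty by default because such lists must be transcribed
#'   from a structure annotation.
#' @return Configuration list.
#' @export
characterize_config <- function(promoter_window = 600L,
                                med_cluster_gap = 5000L,
                                end3_cluster_gap = 10000L,
                                d_atg_med = 300L, d_atg_end = 200L,
                                truncation_fraction = 0.6,
                                near_dup_identity = 0.99,
                                consensus_threshold = 0.5,
                                contact_positions = list()) {
  assert_that(promoter_window > 0L && med_cluster_gap > 0L &&
                end3_cluster_gap > 0L, "thresholds must be positive",
              class = "gatafam_config_error")
  list(promoter_window = as.integer(promoter_window),
       med_cluster_gap = as.integer(med_cluster_gap),
       end3_cluster_gap = as.integer(end3_cluster_gap),
       d_atg_med = as.integer(d_atg_med), d_atg_end = as.integer(d_atg_end),
       truncation_fraction = truncation_fraction,
       near_dup_identity = near_dup_identity,
       consensus_threshold = consensus_threshold,
       contact_positions = contact_positions)
}

#' Read a written dataset directory back into memory
#'
#' Counterpart of [write_dataset()]: reads scaffolds, gene models, the
#' site listing and any per-family alignments. Sequences derived from the
#' models (CDS, proteins, promoters) are reassembled by the pipeline.
#'
#' @param input_dir Directory produced by [write_dataset()] (or laid out
#'   the same way).
#' @return List with `scaffolds`, `models`, `site_listing`, `alignments`.
#' @export
read_dataset <- function(input_dir) {
  fp <- function(x) file.path(input_dir, x)
  assert_that(dir.exists(input_dir), "no such directory: ", input_dir,
              class = "gatafam_io_error")
  scaffolds <- read_fasta(fp("scaffolds.fasta"), "dna")
  models <- read_gene_models(fp("models.tsv"), dialect = "tsv")
  site_listing <- if (file.exists(fp("sites.tsv"))) {
    read_site_listing(fp("sites.tsv"))
  } else {
    NULL
  }
  aln_files <- list.files(input_dir, pattern = "^alignment_.*\\.fasta$")
  alignments <- lapply(aln_files, function(f) {
    set <- Biostrings::readBStringSet(fp(f))
    out <- toupper(as.character(set))
    names(out) <- sub("\\s.*$", "", names(set))
    out
  })
  names(alignments) <- sub("^alignment_(.*)\\.fasta$", "\\1", aln_files)
  list(scaffolds = scaffolds, models = models, site_listing = site_listing,
       alignments = alignments)
}

# Family -> motifs summarized for it, with the ATG-proximity threshold.
family_motif_plan <- function(config) {
  list(
    med = list(motifs = c("skn1_double", "skn1_core", "tctkcac"),
               d_atg = config$d_atg_med),
    end3 = list(motifs = c("med_site", "skn1_degenerate"),
                d_atg = config$d_atg_end),
    end1 = list(motifs = c("med_site", "skn1_degenerate"),
                d_atg = config$d_atg_end)
  )
}

#' Run the full family characterization
#'
#' @param dataset A `gf_dataset` from [generate_dataset()], or `NULL` when
#'   reading from `input_dir`.
#' @param input_dir Directory laid out as by [write_dataset()].
#' @param outdir Optional output directory for the report TSV/BED files.
#' @param lexicon_path Optional motif-lexicon YAML; default the packaged
#'   lexicon. Validated before any computation.
#' @param config A [characterize_config()].
#' @return A report list: `counts` (species x family status matrix),
#'   `pseudogene_calls`, `representatives`, `sites`, `enrichment`,
#'   `summaries`, `ppy_summary`, `linkage`, `clusters`, `domains`,
#'   `codon_bias`, `conservation`.
#' @export
run_characterize <- function(dataset = NULL, input_dir = NULL,
                             outdir = NULL, lexicon_path = NULL,
                             config = characterize_config()) {
  lexicon <- read_motif_lexicon(lexicon_path)  # fail fast on bad config
  if (is.null(dataset)) {
    assert_that(!is.null(input_dir), "need a dataset or an input_dir",
                class = "gatafam_config_error")
    dataset <- read_dataset(input_dir)
  }
  models <- dataset$models
  scaffolds <- dataset$scaffolds
  log_info("characterize: ", length(models), " gene model(s), ",
           length(scaffolds), " scaffold(s)")

  # ---- sequence reconstruction -------------------------------------------
  cds <- lapply(models, function(m) assemble_cds(m, scaffolds[[m$scaffold_id]]))
  translations <- lapply(cds, translate_cds)
  proteins <- lapply(translations, `[[`, "protein")
  for (gid in names(proteins)) proteins[[gid]]$id <- gid

  info <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    species = vapply(models, function(m) m$species %||% NA_character_,
                     character(1)),
    family = vapply(models, `[[`, character(1), "family"),
    scaffold_id = vapply(models, `[[`, character(1), "scaffold_id"),
    protein_length = vapply(proteins, function(p) nchar(p$residues),
                            integer(1)),
    stringsAsFactors = FALSE
  )

  # ---- pseudogene classification ------------------------------------------
  fingers <- lapply(proteins, function(p) {
    if (nchar(p$residues) >= 25L) find_zinc_fingers(p) else list()
  })
  dbd_offsets <- tapply(seq_len(nrow(info)), info$family, function(ix) {
    offs <- unlist(lapply(ix, function(i) {
      zf <- fingers[[i]]
      if (length(zf) == 0L) return(NULL)
      info$protein_length[i] - zf[[length(zf)]]$interval[1]
    }))
    if (length(offs) == 0L) 40L else as.integer(stats::median(offs))
  })
  calls <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    gid <- info$gene_id[i]
    fam <- info$family[i]
    len <- info$protein_length[i]
    zf <- fingers[[i]]
    dbd <- if (length(zf) > 0L) {
      c(zf[[length(zf)]]$interval[1], len)
    } else {
      c(max(0L, len - dbd_offsets[[fam]]), len)
    }
    peer_ix <- which(info$family == fam & info$species == info$species[i] &
                       info$gene_id != gid)
    fam_lengths <- info$protein_length[info$family == fam]
    calls[[i]] <- classify_pseudogene(
      models[[gid]], proteins[[gid]], dbd,
      family_peers = proteins[info$gene_id[peer_ix]],
      family_lengths = fam_lengths,
      truncation_fraction = config$truncation_fraction,
      near_dup_identity = config$near_dup_identity)
  }
  info$status <- vapply(calls, `[[`, character(1), "status")
  info$reasons <- vapply(calls, function(x)
    paste(x$reasons, collapse = ","), character(1))
  info$n_fingers <- vapply(fingers, length, integer(1))

  counts <- as.data.frame.matrix(table(info$species,
                                       paste(info$family, info$status,
                                             sep = ".")))
  counts$species <- rownames(counts)

  # ---- representative selection -------------------------------------------
  # one gene per family per species: the lowest-index functional
  # single-finger paralogue; a species whose only copies are unresolved
  # near-identical duplicates keeps the lowest-index duplicate (one of the
  # pair is presumed to be the real locus)
  rep_ids <- unname(unlist(lapply(split(info,
                                        paste(info$species, info$family)),
                           function(sub) {
    ok <- sub[sub$status == "functional" & sub$n_fingers == 1L, ,
              drop = FALSE]
    if (nrow(ok) == 0L) {
      ok <- sub[sub$status == "unresolved_duplicate" & sub$n_fingers == 1L, ,
                drop = FALSE]
    }
    if (nrow(ok) == 0L) return(NULL)
    ok$gene_id[order(ok$gene_id)][1]
  })))

  # ---- promoter scanning ---------------------------------------------------
  plan <- family_motif_plan(config)
  sites_rows <- list()
  enr_rows <- list()
  promoter_of <- list()
  for (gid in rep_ids) {
    m <- models[[gid]]
    if (!m$family %in% names(plan)) next
    prom <- extract_promoter(m, scaffolds[[m$scaffold_id]],
                             window = config$promoter_window)
    promoter_of[[gid]] <- prom
    for (mot_name in plan[[m$family]]$motifs) {
      mot <- lexicon[[mot_name]]
      assert_that(!is.null(mot), "motif '", mot_name, "' absent from lexicon",
                  class = "gatafam_config_error")
      hits <- scan_iupac(prom$sequence, mot)
      enr <- poisson_enrichment(prom$sequence, mot, gene_id = gid)
      enr_rows[[length(enr_rows) + 1L]] <- data.frame(
        gene_id = gid, species = m$species, family = m$family,
        motif_name = mot_name, observed = enr$observed,
        lambda = enr$lambda, p_value = enr$p_value,
        stringsAsFactors = FALSE)
      if (nrow(hits) > 0L) {
        hits <- add_upstream_positions(hits, prom$length)
        hits$gene_id <- gid
        hits$species <- m$species
        hits$family <- m$family
        sites_rows[[length(sites_rows) + 1L]] <- hits
      }
    }
  }
  sites <- if (length(sites_rows) > 0L) do.call(rbind, sites_rows) else NULL
  enrichment <- do.call(rbind, enr_rows)

  summaries <- list()
  if (!is.null(sites)) {
    for (fam in names(plan)) {
      for (mot_name in plan[[fam]]$motifs) {
        sub <- sites[sites$family == fam & sites$motif_name == mot_name, ,
                     drop = FALSE]
        if (nrow(sub) == 0L) next
        summaries[[paste(fam, mot_name, sep = ".")]] <-
          summarize_family(sub, mot_name, family = fam,
                           d_atg = plan[[fam]]$d_atg)
      }
    }
  }
  summaries <- if (length(summaries) > 0L) do.call(rbind, summaries) else NULL

  # PPY strand-bias summary from the site listing when one is available
  # (the planted/curated analog of a supplemental site table); otherwise
  # from de novo tract detection on the end1 promoters.
  ppy_summary <- NULL
  sl <- dataset$site_listing
  if (!is.null(sl)) {
    mot_col <- sl$motif_name %||% sl$motif
    ppy <- sl[mot_col == "ppy", , drop = FALSE]
    if (nrow(ppy) > 0L) {
      ppy_summary <- data.frame(
        family = sort(unique(ppy$family)),
        n_sites = as.integer(table(ppy$family)[sort(unique(ppy$family))]),
        top_strand = vapply(sort(unique(ppy$family)), function(f)
          sum(ppy$strand[ppy$family == f] == "+"), integer(1)),
        stringsAsFactors = FALSE)
      ppy_summary$top_strand_fraction <-
        ppy_summary$top_strand / ppy_summary$n_sites
    }
  } else if (length(promoter_of) > 0L) {
    rows <- list()
    for (gid in names(promoter_of)) {
      if (models[[gid]]$family != "end1") next
      tr <- detect_ppy_tracts(promoter_of[[gid]]$sequence)
      if (nrow(tr) > 0L) {
        tr$gene_id <- gid
        rows[[length(rows) + 1L]] <- tr
      }
    }
    if (length(rows) > 0L) {
      all_tr <- do.call(rbind, rows)
      ppy_summary <- data.frame(
        family = "end1", n_sites = nrow(all_tr),
        top_strand = sum(all_tr$strand == "+"),
        top_strand_fraction = mean(all_tr$strand == "+"),
        stringsAsFactors = FALSE)
    }
  }

  # ---- synteny -------------------------------------------------------------
  linkage_rows <- list()
  for (sp in unique(info$species)) {
    e1 <- rep_ids[grepl(paste0("^", sp, "_"), rep_ids) &
                    vapply(rep_ids, function(g) models[[g]]$family == "end1",
                           logical(1))]
    e3 <- rep_ids[grepl(paste0("^", sp, "_"), rep_ids) &
                    vapply(rep_ids, function(g) models[[g]]$family == "end3",
                           logical(1))]
    if (length(e1) == 1L && length(e3) == 1L) {
      p <- pair_linkage(models[[e1]], models[[e3]])
      linkage_rows[[length(linkage_rows) + 1L]] <- data.frame(
        species = sp, gene_a = p$gene_a, gene_b = p$gene_b,
        same_scaffold = p$same_scaffold, gap_bp = p$gap_bp,
        orientation = p$orientation, stringsAsFactors = FALSE)
    }
  }
  linkage <- do.call(rbind, linkage_rows)

  med_models <- models[info$gene_id[info$family == "med"]]
  end3_models <- models[info$gene_id[info$family == "end3"]]
  clusters <- list(
    med = find_clusters(med_models, config$med_cluster_gap),
    end3 = find_clusters(end3_models, config$end3_cluster_gap)
  )

  # ---- domain maps ---------------------------------------------------------
  dom_rows <- list()
  for (gid in rep_ids) {
    fam <- models[[gid]]$family
    p <- proteins[[gid]]
    zf <- fingers[[which(info$gene_id == gid)]]
    mode <- if (fam == "med") "ser_thr" else "serine_only"
    ps <- detect_poly_s(p, mode = mode)
    egd <- if (length(zf) > 0L && fam != "med") {
      locate_egd(p, zf[[1]])
    } else {
      NULL
    }
    cls <- if (length(zf) > 0L) classify_finger(zf[[1]]) else NULL
    dom_rows[[length(dom_rows) + 1L]] <- data.frame(
      gene_id = gid, family = fam,
      polys_start = if (!is.null(ps)) ps$interval[1] else NA_integer_,
      polys_end = if (!is.null(ps)) ps$interval[2] else NA_integer_,
      egd_start = if (!is.null(egd)) egd$interval[1] else NA_integer_,
      egd_end = if (!is.null(egd)) egd$interval[2] else NA_integer_,
      finger_start = if (length(zf) > 0L) zf[[1]]$interval[1] else NA_integer_,
      finger_end = if (length(zf) > 0L) zf[[1]]$interval[2] else NA_integer_,
      inner_spacing = if (length(zf) > 0L) zf[[1]]$inner_spacing else NA_integer_,
      finger_class = if (!is.null(cls)) cls$label else NA_character_,
      amino_gap_class = if (!is.null(cls)) cls$amino_gap_class else NA_character_,
      stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, dom_rows)

  # ---- poly-serine codon bias ---------------------------------------------
  tallies <- list()
  for (gid in rep_ids) {
    fam <- models[[gid]]$family
    if (!fam %in% c("end1", "end3")) next
    d <- domains[domains$gene_id == gid, ]
    if (is.na(d$polys_start)) next
    tallies[[gid]] <- tally_serine_codons(cds[[gid]],
                                          c(d$polys_start, d$polys_end))
  }
  codon_bias <- NULL
  if (length(tallies) > 0L) {
    counts_sum <- Reduce(`+`, lapply(tallies, `[[`, "counts"))
    pooled <- structure(list(counts = counts_sum, total = sum(counts_sum),
                             tcn_total = sum(counts_sum[TCN_CODONS])),
                        class = "codon_tally")
    codon_bias <- list(
      tally = pooled,
      tcn_fraction = pooled$tcn_total / pooled$total,
      tcn_vs_agy = chisq_codon_bias(pooled, mode = "tcn_vs_agy"),
      within_tcn = chisq_codon_bias(pooled, mode = "within_tcn"))
  }

  # ---- conservation --------------------------------------------------------
  conservation <- list()
  if (!is.null(dataset$alignments) && length(dataset$alignments) > 0L) {
    for (fam in names(dataset$alignments)) {
      prof <- profile_alignment(dataset$alignments[[fam]],
                                consensus_threshold = config$consensus_threshold)
      conservation[[fam]] <- list(
        profile = prof,
        n_invariant = count_invariant(prof),
        blocks = conserved_blocks(prof))
    }
  }
  # clade separation on a carboxy-anchored DBD stack across families
  stack_len <- 34L
  stack <- vapply(rep_ids, function(gid) {
    p <- proteins[[gid]]$residues
    substr(p, max(1L, nchar(p) - stack_len + 1L), nchar(p))
  }, character(1))
  stack <- stack[nchar(stack) == stack_len]
  tree_check <- NULL
  if (length(stack) >= 4L) {
    labels <- vapply(names(stack), function(g) models[[g]]$family,
                     character(1))
    tree_check <- pdistance_tree(stack, labels)
  }

  report <- list(counts = counts, gene_table = info,
                 representatives = unname(rep_ids), sites = sites,
                 enrichment = enrichment, summaries = summaries,
                 ppy_summary = ppy_summary, linkage = linkage,
                 clusters = clusters, domains = domains,
                 codon_bias = codon_bias, conservation = conservation,
                 tree_check = tree_check, config = config)
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write the characterization report bundle
#'
#' @param report Output of [run_characterize()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  wt <- function(x, f) {
    if (!is.null(x)) write.table(x, fp(f), sep = "\t", quote = FALSE,
                                 row.names = FALSE)
  }
  wt(report$counts, "count_matrix.tsv")
  wt(report$gene_table, "gene_table.tsv")
  wt(report$enrichment, "enrichment.tsv")
  wt(report$summaries, "site_summaries.tsv")
  wt(report$linkage, "linkage.tsv")
  wt(report$domains, "domains.tsv")
  wt(report$ppy_summary, "ppy_summary.tsv")
  if (!is.null(report$sites)) {
    bed <- report$sites
    bed$seqname <- paste0(bed$gene_id, "_promoter")
    export_sites_bed(bed, fp("sites.bed"))
  }
  cl_rows <- list()
  for (fam in names(report$clusters)) {
    for (cl in report$clusters[[fam]]) {
      cl_rows[[length(cl_rows) + 1L]] <- data.frame(
        family = fam, scaffold_id = cl$scaffold_id,
        n_genes = length(cl$member_gene_ids), span_bp = cl$span_bp,
        max_internal_gap = cl$max_internal_gap,
        members = paste(cl$member_gene_ids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cl_rows) > 0L) wt(do.call(rbind, cl_rows), "clusters.tsv")
  if (!is.null(report$codon_bias)) {
    cb <- report$codon_bias
    wt(data.frame(mode = c("tcn_vs_agy", "within_tcn"),
                  statistic = c(cb$tcn_vs_agy$statistic,
                                cb$within_tcn$statistic),
                  df = c(cb$tcn_vs_agy$df, cb$within_tcn$df),
                  p_value = c(cb$tcn_vs_agy$p_value, cb$within_tcn$p_value),
                  tcn_fraction = cb$tcn_fraction),
       "codon_bias.tsv")
  }
  if (length(report$conservation) > 0L) {
    cons <- data.frame(
      family = names(report$conservation),
      n_invariant = vapply(report$conservation, `[[`, integer(1),
                           "n_invariant"),
      n_columns = vapply(report$conservation, function(x)
        x$profile$n_columns, integer(1)),
      consensus = vapply(report$conservation, function(x)
        x$profile$consensus, character(1)),
      stringsAsFactors = FALSE)
    wt(cons, "conservation.tsv")
  }
  if (!is.null(report$tree_check)) {
    ape::write.tree(report$tree_check$tree, fp("dbd_tree.nwk"))
    writeLines(sprintf("clade_purity\t%g", report$tree_check$purity),
               fp("clade_purity.tsv"))
  }
  invisible(outdir)
}
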