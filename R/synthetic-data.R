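# Seeded generator of multi-species genomes carrying med/end1/end3-style
# GATA-factor families, with machine-readable truth tables for every
# planted feature: exon/intron structures, domains, finger spacings,
# serine codon draws, promoter motif sites, pseudogene lesions, linkage
# distances/orientations and tandem clusters.
#
# Background protein sequence is drawn from an alphabet without cysteine,
# serine or threonine so that planted zinc fingers and poly-serine domains
# are the only instances of their patterns; substitutions never introduce
# those residues either. True alignments are emitted from the mutation
# trace (substitutions only, plus one known spacer deletion), so no
# aligner is needed downstream.

AA_BACKGROUND_POOL <- strsplit("ADEFGHIKLMNPQRVWY", "")[[1]]

CODON_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Specification of a synthetic gene-family dataset
#'
#' Defaults mirror the summary statistics of the study system: 20 species
#' (5 of them forming a Japonica-like group), a unique end1 per species,
#' end3 copy numbers averaging 2.0, med copy numbers averaging 5.6 (driven
#' by two heavily amplified species), 600-bp promoters, planted motif-site
#' counts averaging 3.5 double-SKN-1 sites per med promoter, 2.6 MED sites
#' per end3 and 1.2 per end1 gene with sites, a 30/34 top-strand split of
#' end1 PPY tracts, a 0.99 TCN bias in poly-serine codons with TCT/TCC at
#' 50%/22% within TCN, substitution rates ordered med > end3 > end1, and
#' linkage/cluster geometry (end1-end3 within 20-63 kbp in 13/20 species;
#' med clusters within 5 kbp; one 9-gene 23-kbp cluster).
#'
#' @param n_species Number of species.
#' @param n_japonica Species 1..n_japonica form the Japonica-like group
#'   (med genes keep the zinc-finger intron and an X17 finger).
#' @param pseudogene_rate Lesion probability per non-representative copy.
#' @param lesion_mix Sampling weights of the four lesion types.
#' @param substitution_rates Per-site substitution rate per family.
#' @param polys_tcn_bias,polys_tcn_split Serine codon bias inside the
#'   poly-serine domain.
#' @param composition Background mononucleotide composition (AT-rich).
#' @param promoter_window Promoter length in bp.
#' @param seed Master seed; the same seed gives byte-identical output.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_species = 20L, n_japonica = 5L,
                        pseudogene_rate = 0.16,
                        lesion_mix = c(truncated = 1,
                                       internal_stop_in_dbd = 1,
                                       frameshift_in_dbd = 1,
                                       missing_finger_cysteine = 1),
                        substitution_rates = c(med = 0.25, end3 = 0.12,
                                               end1 = 0.05),
                        polys_tcn_bias = 0.99,
                        polys_tcn_split = c(TCT = 0.50, TCC = 0.22,
                                            TCA = 0.18, TCG = 0.10),
                        composition = c(A = 0.32, C = 0.18,
                                        G = 0.18, T = 0.32),
                        promoter_window = 600L,
                        seed = 1L) {
  assert_that(n_species >= 6L, "need at least 6 species",
              class = "gatafam_validation_error")
  assert_that(n_japonica >= 2L && n_japonica < n_species,
              "n_japonica out of range", class = "gatafam_validation_error")
  assert_that(pseudogene_rate >= 0 && pseudogene_rate <= 1,
              "pseudogene_rate must be in [0,1]",
              class = "gatafam_validation_error")
  assert_that(all(substitution_rates >= 0 & substitution_rates <= 1),
              "substitution rates must be in [0,1]",
              class = "gatafam_validation_error")
  assert_that(abs(sum(polys_tcn_split) - 1) < 1e-9,
              "polys_tcn_split must sum to 1",
              class = "gatafam_validation_error")
  structure(list(
    n_species = as.integer(n_species), n_japonica = as.integer(n_japonica),
    copy_lambda = c(end3 = 1.0, med = 2.7),  # extra copies beyond the first
    amplified_species = c(10L, 11L),         # heavily amplified med species
    amplified_copies = c(20L, 21L),
    pseudogene_rate = pseudogene_rate,
    lesion_mix = lesion_mix / sum(lesion_mix),
    substitution_rates = substitution_rates,
    polys_tcn_bias = polys_tcn_bias, polys_tcn_split = polys_tcn_split,
    composition = composition / sum(composition),
    promoter_window = as.integer(promoter_window),
    # planted promoter-site regime (per representative promoter)
    sites = list(
      med_skn1_mean = 3.5, med_tctkcac_species = 9L, med_tctkcac_mean = 1.6,
      end3_med_mean = 2.6, end3_deg_species = 14L, end3_deg_mean = 1.6,
      end1_med_species = 9L, end1_med_mean = 1.2,
      end1_deg_species = 12L, end1_deg_mean = 1.5,
      end1_ppy_species = 15L, end1_ppy_total = 34L, end1_ppy_top = 30L,
      panamensis_species = 2L, panamensis_rtcat = 6L
    ),
    linkage = list(n_linked = 13L, dist_range = c(20000L, 63000L),
                   elegans_like_species = 20L, elegans_like_dist = 30000L,
                   edge_species = 6L, edge_margin = 3000L),
    clusters = list(end3_within10k_prob = 0.7,
                    end3_gap_range = c(2000L, 9000L),
                    med_cluster_prob = 0.5,
                    med_gap_range = c(1300L, 4500L),
                    big_cluster_species = 10L, big_cluster_n = 9L,
                    big_cluster_span = 23000L),
    dup_species = 10L,  # carries a near-identical second end1
    seed = as.integer(seed)
  ), class = "family_spec")
}

rand_dna <- function(n, comp) {
  if (n <= 0L) return("")
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

rand_prot <- function(n, pool = AA_BACKGROUND_POOL) {
  if (n <= 0L) return("")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Poly-serine block: starts and ends with serine runs, ~92% serine inside.
polys_block <- function(len) {
  stopifnot(len >= 6L)
  inner <- ifelse(runif(max(0L, len - 4L)) < 0.92, "S",
                  sample(AA_BACKGROUND_POOL, max(0L, len - 4L),
                         replace = TRUE))
  paste(c("S", "S", "S", inner, "S"), collapse = "")
}

polyst_block <- function(len) {
  stopifnot(len >= 4L)
  draw <- runif(len - 2L)
  inner <- ifelse(draw < 0.5, "S",
                  ifelse(draw < 0.8, "T",
                         sample(AA_BACKGROUND_POOL, len - 2L, replace = TRUE)))
  paste(c("S", inner, "S"), collapse = "")
}

make_finger <- function(amino_gap_seq, inner_len, carboxy_gap = "NP") {
  paste0("C", amino_gap_seq, "C", rand_prot(inner_len), "C", carboxy_gap, "C")
}

# Build one family's ancestral protein with annotated feature coordinates
# (all 0-based half-open on the protein).
build_ancestor <- function(family, spec) {
  if (family == "end1") {
    polys_len <- sample(20:32, 1L)
    parts <- list(head = "MK", polys = polys_block(polys_len),
                  link1 = rand_prot(14L), block1 = rand_prot(8L),
                  link2 = rand_prot(10L), center = paste0("FGQYF",
                                                          rand_prot(4L)),
                  link3 = rand_prot(10L), block3 = rand_prot(6L),
                  link4 = rand_prot(8L), egd = rand_prot(25L),
                  finger = make_finger("SNPN", 17L), tail = rand_prot(12L))
    frozen <- c("block1", "center", "block3")
  } else if (family == "end3") {
    polys_len <- sample(14:28, 1L)
    parts <- list(head = "MK", polys = polys_block(polys_len),
                  link1 = rand_prot(24L), egd = rand_prot(25L),
                  finger = make_finger("SN", 17L), tail = rand_prot(12L))
    frozen <- character(0)
  } else {
    polys_len <- sample(12:20, 1L)
    parts <- list(head = "M", polys = polyst_block(polys_len),
                  link1 = rand_prot(20L), finger = make_finger("TT", 18L,
                                                               "VK"),
                  tail = paste0("YR", rand_prot(10L)))
    frozen <- character(0)
  }
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  iv <- function(nm) c(starts[[nm]], ends[[nm]])
  protein <- paste(unlist(parts), collapse = "")
  finger_iv <- iv("finger")
  # cysteine offsets directly from construction
  amino_gap <- if (family == "end1") 4L else 2L
  inner_len <- if (family == "med") 18L else 17L
  c1 <- finger_iv[1]
  c2 <- c1 + 1L + amino_gap
  c3 <- c2 + 1L + inner_len
  c4 <- c3 + 3L
  frozen_pos <- unlist(lapply(frozen, function(nm) {
    seq(starts[[nm]], ends[[nm]] - 1L)
  }))
  mutable <- setdiff(seq_len(nchar(protein)) - 1L,
                     c(0L,                       # start methionine
                       seq(iv("polys")[1], iv("polys")[2] - 1L),
                       c(c1, c2, c3, c4), frozen_pos))
  list(family = family, protein = protein,
       polys = unname(iv("polys")),
       egd = if ("egd" %in% names(parts)) unname(iv("egd")) else NULL,
       finger = unname(finger_iv),
       dbd = c(unname(finger_iv[1]), nchar(protein)),
       cys = c(c1, c2, c3, c4),
       amino_gap = amino_gap, inner_spacing = inner_len,
       mutable = mutable,
       # zinc-finger intron interrupts the inner spacer
       zf_intron_pos = c3 - 6L)
}

mutate_protein <- function(seq, rate, mutable) {
  chars <- strsplit(seq, "")[[1]]
  hit <- mutable[runif(length(mutable)) < rate]
  for (i in hit) {
    cur <- chars[i + 1L]
    repl <- sample(setdiff(AA_BACKGROUND_POOL, cur), 1L)
    chars[i + 1L] <- repl
  }
  list(protein = paste(chars, collapse = ""), mutated = sort(hit))
}

# Reverse-translate; serines inside the poly-serine interval follow the
# biased codon table, all other residues draw uniformly among synonymous
# codons. Returns the CDS (with stop) and the serine codon draws.
reverse_translate <- function(protein, polys_iv, spec) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  codons <- character(n)
  polys_codons <- character(0)
  split_p <- spec$polys_tcn_split
  for (i in seq_len(n)) {
    aa <- chars[i]
    in_polys <- !is.null(polys_iv) && (i - 1L) >= polys_iv[1] &&
      (i - 1L) < polys_iv[2]
    if (aa == "S" && in_polys) {
      cd <- if (runif(1) < spec$polys_tcn_bias) {
        sample(names(split_p), 1L, prob = split_p)
      } else {
        sample(c("AGT", "AGC"), 1L)
      }
      polys_codons <- c(polys_codons, cd)
    } else {
      cd <- sample(CODON_BY_AA[[aa]], 1L)
    }
    codons[i] <- cd
  }
  list(cds = paste0(paste(codons, collapse = ""), "TAA"),
       polys_codons = polys_codons)
}

# Interleave a CDS with introns. `introns` is a data.frame with
# protein_position, phase, length; cut coordinates are CDS string offsets.
build_gene_seq <- function(cds, introns, comp) {
  if (is.null(introns) || nrow(introns) == 0L) {
    return(list(seq = cds,
                exons_rel = matrix(c(0L, nchar(cds)), ncol = 2),
                introns = introns))
  }
  cuts <- sort(3L * introns$protein_position + introns$phase)
  introns <- introns[order(3L * introns$protein_position + introns$phase), ,
                     drop = FALSE]
  assert_that(all(cuts > 0L & cuts < nchar(cds)),
              "intron cut outside CDS", class = "gatafam_validation_error")
  seg_bounds <- c(0L, cuts, nchar(cds))
  parts <- character(0)
  exons_rel <- matrix(integer(0), ncol = 2)
  pos <- 0L
  for (k in seq_len(length(seg_bounds) - 1L)) {
    seg <- substr(cds, seg_bounds[k] + 1L, seg_bounds[k + 1L])
    parts <- c(parts, seg)
    exons_rel <- rbind(exons_rel, c(pos, pos + nchar(seg)))
    pos <- pos + nchar(seg)
    if (k < length(seg_bounds) - 1L) {
      ilen <- introns$length[k]
      intron_seq <- paste0("GT", rand_dna(ilen - 4L, comp), "AG")
      parts <- c(parts, intron_seq)
      pos <- pos + ilen
    }
  }
  list(seq = paste(parts, collapse = ""), exons_rel = exons_rel,
       introns = introns)
}

draw_intron_lengths <- function(n) {
  if (n == 0L) return(integer(0))
  sample(c(47:90, seq(100L, 300L, by = 7L)), n, replace = TRUE)
}

#' Generate a promoter with planted motif sites
#'
#' Background bases are i.i.d. from `composition`; each planted site is
#' written at its placement (minus-strand sites as the reverse complement
#' of their text). A site either carries a fixed 0-based `start` (a
#' collision with an earlier fixed site is an error) or a `[lo, hi]` start
#' range from which positions are re-drawn on collision up to a bounded
#' number of retries; with neither, the whole promoter is the range.
#' Fixed sites are written before ranged ones.
#'
#' @param length Promoter length in bp.
#' @param composition Named A/C/G/T probability vector.
#' @param planted Data.frame with columns `text`, `strand` and optionally
#'   `start` and/or `lo`/`hi`, plus optional `guard_before`/`guard_after`
#'   bases written flanking the site (outside its coordinates) to insulate
#'   it from chance extension by the background; may be `NULL`.
#' @param max_retry Per-site placement retries before failing.
#' @return List with `sequence` and `sites` (the realized placements, in
#'   the input row order).
#' @export
generate_promoter <- function(length, composition, planted = NULL,
                              max_retry = 50L) {
  comp <- composition / sum(composition)
  seq_chars <- strsplit(rand_dna(length, comp), "")[[1]]
  occupied <- matrix(integer(0), ncol = 2)
  out_sites <- NULL
  if (!is.null(planted) && nrow(planted) > 0L) {
    n_sites <- nrow(planted)
    starts <- integer(n_sites)
    fixed <- if (!is.null(planted$start)) !is.na(planted$start) else
      rep(FALSE, n_sites)
    guard <- function(col, i) {
      if (is.null(planted[[col]]) || is.na(planted[[col]][i])) "" else
        planted[[col]][i]
    }
    for (i in order(!fixed)) {  # fixed placements first
      gb <- guard("guard_before", i); ga <- guard("guard_after", i)
      w <- nchar(planted$text[i])
      wg <- w + nchar(gb) + nchar(ga)
      assert_that(wg <= length, "planted site longer than promoter",
                  class = "gatafam_validation_error")
      tries <- 0L
      repeat {
        cand <- if (fixed[i]) {
          planted$start[i]
        } else if (!is.null(planted$lo) && !is.na(planted$lo[i])) {
          sample(seq(max(planted$lo[i], nchar(gb)),
                     min(planted$hi[i], length - w - nchar(ga))), 1L)
        } else {
          sample.int(length - wg + 1L, 1L) - 1L + nchar(gb)
        }
        lo_occ <- cand - nchar(gb); hi_occ <- cand + w + nchar(ga)
        clash <- lo_occ < 0L || hi_occ > length ||
          (nrow(occupied) > 0L &&
             any(lo_occ < occupied[, 2] & hi_occ > occupied[, 1]))
        if (!clash) break
        assert_that(!fixed[i], "planted site collides with a fixed placement",
                    class = "gatafam_validation_error")
        tries <- tries + 1L
        assert_that(tries <= max_retry, "cannot place planted site (",
                    planted$text[i], ") without overlap",
                    class = "gatafam_validation_error")
      }
      written <- paste0(gb,
                        if (planted$strand[i] == "-") revcomp(planted$text[i])
                        else planted$text[i],
                        ga)
      seq_chars[(cand - nchar(gb) + 1L):(cand + w + nchar(ga))] <-
        strsplit(written, "")[[1]]
      occupied <- rbind(occupied, c(cand - nchar(gb), cand + w + nchar(ga)))
      starts[i] <- cand
    }
    out_sites <- data.frame(text = planted$text, strand = planted$strand,
                            start = starts,
                            end = starts + nchar(planted$text),
                            stringsAsFactors = FALSE)
  }
  list(sequence = paste(seq_chars, collapse = ""), sites = out_sites)
}

# Distribute `total` sites over `n` genes so the mean is exact; each listed
# gene gets at least `min_each`.
allocate_counts <- function(total, n, min_each = 0L) {
  base <- rep(min_each, n)
  rest <- total - min_each * n
  assert_that(rest >= 0L, "allocate_counts: total too small")
  if (rest > 0L && n > 0L) {
    extra <- as.vector(rmultinom(1L, rest, rep(1 / n, n)))
    base <- base + extra
  }
  base
}

# Realize an IUPAC consensus into a concrete site text.
realize_iupac <- function(consensus) {
  sets <- iupac_sets()
  paste(vapply(strsplit(consensus, "")[[1]], function(code) {
    s <- sets[[code]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

#' Evolve a family of sequences along a tree
#'
#' Substitutions are applied per branch at the stated per-site rate over
#' the mutable positions; because no indels are introduced the leaf
#' sequences are their own true alignment. With an integer `tree`, a star
#' tree over that many leaves is used.
#'
#' @param ancestor Protein string or [seq_record].
#' @param tree An [ape::phylo] (branch lengths scale the rate) or an
#'   integer number of leaves.
#' @param rate Per-site substitution probability per unit branch length.
#' @param mutable 0-based positions allowed to change; default all.
#' @param leaf_names Names for the leaves of a star tree.
#' @return List with `sequences` (named character; the true alignment) and
#'   `mutated` (named list of 0-based substituted positions per leaf).
#' @export
evolve_family <- function(ancestor, tree, rate, mutable = NULL,
                          leaf_names = NULL) {
  seq0 <- residues_of(ancestor)
  if (is.null(mutable)) mutable <- seq_len(nchar(seq0)) - 1L
  if (is.numeric(tree) && length(tree) == 1L) {
    n <- as.integer(tree)
    leaf_names <- leaf_names %||% sprintf("leaf%02d", seq_len(n))
    seqs <- character(n); muts <- vector("list", n)
    for (i in seq_len(n)) {
      m <- mutate_protein(seq0, rate, mutable)
      seqs[i] <- m$protein; muts[[i]] <- m$mutated
    }
    names(seqs) <- leaf_names; names(muts) <- leaf_names
    return(list(sequences = seqs, mutated = muts))
  }
  assert_that(inherits(tree, "phylo"), "tree must be a phylo or an integer")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  states <- vector("list", n_tip + n_node)
  mut_acc <- vector("list", n_tip + n_node)
  root <- n_tip + 1L
  states[[root]] <- seq0
  mut_acc[[root]] <- integer(0)
  # postorder lists each child before its parent; reversing guarantees every
  # parent state exists before its children are visited
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(post$edge)))) {
    parent <- post$edge[e, 1]; child <- post$edge[e, 2]
    bl <- (post$edge.length %||% rep(1, nrow(post$edge)))[e]
    m <- mutate_protein(states[[parent]], min(1, rate * bl), mutable)
    states[[child]] <- m$protein
    mut_acc[[child]] <- sort(unique(c(mut_acc[[parent]], m$mutated)))
  }
  seqs <- unlist(states[seq_len(n_tip)])
  names(seqs) <- tree$tip.label
  muts <- mut_acc[seq_len(n_tip)]
  names(muts) <- tree$tip.label
  list(sequences = seqs, mutated = muts)
}
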