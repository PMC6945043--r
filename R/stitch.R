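# TBLASTN-HSP-guided gene-model construction. Inter-HSP gaps are closed by
# GT..AG introns whose boundaries maximize amino-acid identity to a
# reference protein within a bounded search window around the HSP edges,
# operationalizing manual boundary curation in favor of maximal homology.

#' Construct a high-scoring segment pair (HSP)
#'
#' Intervals are 0-based half-open; `genomic_interval` is on the forward
#' scaffold strand, `query_interval` on the reference protein. The genomic
#' length must be exactly three times the protein length (ungapped TBLASTN
#' block).
#'
#' @param scaffold_id,strand Location of the hit.
#' @param genomic_interval,query_interval Length-2 integer vectors.
#' @param frame TBLASTN frame (-3..-1, 1..3), informational.
#' @param score Alignment score, informational.
#' @return Object of class `hsp`.
#' @export
hsp <- function(scaffold_id, strand, genomic_interval, query_interval,
                frame = NA_integer_, score = 0) {
  assert_that(strand %in% c("+", "-"), "hsp: bad strand")
  g <- as.integer(genomic_interval); q <- as.integer(query_interval)
  assert_that(g[2] > g[1] && q[2] > q[1], "hsp: empty interval")
  assert_that((g[2] - g[1]) == 3L * (q[2] - q[1]),
              "hsp: genomic length must be 3x protein length",
              class = "gatafam_validation_error")
  structure(list(scaffold_id = scaffold_id, strand = strand,
                 genomic_interval = g, query_interval = q,
                 frame = frame, score = score),
            class = "hsp")
}

#' Read TBLASTN HSPs from a tabular file
#'
#' Accepts outfmt-6-like columns. Column names are configurable; the
#' defaults expect `sseqid`, `sstart`, `send`, `qstart`, `qend`,
#' `bitscore` with 1-based inclusive coordinates and `sstart > send`
#' indicating a minus-strand hit (BLAST convention).
#'
#' @param path Tab-separated file with a header row.
#' @param columns Named list mapping the fields used here to column names.
#' @return List of [hsp] objects.
#' @export
read_hsps <- function(path, columns = list(sseqid = "sseqid",
                                           sstart = "sstart", send = "send",
                                           qstart = "qstart", qend = "qend",
                                           bitscore = "bitscore")) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- unlist(columns[c("sseqid", "sstart", "send", "qstart", "qend")])
  missing_cols <- setdiff(need, names(tab))
  assert_that(length(missing_cols) == 0L, "HSP table missing column(s): ",
              paste(missing_cols, collapse = ", "),
              class = "gatafam_config_error")
  lapply(seq_len(nrow(tab)), function(i) {
    s1 <- tab[[columns$sstart]][i]; s2 <- tab[[columns$send]][i]
    strand <- if (s1 <= s2) "+" else "-"
    gs <- min(s1, s2) - 1L; ge <- max(s1, s2)
    hsp(tab[[columns$sseqid]][i], strand, c(gs, ge),
        c(tab[[columns$qstart]][i] - 1L, tab[[columns$qend]][i]),
        score = if (!is.null(tab[[columns$bitscore]]))
          tab[[columns$bitscore]][i] else 0)
  })
}

identity_frac <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0)
  sum(ca[seq_len(n)] == cb[seq_len(n)]) / max(length(ca), length(cb))
}

translate_plain <- function(dna) {
  n_codon <- nchar(dna) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(dna, 3L * (seq_len(n_codon) - 1L) + 1L,
                      3L * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Stitch TBLASTN HSPs into a gene-model candidate
#'
#' All HSPs must lie on one scaffold and strand with non-conflicting query
#' intervals. Each inter-HSP gap is closed by a GT..AG intron searched
#' within `window` bp of the HSP edges; among frame-consistent candidates
#' the splice maximizing identity to the reference protein is chosen (ties
#' prefer boundaries closest to the HSP edges). A candidate intron shorter
#' than `short_intron_max` bp whose removal keeps the frame open is
#' read through instead whenever the read-through variant scores higher
#' identity; ties keep the intron. The model is then extended to the
#' nearest suitable in-frame ATG upstream and through the stop codon
#' downstream.
#'
#' @param hsps List of [hsp] objects.
#' @param scaffold Scaffold [seq_record] or DNA string.
#' @param reference Reference protein [seq_record] or string.
#' @param gene_id,species,family Passed to the resulting [gene_model].
#' @param window Search half-width around each HSP edge, bp.
#' @param short_intron_max Threshold below which the read-through judgment
#'   is applied, bp.
#' @return A [gene_model] with an extra `stitch_info` field:
#'   `unresolved_gaps`, `has_start`, `has_stop`.
#' @export
stitch_hsps <- function(hsps, scaffold, reference, gene_id = "stitched",
                        species = NA_character_, family = "other",
                        window = 30L, short_intron_max = 50L) {
  assert_that(length(hsps) >= 1L, "stitch_hsps: no HSPs")
  strand <- hsps[[1]]$strand
  scafid <- hsps[[1]]$scaffold_id
  assert_that(all(vapply(hsps, function(h) h$strand == strand &&
                           h$scaffold_id == scafid, logical(1))),
              "stitch_hsps: HSPs must share one scaffold and strand")
  fwd <- residues_of(scaffold)
  L <- nchar(fwd)
  ref <- residues_of(reference)
  # Work in transcribed coordinates: plus strand of the transcribed sequence.
  tseq <- if (strand == "-") revcomp(fwd) else fwd
  tg <- lapply(hsps, function(h) {
    g <- h$genomic_interval
    if (strand == "-") c(L - g[2], L - g[1]) else g
  })
  qs <- vapply(hsps, function(h) h$query_interval[1], integer(1))
  qe <- vapply(hsps, function(h) h$query_interval[2], integer(1))
  ord <- order(qs)
  tg <- tg[ord]; qs <- qs[ord]; qe <- qe[ord]
  n <- length(hsps)
  if (n > 1L) {
    assert_that(all(qs[-1] >= qe[-n]),
                "stitch_hsps: conflicting query intervals",
                class = "gatafam_validation_error")
    gstarts <- vapply(tg, `[`, integer(1), 1)
    assert_that(all(diff(gstarts) > 0),
                "stitch_hsps: HSP order along scaffold conflicts with query order",
                class = "gatafam_validation_error")
  }
  starts <- vapply(tg, `[`, integer(1), 1)
  ends <- vapply(tg, `[`, integer(1), 2)
  merged_into_prev <- rep(FALSE, n)
  unresolved <- 0L

  at <- function(i, j) substr(tseq, i + 1L, j)  # 0-based half-open slice

  for (i in seq_len(max(0L, n - 1L))) {
    g1s <- tg[[i]][1]; e1 <- tg[[i]][2]
    s2 <- tg[[i + 1]][1]; g2e <- tg[[i + 1]][2]
    span3 <- 3L * (qe[i + 1] - qs[i])
    ref_seg <- substr(ref, qs[i] + 1L, qe[i + 1])
    # collinear HSPs: the inter-HSP genomic span codes straight through
    merge_idty <- -1
    if (g2e - g1s == span3) {
      merge_prot <- translate_plain(at(g1s, g2e))
      if (!grepl("\\*", merge_prot)) {
        merge_idty <- identity_frac(merge_prot, ref_seg)
      }
    }
    cands <- list()
    for (d in seq(max(g1s + 3L, e1 - window), min(e1 + window, s2), by = 1L)) {
      a <- g2e - span3 + (d - g1s)
      if (a - d < 4L) next
      if (abs(a - s2) > window) next
      if (a > g2e - 3L) next
      if (substr(tseq, d + 1L, d + 2L) != "GT") next
      if (substr(tseq, a - 1L, a) != "AG") next
      cand_cds <- paste0(at(g1s, d), at(a, g2e))
      idty <- identity_frac(translate_plain(cand_cds), ref_seg)
      cands[[length(cands) + 1L]] <- list(d = d, a = a, idty = idty)
    }
    if (length(cands) == 0L) {
      if (merge_idty >= 0) {
        merged_into_prev[i + 1L] <- TRUE
      } else {
        unresolved <- unresolved + 1L
        log_debug(gene_id, ": gap ", i, " unresolved (no GT..AG in window); ",
                  "both candidate exons retained")
      }
      next
    }
    idtys <- vapply(cands, `[[`, numeric(1), "idty")
    ds <- vapply(cands, `[[`, integer(1), "d")
    best <- order(-idtys, abs(ds - e1), ds)[1]
    d <- cands[[best]]$d; a <- cands[[best]]$a
    spliced_idty <- cands[[best]]$idty
    if (merge_idty > spliced_idty) {  # ties keep the intron
      merged_into_prev[i + 1L] <- TRUE
      next
    }
    intron_len <- a - d
    if (intron_len < short_intron_max && intron_len %% 3L == 0L) {
      rt_prot <- translate_plain(at(g1s, g2e))
      if (!grepl("\\*", rt_prot)) {
        k <- (d - g1s) %/% 3L
        ins <- intron_len %/% 3L
        ref_chars <- strsplit(ref_seg, "")[[1]]
        rt_chars <- strsplit(rt_prot, "")[[1]]
        pref <- sum(rt_chars[seq_len(k)] == ref_chars[seq_len(k)])
        n_suf <- length(ref_chars) - k
        suf <- sum(rt_chars[k + ins + seq_len(n_suf)] ==
                     ref_chars[k + seq_len(n_suf)])
        rt_idty <- (pref + suf) / length(rt_chars)
        if (rt_idty > spliced_idty) {
          log_debug(gene_id, ": gap ", i, " read through (", intron_len,
                    " bp, identity ", round(rt_idty, 3), " > ",
                    round(spliced_idty, 3), ")")
          merged_into_prev[i + 1L] <- TRUE
          next
        }
      }
    }
    ends[i] <- d
    starts[i + 1L] <- a
  }

  # Start-codon choice: walk upstream in frame from the first exon start,
  # stopping at a stop codon; pick the ATG whose added length best covers
  # the reference amino terminus, ties to the most upstream.
  has_start <- FALSE
  q_need <- qs[1]
  atg_ks <- integer(0)
  k <- 0L
  repeat {
    pos <- starts[1] - 3L * k
    if (pos < 0L) break
    codon <- at(pos, pos + 3L)
    if (k > 0L && codon %in% STOP_CODONS) break
    if (codon == "ATG") atg_ks <- c(atg_ks, k)
    k <- k + 1L
  }
  if (length(atg_ks) > 0L) {
    best_k <- atg_ks[order(abs(atg_ks - q_need), -atg_ks)][1]
    starts[1] <- starts[1] - 3L * best_k
    has_start <- TRUE
  } else {
    log_debug(gene_id, ": no in-frame ATG found upstream")
  }

  # Stop extension downstream (the stop codon is included in the CDS).
  has_stop <- FALSE
  if (unresolved == 0L) {
    pos <- ends[n]
    while (pos + 3L <= nchar(tseq)) {
      codon <- at(pos, pos + 3L)
      pos <- pos + 3L
      if (codon %in% STOP_CODONS) {
        has_stop <- TRUE
        break
      }
    }
    if (has_stop) ends[n] <- pos
  }

  # Collapse read-through merges into single exons.
  ex_s <- integer(0); ex_e <- integer(0)
  for (i in seq_len(n)) {
    if (i > 1L && merged_into_prev[i]) {
      ex_e[length(ex_e)] <- ends[i]
    } else {
      ex_s <- c(ex_s, starts[i]); ex_e <- c(ex_e, ends[i])
    }
  }
  exons_t <- cbind(ex_s, ex_e)
  exons_fwd <- if (strand == "-") {
    cbind(L - exons_t[, 2], L - exons_t[, 1])
  } else {
    exons_t
  }
  model <- gene_model(gene_id = gene_id, species = species, family = family,
                      scaffold_id = scafid, strand = strand,
                      exons = exons_fwd)
  model$stitch_info <- list(unresolved_gaps = unresolved,
                            has_start = has_start, has_stop = has_stop)
  model
}
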