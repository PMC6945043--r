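# Promoter extraction, IUPAC consensus scanning on both strands, Poisson
# enrichment p-values, polypyrimidine tract detection, and family-level
# site summaries.
#
# Scanning counts a match at every start offset (no greedy consumption):
# overlapping occurrences are biologically meaningful here because the
# double SKN-1 site is itself two overlapping core sites.

#' Construct a motif definition
#'
#' @param name Motif name.
#' @param consensus IUPAC consensus string (length >= 4).
#' @param strands Default scanning mode, `"both"` or `"top"`.
#' @param notes Free text.
#' @return Object of class `motif_definition`.
#' @export
motif_definition <- function(name, consensus, strands = "both", notes = "") {
  consensus <- toupper(consensus)
  assert_that(nchar(consensus) >= 4L, "motif '", name,
              "': consensus shorter than 4")
  bad <- setdiff(unique(strsplit(consensus, "")[[1]]),
                 names(Biostrings::IUPAC_CODE_MAP))
  assert_that(length(bad) == 0L, "motif '", name,
              "': non-IUPAC character(s) ", paste(bad, collapse = ","))
  assert_that(strands %in% c("both", "top"), "motif '", name,
              "': strands must be 'both' or 'top'")
  structure(list(name = name, consensus = consensus, strands = strands,
                 notes = notes),
            class = "motif_definition")
}

#' Load a motif lexicon
#'
#' Reads a YAML lexicon (`motifs:` list of `name`/`consensus`/`strands`/
#' `notes` entries). With no argument the lexicon shipped with the package
#' is loaded, which carries the med/end promoter motifs (SKN-1 cores and
#' variants, the MED `AGTATAC` site, and accessory elements).
#'
#' @param path YAML file; default the packaged lexicon.
#' @return Named list of [motif_definition] objects.
#' @export
read_motif_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_lexicon.yaml", package = "gatafam")
  }
  assert_that(file.exists(path), "no such lexicon: ", path,
              class = "gatafam_config_error")
  raw <- yaml::read_yaml(path)
  assert_that(!is.null(raw$motifs), "lexicon ", path, ": no 'motifs' key",
              class = "gatafam_config_error")
  out <- lapply(raw$motifs, function(m) {
    motif_definition(m$name, m$consensus, m$strands %||% "both",
                     m$notes %||% "")
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

empty_sites <- function() {
  data.frame(motif_name = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Every matching start offset is reported (overlaps allowed). Minus-strand
#' matches are reported with forward-strand coordinates, strand `"-"`, and
#' the matched text as read on the minus strand. A match identical in
#' interval on both strands (a palindromic hit) is reported once with
#' strand `"+"`. `N` in the scanned sequence never satisfies a non-`N`
#' consensus code.
#'
#' @param seq DNA string or [seq_record].
#' @param motif A [motif_definition].
#' @param strands `"both"` or `"top"`; defaults to the motif's own setting.
#' @return Data.frame with `motif_name`, `start` (0-based), `end`,
#'   `strand`, `matched_text`.
#' @export
scan_iupac <- function(seq, motif, strands = NULL) {
  seq <- residues_of(seq)
  strands <- strands %||% motif$strands
  strands <- match.arg(strands, c("both", "top"))
  w <- nchar(motif$consensus)
  if (nchar(seq) < w) return(empty_sites())
  subject <- Biostrings::DNAString(seq)
  hit_rows <- function(consensus, strand_label) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(consensus), subject,
                                  fixed = "subject")
    if (length(m) == 0L) return(NULL)
    s0 <- Biostrings::start(m) - 1L
    txt <- as.character(m)
    if (strand_label == "-") txt <- vapply(txt, revcomp, character(1),
                                           USE.NAMES = FALSE)
    data.frame(motif_name = motif$name, start = s0, end = s0 + w,
               strand = strand_label, matched_text = txt,
               stringsAsFactors = FALSE)
  }
  plus <- hit_rows(motif$consensus, "+")
  if (strands == "top") {
    return(plus %||% empty_sites())
  }
  minus <- hit_rows(revcomp(motif$consensus), "-")
  if (!is.null(plus) && !is.null(minus)) {
    dup <- minus$start %in% plus$start  # palindromic: same interval both ways
    minus <- minus[!dup, , drop = FALSE]
  }
  out <- rbind(plus %||% empty_sites(), minus %||% empty_sites())
  out[order(out$start, out$strand), , drop = FALSE]
}

# Mononucleotide composition of a DNA string (N excluded from the
# denominator); falls back to uniform for an all-N sequence.
base_composition <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b),
                   numeric(1))
  if (sum(counts) == 0) return(c(A = .25, C = .25, G = .25, T = .25))
  counts / sum(counts)
}

match_probability <- function(consensus, comp) {
  sets <- iupac_sets()
  prod(vapply(strsplit(consensus, "")[[1]], function(code) {
    sum(comp[sets[[code]]])
  }, numeric(1)))
}

#' Poisson enrichment of a motif in a sequence
#'
#' The null expectation `lambda` sums, over every scanned offset and
#' strand, the probability that an i.i.d. mononucleotide background matches
#' the consensus. By default the background composition is that of the
#' scanned sequence itself (`"promoter"`); `"uniform"` and a user-supplied
#' composition are available. The p-value is the Poisson upper tail
#' `P(X >= k; lambda)`.
#'
#' @param seq DNA string or [seq_record]; must be at least as long as the
#'   motif.
#' @param motif A [motif_definition].
#' @param strands `"both"` or `"top"`.
#' @param background `"promoter"`, `"uniform"` or `"given"`.
#' @param composition Length-4 named vector (A,C,G,T) when
#'   `background = "given"`.
#' @param k Optional externally supplied count; checked against the scan.
#' @param gene_id Carried into the result for bookkeeping.
#' @return An `enrichment_result`: list with `gene_id`, `motif_name`,
#'   `observed`, `lambda`, `p_value`.
#' @export
poisson_enrichment <- function(seq, motif, strands = NULL,
                               background = c("promoter", "uniform", "given"),
                               composition = NULL, k = NULL,
                               gene_id = NA_character_) {
  background <- match.arg(background)
  seq <- residues_of(seq)
  strands <- strands %||% motif$strands
  w <- nchar(motif$consensus)
  assert_that(nchar(seq) >= w, "sequence shorter than motif '", motif$name,
              "'", class = "gatafam_validation_error")
  k_scan <- nrow(scan_iupac(seq, motif, strands))
  if (!is.null(k)) {
    assert_that(k == k_scan, "supplied k (", k, ") does not equal scan count (",
                k_scan, ") for motif '", motif$name, "'",
                class = "gatafam_validation_error")
  }
  k <- k_scan
  comp <- switch(background,
    promoter = base_composition(seq),
    uniform = c(A = .25, C = .25, G = .25, T = .25),
    given = {
      assert_that(!is.null(composition) &&
                    all(c("A", "C", "G", "T") %in% names(composition)),
                  "background='given' needs a named A,C,G,T composition")
      composition[c("A", "C", "G", "T")] / sum(composition[c("A", "C", "G", "T")])
    })
  n_offsets <- nchar(seq) - w + 1L
  p_plus <- match_probability(motif$consensus, comp)
  lambda <- if (strands == "both") {
    p_minus <- match_probability(revcomp(motif$consensus), comp)
    n_offsets * (p_plus + p_minus)
  } else {
    n_offsets * p_plus
  }
  structure(list(gene_id = gene_id, motif_name = motif$name, observed = k,
                 lambda = lambda,
                 p_value = ppois(k - 1L, lambda, lower.tail = FALSE)),
            class = "enrichment_result")
}

#' Extract the promoter of a gene model
#'
#' Returns the `window` bases immediately 5' of the ATG on the transcribed
#' strand (reverse-complemented for minus-strand genes). When the scaffold
#' end intervenes the promoter is shorter and flagged truncated. Site
#' positions downstream are conventionally reported as bp upstream of the
#' ATG, where 1 is the base immediately 5' of the A.
#'
#' @param model A [gene_model]; the ATG is taken at the transcription start
#'   of the first exon.
#' @param scaffold Scaffold [seq_record] or DNA string.
#' @param window Promoter window in bp (default 600).
#' @return A `promoter_region`: list with `gene_id`, `sequence`, `length`,
#'   `truncated`, `offset_of_atg`.
#' @export
extract_promoter <- function(model, scaffold, window = 600L) {
  seq <- residues_of(scaffold)
  L <- nchar(seq)
  window <- as.integer(window)
  if (model$strand == "+") {
    atg <- model$exons[1, 1]
    lo <- max(0L, atg - window)
    assert_that(atg > 0L, "gene ", model$gene_id,
                ": no upstream sequence on scaffold",
                class = "gatafam_bounds_error")
    prom <- subseq_fwd(seq, lo, atg)
  } else {
    atg <- model$exons[1, 2]  # transcription-first exon's genomic end
    hi <- min(L, atg + window)
    assert_that(atg < L, "gene ", model$gene_id,
                ": no upstream sequence on scaffold",
                class = "gatafam_bounds_error")
    prom <- revcomp(subseq_fwd(seq, atg, hi))
  }
  truncated <- nchar(prom) < window
  if (truncated) {
    log_debug("gene ", model$gene_id, ": truncated promoter (",
              nchar(prom), " bp)")
  }
  structure(list(gene_id = model$gene_id, sequence = prom,
                 length = nchar(prom), truncated = truncated,
                 offset_of_atg = nchar(prom)),
            class = "promoter_region")
}

#' Convert promoter scan coordinates to bp upstream of the ATG
#'
#' @param sites Site data.frame from [scan_iupac()] run on a promoter.
#' @param promoter_length Length of the scanned promoter.
#' @return `sites` with an added `upstream` column (site start, 1 = base
#'   immediately 5' of the ATG).
#' @export
add_upstream_positions <- function(sites, promoter_length) {
  sites$upstream <- promoter_length - sites$start
  sites
}

#' Summarize motif sites across a gene family
#'
#' Input is one representative gene per species. Means are computed only
#' over genes carrying at least one site; spacing is the mean distance
#' between consecutive site starts within a gene (reported `NA` when no
#' gene has two sites).
#'
#' @param sites Data.frame with columns `gene_id`, `species`, `start`,
#'   `strand`, `upstream` (see [add_upstream_positions()]).
#' @param motif_name Motif being summarized.
#' @param family Family label carried into the output.
#' @param d_atg Distance threshold (bp upstream of the ATG) for the
#'   proximal-site fraction; conventionally 300 for med-context and 200
#'   for end-context summaries.
#' @return One-row data.frame (class `family_site_summary`).
#' @export
summarize_family <- function(sites, motif_name, family = NA_character_,
                             d_atg = 300L) {
  assert_that(nrow(sites) > 0L, "summarize_family: empty site table",
              class = "gatafam_validation_error")
  per_gene <- split(sites, sites$gene_id)
  counts <- vapply(per_gene, nrow, integer(1))
  spacings <- unlist(lapply(per_gene, function(g) {
    if (nrow(g) < 2L) return(NULL)
    diff(sort(g$start))
  }))
  out <- data.frame(
    motif_name = motif_name,
    family = family,
    n_species_with_site = length(unique(sites$species)),
    n_genes_with_site = length(per_gene),
    mean_sites_per_gene_with_site = mean(counts),
    mean_nearest_spacing = if (length(spacings) > 0L) mean(spacings) else NA_real_,
    fraction_within_d_of_atg = mean(sites$upstream <= d_atg),
    top_strand_fraction = mean(sites$strand == "+"),
    n_sites = nrow(sites),
    stringsAsFactors = FALSE
  )
  class(out) <- c("family_site_summary", class(out))
  out
}

#' Detect polypyrimidine (PPY) / polypurine tracts
#'
#' Maximal windows of length at least `min_len` whose C+T fraction on the
#' top strand is at least `min_fraction` are reported as top-strand PPY
#' tracts; symmetrically, A+G-rich windows are reported as bottom-strand
#' PPY tracts (the pyrimidine run lies on the minus strand).
#'
#' @param seq DNA string or [seq_record].
#' @param min_len Minimum tract length (default 12).
#' @param min_fraction Minimum defining-base fraction (default 0.9).
#' @return Data.frame with `motif_name` (`ppy`), `start`, `end`, `strand`,
#'   `matched_text`, `fraction`.
#' @export
detect_ppy_tracts <- function(seq, min_len = 12L, min_fraction = 0.9) {
  seq <- residues_of(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  tract_scan <- function(is_def, strand_label) {
    if (n < min_len) return(NULL)
    cum <- c(0L, cumsum(is_def))
    frac <- function(s, e) (cum[e + 1L] - cum[s + 1L]) / (e - s)  # 0-based
    rows <- list()
    for (s in 0:(n - min_len)) {
      best_e <- -1L
      for (e in seq(s + min_len, n)) {
        if (frac(s, e) >= min_fraction) best_e <- e
      }
      if (best_e > 0L) {
        rows[[length(rows) + 1L]] <- c(s, best_e)
      }
    }
    if (length(rows) == 0L) return(NULL)
    iv <- do.call(rbind, rows)
    keep <- rep(TRUE, nrow(iv))
    for (i in seq_len(nrow(iv))) {
      contained <- iv[, 1] <= iv[i, 1] & iv[, 2] >= iv[i, 2] &
        (iv[, 1] != iv[i, 1] | iv[, 2] != iv[i, 2])
      if (any(contained & keep)) keep[i] <- FALSE
    }
    iv <- iv[keep, , drop = FALSE]
    data.frame(motif_name = "ppy", start = iv[, 1], end = iv[, 2],
               strand = strand_label,
               matched_text = substring(seq, iv[, 1] + 1L, iv[, 2]),
               fraction = vapply(seq_len(nrow(iv)),
                                 function(i) frac(iv[i, 1], iv[i, 2]),
                                 numeric(1)),
               stringsAsFactors = FALSE)
  }
  top <- tract_scan(chars %in% c("C", "T"), "+")
  bottom <- tract_scan(chars %in% c("A", "G"), "-")
  out <- rbind(top, bottom)
  if (is.null(out)) {
    out <- data.frame(motif_name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matched_text = character(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start), , drop = FALSE]
}
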