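# Protein-level annotation of GATA-family features: C4 zinc-finger
# detection and spacing classification, poly-serine (and Ser/Thr) domain
# detection, the ~25-residue Endodermal GATA Domain (EGD), and pseudogene
# classification.

# C4 finger: C x{2,4} C x{15,19} C x{2} C. The amino gap (2-4) and inner
# spacing (15-19) bounds cover every reported spacing variant (X16-X18
# inner; CXXC and extended CSNPNC-type amino gaps) with one-residue
# margins, so detection does not presuppose the family. Lazy quantifiers
# make each match the shortest consistent spacing at its start position;
# matches are taken left-to-right without overlap.
C4_FINGER_PATTERN <- "(C)(.{2,4}?)(C)(.{15,19}?)(C)(.{2})(C)"

#' Find C4 zinc fingers in a protein
#'
#' @param protein Protein [seq_record] or string, length >= 25.
#' @return List of `zinc_finger` objects, each with 0-based `interval`
#'   (`[start, end)`), `cys_positions` (0-based), `inner_spacing` (residues
#'   between the 2nd and 3rd cysteines), `amino_gap` (residues between the
#'   1st and 2nd) and `amino_gap_sequence`.
#' @export
find_zinc_fingers <- function(protein) {
  seq <- residues_of(protein)
  assert_that(nchar(seq) >= 25L, "protein too short for finger search")
  m <- gregexpr(C4_FINGER_PATTERN, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  lapply(seq_along(starts), function(i) {
    s <- starts[i]; len <- lens[i]
    frag <- substr(seq, s + 1L, s + len)
    # recover internal cysteine offsets by re-matching the anchored pattern
    mm <- regexpr(paste0("^", C4_FINGER_PATTERN), frag, perl = TRUE)
    cs <- as.integer(attr(mm, "capture.start"))
    cl <- as.integer(attr(mm, "capture.length"))
    cys_local <- cs[c(1, 3, 5, 7)] - 1L
    structure(
      list(interval = c(s, s + len),
           cys_positions = s + cys_local,
           inner_spacing = cl[4],
           amino_gap = cl[2],
           amino_gap_sequence = substr(frag, cs[2], cs[2] + cl[2] - 1L)),
      class = "zinc_finger"
    )
  })
}

#' @export
print.zinc_finger <- function(x, ...) {
  cat(sprintf("<zinc_finger> [%d,%d) C%sC-X%d-CXXC\n", x$interval[1],
              x$interval[2], x$amino_gap_sequence, x$inner_spacing))
  invisible(x)
}

#' Classify a zinc finger by its spacing
#'
#' The inner spacing (residues between the 2nd and 3rd cysteines) assigns
#' the label: 18 is the Elegans-group MED-like structure, 17 the canonical
#' GATA/END structure, 16 a diverged Japonica-group MED variant, anything
#' else `other`. An amino gap larger than two residues (the END-1
#' CSNPNC-type insertion) is reported as an `extended` gap.
#'
#' @param zf A `zinc_finger` from [find_zinc_fingers()].
#' @return List with `label` (`X18`/`X17`/`X16`/`other`),
#'   `amino_gap_class` (`standard`/`extended`), `amino_gap_sequence`.
#' @export
classify_finger <- function(zf) {
  label <- switch(as.character(zf$inner_spacing),
                  "18" = "X18", "17" = "X17", "16" = "X16", "other")
  list(label = label,
       amino_gap_class = if (zf$amino_gap > 2L) "extended" else "standard",
       amino_gap_sequence = zf$amino_gap_sequence)
}

domain_annotation <- function(kind, start, end, stats = list()) {
  structure(list(kind = kind, interval = c(as.integer(start), as.integer(end)),
                 stats = stats),
            class = "domain_annotation")
}

#' Detect the amino-terminal poly-serine domain
#'
#' Looks for the maximal interval beginning at the first serine run (length
#' >= 3) starting within the first 10 residues, extended while every
#' 10-residue window keeps the defining-residue fraction at or above 0.5.
#' `serine_only` counts S (the END-type Poly-S domain); `ser_thr` counts
#' S and T (the MED-type Poly-S/T region). Returns `NULL` when no
#' qualifying run exists.
#'
#' @param protein Protein [seq_record] or string, length >= 10.
#' @param mode `"serine_only"` or `"ser_thr"`.
#' @param min_run Minimum seed-run length.
#' @param window,min_fraction Window rule operationalizing "homopolymeric
#'   clusters".
#' @return A `domain_annotation` of kind `poly_s`/`poly_st`, or `NULL`.
#' @export
detect_poly_s <- function(protein, mode = c("serine_only", "ser_thr"),
                          min_run = 3L, window = 10L, min_fraction = 0.5) {
  mode <- match.arg(mode)
  seq <- residues_of(protein)
  assert_that(nchar(seq) >= 10L, "protein too short for poly-S search")
  chars <- strsplit(seq, "")[[1]]
  def <- if (mode == "serine_only") chars == "S" else chars %in% c("S", "T")
  runs <- rle(def)
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  seed <- which(runs$values & runs$lengths >= min_run &
                  run_starts <= window)[1]
  if (is.na(seed)) return(NULL)
  s0 <- run_starts[seed]            # 1-based
  e0 <- run_ends[seed]
  n <- length(chars)
  e <- e0
  while (e < n) {
    cand <- e + 1L
    wlo <- max(s0, cand - window + 1L)
    if (mean(def[wlo:cand]) < min_fraction) break
    e <- cand
  }
  while (e > e0 && !def[e]) e <- e - 1L          # trim trailing background
  while (e > e0 && mean(def[s0:e]) < min_fraction) {
    e <- e - 1L
    while (e > e0 && !def[e]) e <- e - 1L
  }
  frac <- mean(def[s0:e])
  domain_annotation(if (mode == "serine_only") "poly_s" else "poly_st",
                    s0 - 1L, e,
                    stats = list(defining_fraction = frac,
                                 n_defining = sum(def[s0:e])))
}

#' Locate the Endodermal GATA Domain (EGD)
#'
#' The EGD is taken as the `width` residues immediately upstream of the
#' first cysteine of the zinc finger. When fewer residues are available the
#' interval is truncated and flagged.
#'
#' @param protein Protein [seq_record] or string.
#' @param zf A `zinc_finger`.
#' @param width Domain width in residues (default 25).
#' @return A `domain_annotation` of kind `egd` with a `truncated` stat.
#' @export
locate_egd <- function(protein, zf, width = 25L) {
  c1 <- zf$cys_positions[1]
  start <- max(0L, c1 - as.integer(width))
  domain_annotation("egd", start, c1,
                    stats = list(truncated = start == 0L && c1 < width))
}

#' Classify a gene as functional, pseudogene, or unresolved duplicate
#'
#' A gene is called a pseudogene when its protein is truncated relative to
#' the family median, carries an in-frame stop or a frameshift within the
#' DNA-binding domain, or lacks an intact C4 finger there (a missing finger
#' cysteine). A near-identical same-assembly duplicate (likely an
#' unresolved haplotype) is reported as `unresolved_duplicate` rather than
#' a pseudogene; a lesion takes precedence over near-duplication.
#'
#' When the model's CDS length is not divisible by 3 the translation
#' downstream of the break is unreliable, so the call is attributed to a
#' frameshift when the DNA-binding domain no longer contains an intact
#' finger, and the finger/stop rules are not applied separately.
#'
#' @param model The gene's [gene_model] (or `NULL` to skip frame checks).
#' @param protein Protein [seq_record] or string.
#' @param dbd_interval 0-based half-open `[start, end)` protein interval of
#'   the DNA-binding domain.
#' @param family_peers List of same-species family proteins ([seq_record]
#'   or strings) for the near-duplicate test; may be empty.
#' @param family_lengths Protein lengths of the family across species, used
#'   for the truncation test; defaults to the peer lengths.
#' @param truncation_fraction Truncation threshold as a fraction of the
#'   family median protein length.
#' @param near_dup_identity Identity threshold for the duplicate test.
#' @return A `pseudogene_call`: list with `status` (`functional`,
#'   `pseudogene`, `unresolved_duplicate`) and `reasons`.
#' @export
classify_pseudogene <- function(model, protein, dbd_interval,
                                family_peers = list(),
                                family_lengths = NULL,
                                truncation_fraction = 0.6,
                                near_dup_identity = 0.99) {
  seq <- residues_of(protein)
  plen <- nchar(seq)
  reasons <- character(0)

  if (is.null(family_lengths)) {
    family_lengths <- vapply(family_peers, function(p) nchar(residues_of(p)),
                             numeric(1))
  }
  if (length(family_lengths) > 0L &&
      plen < truncation_fraction * stats::median(family_lengths)) {
    reasons <- c(reasons, "truncated")
  }

  frame_broken <- !is.null(model) && cds_length(model) %% 3L != 0L
  finger_in_dbd <- FALSE
  if (plen >= 25L) {
    for (zf in find_zinc_fingers(seq)) {
      if (zf$interval[1] < dbd_interval[2] &&
          zf$interval[2] > dbd_interval[1]) {
        finger_in_dbd <- TRUE
        break
      }
    }
  }
  if (frame_broken) {
    if (!finger_in_dbd) reasons <- c(reasons, "frameshift_in_dbd")
  } else {
    stops <- which(strsplit(seq, "")[[1]] == "*") - 1L
    if (any(stops >= dbd_interval[1] & stops < dbd_interval[2])) {
      reasons <- c(reasons, "internal_stop_in_dbd")
    }
    if (!finger_in_dbd) reasons <- c(reasons, "missing_finger_cysteine")
  }

  near_dup <- FALSE
  for (p in family_peers) {
    pseq <- residues_of(p)
    if (identical(pseq, seq)) next  # self
    if (nchar(pseq) == plen) {
      idty <- identity_frac(seq, pseq)
      if (idty >= near_dup_identity) {
        near_dup <- TRUE
        break
      }
    }
  }

  status <- if (length(reasons) > 0L) "pseudogene"
            else if (near_dup) "unresolved_duplicate"
            else "functional"
  if (near_dup) reasons <- c(reasons, "near_identical_duplicate")
  if (status != "functional") {
    log_debug("pseudogene call ", if (!is.null(model)) model$gene_id else "?",
              ": ", status, " (", paste(reasons, collapse = ","), ")")
  }
  structure(list(status = status, reasons = reasons),
            class = "pseudogene_call")
}
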