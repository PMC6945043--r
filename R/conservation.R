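# Alignment-column statistics (invariant counts, consensus), conserved
# block detection, contact-residue conservation scoring, and a lightweight
# neighbor-joining p-distance tree for clade-separation checks.
#
# Gap handling: a column containing any gap is never invariant; the
# identity-fraction denominator excludes gaps (so "conserved" is judged
# among the residues present) while "invariant" is judged over all rows.

alignment_matrix <- function(alignment) {
  if (inherits(alignment, "seq_set") || is.list(alignment)) {
    alignment <- vapply(alignment, residues_of, character(1))
  }
  assert_that(length(alignment) >= 2L, "alignment needs >= 2 sequences",
              class = "gatafam_validation_error")
  lens <- nchar(alignment)
  assert_that(length(unique(lens)) == 1L, "ragged alignment: row lengths ",
              paste(unique(lens), collapse = ", "),
              class = "gatafam_validation_error")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  mat
}

#' Profile a multiple alignment
#'
#' Per-column majority residue, identity fraction (majority count over
#' non-gap rows), gap fraction, and the invariant flag (no gaps and all
#' rows identical). The consensus string shows the majority residue where
#' the identity fraction reaches `consensus_threshold`, else `.`.
#'
#' @param alignment Named character vector, list, or `seq_set` of aligned
#'   sequences (gaps as `-`), all the same length, >= 2 rows.
#' @param consensus_threshold Identity fraction required to print a
#'   consensus residue (default 0.5).
#' @return An `alignment_profile`: list with `n_sequences`, `n_columns`,
#'   `columns` (data.frame: `majority`, `identity_fraction`,
#'   `gap_fraction`, `invariant`), `consensus`.
#' @export
profile_alignment <- function(alignment, consensus_threshold = 0.5) {
  mat <- alignment_matrix(alignment)
  n <- nrow(mat); nc <- ncol(mat)
  majority <- character(nc)
  identity_fraction <- gap_fraction <- numeric(nc)
  invariant <- logical(nc)
  for (j in seq_len(nc)) {
    col <- mat[, j]
    gaps <- sum(col == "-")
    gap_fraction[j] <- gaps / n
    res <- col[col != "-"]
    if (length(res) == 0L) {
      majority[j] <- "-"
      identity_fraction[j] <- 0
    } else {
      tab <- sort(table(res), decreasing = TRUE)
      majority[j] <- names(tab)[1]
      identity_fraction[j] <- tab[1] / length(res)
    }
    invariant[j] <- gaps == 0L && identity_fraction[j] == 1
  }
  consensus <- ifelse(identity_fraction >= consensus_threshold &
                        majority != "-", majority, ".")
  structure(list(
    n_sequences = n, n_columns = nc,
    columns = data.frame(majority = majority,
                         identity_fraction = identity_fraction,
                         gap_fraction = gap_fraction,
                         invariant = invariant),
    consensus = paste(consensus, collapse = "")
  ), class = "alignment_profile")
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat(sprintf("<alignment_profile> %d sequences x %d columns, %d invariant\n",
              x$n_sequences, x$n_columns, sum(x$columns$invariant)))
  invisible(x)
}

#' Count invariant columns in an interval
#'
#' @param profile An `alignment_profile`.
#' @param interval 0-based half-open column interval; `NULL` for all
#'   columns.
#' @return Integer count of invariant columns.
#' @export
count_invariant <- function(profile, interval = NULL) {
  if (is.null(interval)) interval <- c(0L, profile$n_columns)
  assert_that(interval[1] >= 0L && interval[2] <= profile$n_columns,
              "column interval out of range",
              class = "gatafam_validation_error")
  sum(profile$columns$invariant[seq(interval[1] + 1L, interval[2])])
}

#' Conservation at structure-defined contact positions
#'
#' Scores a user-supplied list of alignment columns (e.g., the base-contact
#' residues of a reference GATA-factor structure transcribed onto the
#' alignment): a position is conserved when its identity fraction reaches
#' `threshold`, invariant when the column is invariant.
#'
#' @param profile An `alignment_profile`.
#' @param reference_positions 0-based column indices.
#' @param threshold Identity fraction for "generally conserved"
#'   (default 0.8).
#' @return A `contact_conservation`: list with `reference_positions`,
#'   `n_invariant`, `n_conserved`, `threshold`.
#' @export
contact_conservation <- function(profile, reference_positions,
                                 threshold = 0.8) {
  pos <- as.integer(reference_positions)
  assert_that(all(pos >= 0L & pos < profile$n_columns),
              "contact position outside alignment",
              class = "gatafam_validation_error")
  cols <- profile$columns[pos + 1L, , drop = FALSE]
  structure(list(reference_positions = pos,
                 n_invariant = sum(cols$invariant),
                 n_conserved = sum(cols$identity_fraction >= threshold),
                 threshold = threshold),
            class = "contact_conservation")
}

#' Detect conserved blocks in an alignment
#'
#' Maximal runs of columns whose identity fraction is at least
#' `min_identity`, of length at least `min_len`. Each block is returned as
#' a `domain_annotation` of kind `conserved_block` over column
#' coordinates.
#'
#' @param profile An `alignment_profile`.
#' @param min_len Minimum run length (default 5 columns).
#' @param min_identity Minimum per-column identity fraction (default 0.9).
#' @return List of `domain_annotation` objects.
#' @export
conserved_blocks <- function(profile, min_len = 5L, min_identity = 0.9) {
  ok <- profile$columns$identity_fraction >= min_identity &
    profile$columns$gap_fraction == 0
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hits <- which(runs$values & runs$lengths >= min_len)
  lapply(hits, function(i) {
    cols <- seq(starts[i], ends[i])
    domain_annotation(
      "conserved_block", starts[i] - 1L, ends[i],
      stats = list(mean_identity =
                     mean(profile$columns$identity_fraction[cols]),
                   n_invariant = sum(profile$columns$invariant[cols]))
    )
  })
}

#' Pairwise p-distance matrix of an alignment
#'
#' Fraction of differing positions among columns where neither sequence
#' has a gap (pairwise deletion); `deletion = "complete"` restricts all
#' pairs to columns with no gap in any row.
#'
#' @param alignment As for [profile_alignment()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix.
#' @export
p_distance <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- alignment_matrix(alignment)
  if (deletion == "complete") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) {
        mean(mat[i, ok] != mat[j, ok])
      } else {
        NA_real_
      }
    }
  }
  d
}

#' Neighbor-joining p-distance tree with clade-purity score
#'
#' Builds a neighbor-joining tree on p-distances and scores how well a
#' family labelling is recovered: purity is the fraction of families that
#' form a clade on the unrooted tree (a tip set separable by a single
#' edge; singleton families count as recovered). Tie-breaking among
#' identical sequences is deterministic in input order.
#'
#' @param alignment As for [profile_alignment()]; >= 4 sequences.
#' @param labels Named character vector mapping sequence names to family
#'   labels.
#' @param deletion Gap handling for [p_distance()].
#' @return List with `tree` (an [ape::phylo]), `purity`, `per_family`
#'   (named logical).
#' @export
pdistance_tree <- function(alignment, labels,
                           deletion = c("pairwise", "complete")) {
  if (inherits(alignment, "seq_set") || is.list(alignment)) {
    alignment <- vapply(alignment, residues_of, character(1))
  }
  assert_that(length(alignment) >= 4L, "need >= 4 sequences for a tree",
              class = "gatafam_validation_error")
  assert_that(all(names(alignment) %in% names(labels)),
              "labels missing for some sequences",
              class = "gatafam_validation_error")
  d <- p_distance(alignment, deletion = match.arg(deletion))
  tree <- ape::nj(d)
  fams <- unique(labels[names(alignment)])
  per_family <- vapply(fams, function(f) {
    tips <- names(alignment)[labels[names(alignment)] == f]
    if (length(tips) <= 1L) return(TRUE)
    if (length(tips) == length(alignment)) return(TRUE)
    out_tip <- setdiff(tree$tip.label, tips)[1]
    rooted <- ape::root(tree, outgroup = out_tip, resolve.root = TRUE)
    ape::is.monophyletic(rooted, tips)
  }, logical(1))
  names(per_family) <- fams
  list(tree = tree, purity = mean(per_family), per_family = per_family)
}
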