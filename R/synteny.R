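# Same-scaffold linkage, gap distances, orientation classes, and
# tandem-cluster detection for family members.
#
# Distances are measured between gene extents (outermost exon boundaries),
# not ATGs: extents are strand-neutral and match to-scale linkage diagrams.

#' Pairwise linkage of two gene models
#'
#' @param a,b [gene_model] objects.
#' @return A `synteny_pair`: list with `gene_a`, `gene_b`, `same_scaffold`,
#'   `gap_bp` (`NA` when unlinked) and `orientation` (one of
#'   `same_strand_ab`, `same_strand_ba`, `convergent`, `divergent`, `n/a`).
#' @export
pair_linkage <- function(a, b) {
  same <- identical(a$scaffold_id, b$scaffold_id)
  if (!same) {
    return(structure(list(gene_a = a$gene_id, gene_b = b$gene_id,
                          same_scaffold = FALSE, gap_bp = NA_integer_,
                          orientation = "n/a"),
                     class = "synteny_pair"))
  }
  ea <- model_extent(a); eb <- model_extent(b)
  gap <- max(0L, max(ea[1], eb[1]) - min(ea[2], eb[2]))
  structure(list(gene_a = a$gene_id, gene_b = b$gene_id,
                 same_scaffold = TRUE, gap_bp = as.integer(gap),
                 orientation = classify_orientation(a, b)),
            class = "synteny_pair")
}

#' Classify the relative orientation of two linked genes
#'
#' Four classes: `same_strand_ab` (both genes on one strand with `a`
#' transcribed first), `same_strand_ba` (`b` first), `convergent` (the
#' genes point toward each other, 3' ends adjacent) and `divergent`
#' (transcribed away from a shared intergenic region, 5' ends adjacent).
#'
#' @param a,b [gene_model] objects on the same scaffold.
#' @return Orientation class label.
#' @export
classify_orientation <- function(a, b) {
  assert_that(identical(a$scaffold_id, b$scaffold_id),
              "orientation undefined across scaffolds",
              class = "gatafam_validation_error")
  ea <- model_extent(a); eb <- model_extent(b)
  assert_that(ea[2] <= eb[1] || eb[2] <= ea[1],
              "overlapping gene extents: ", a$gene_id, " / ", b$gene_id,
              class = "gatafam_validation_error")
  left_is_a <- ea[1] < eb[1]
  left <- if (left_is_a) a else b
  right <- if (left_is_a) b else a
  if (left$strand == right$strand) {
    # transcription order: on '+' the left gene is upstream, on '-' the right
    upstream_is_a <- if (left$strand == "+") left_is_a else !left_is_a
    if (upstream_is_a) "same_strand_ab" else "same_strand_ba"
  } else if (left$strand == "+" && right$strand == "-") {
    "convergent"
  } else {
    "divergent"
  }
}

#' Tabulate pairwise linkage for a set of genes
#'
#' @param models List of [gene_model] objects.
#' @return Data.frame, one row per unordered pair.
#' @export
linkage_table <- function(models) {
  n <- length(models)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        p <- pair_linkage(models[[i]], models[[j]])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = p$gene_a, gene_b = p$gene_b,
          same_scaffold = p$same_scaffold, gap_bp = p$gap_bp,
          orientation = p$orientation, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      same_scaffold = logical(0), gap_bp = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Find tandem gene clusters by single-linkage chaining
#'
#' Genes on one scaffold are joined when the gap between their extents is
#' at most `max_gap`; chained groups of two or more are reported. Typical
#' thresholds are 5 kbp for med clusters and 10 kbp for end-3 pairs.
#'
#' @param models List of [gene_model] objects.
#' @param max_gap Maximum allowed gap in bp.
#' @return List of `gene_cluster` objects (`member_gene_ids`, `span_bp`,
#'   `max_internal_gap`, `scaffold_id`).
#' @export
find_clusters <- function(models, max_gap) {
  by_scaf <- split(models, vapply(models, `[[`, character(1), "scaffold_id"))
  clusters <- list()
  for (scaf_models in by_scaf) {
    if (length(scaf_models) < 2L) next
    ext <- t(vapply(scaf_models, model_extent, integer(2)))
    ord <- order(ext[, 1])
    scaf_models <- scaf_models[ord]; ext <- ext[ord, , drop = FALSE]
    run <- 1L
    flush <- function(run_idx) {
      if (length(run_idx) < 2L) return(NULL)
      gaps <- ext[run_idx[-1], 1] - ext[run_idx[-length(run_idx)], 2]
      structure(list(
        member_gene_ids = vapply(scaf_models[run_idx], `[[`, character(1),
                                 "gene_id"),
        span_bp = as.integer(max(ext[run_idx, 2]) - min(ext[run_idx, 1])),
        max_internal_gap = as.integer(max(pmax(gaps, 0L))),
        scaffold_id = scaf_models[[run_idx[1]]]$scaffold_id
      ), class = "gene_cluster")
    }
    run_idx <- 1L
    for (i in seq(2L, length(scaf_models))) {
      gap <- max(0L, ext[i, 1] - ext[i - 1L, 2])
      if (gap <= max_gap) {
        run_idx <- c(run_idx, i)
      } else {
        cl <- flush(run_idx)
        if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
        run_idx <- i
      }
    }
    cl <- flush(run_idx)
    if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
  }
  clusters
}

#' Warn about unlinked genes near scaffold edges
#'
#' A gene whose scaffold ends within `edge_dist` bp of the gene extent may
#' be unlinked only because the assembly breaks there; such cases are
#' flagged so unlinked calls can be interpreted with caution.
#'
#' @param model A [gene_model].
#' @param scaffold Scaffold [seq_record] or DNA string.
#' @param edge_dist Distance threshold in bp (default 10 kbp).
#' @return Logical: `TRUE` when the gene lies near a scaffold end.
#' @export
near_scaffold_edge <- function(model, scaffold, edge_dist = 10000L) {
  L <- nchar(residues_of(scaffold))
  ext <- model_extent(model)
  near <- ext[1] < edge_dist || (L - ext[2]) < edge_dist
  if (near) {
    log_debug("gene ", model$gene_id, " lies within ", edge_dist,
              " bp of a scaffold end; unlinked status may be artifactual")
  }
  near
}
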