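# Gene-structure representation and operations: splice-site validation,
# CDS assembly and translation, protein-coordinate intron mapping,
# cross-ortholog intron comparison, and TBLASTN-HSP-guided stitching.

#' Construct a gene model
#'
#' Exons are stored as `[start, end)` intervals in forward-scaffold
#' coordinates (0-based half-open), ordered in transcription order: by
#' increasing start on the plus strand, decreasing on the minus strand. A
#' model whose total CDS length is not divisible by 3 is automatically
#' flagged as a pseudogene candidate (a frameshift is one of the lesions
#' the pseudogene classifier looks for).
#'
#' @param gene_id,species,scaffold_id Identifiers.
#' @param family One of `"med"`, `"end1"`, `"end3"`, `"other"`.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of exon `[start, end)` intervals.
#' @param is_pseudogene_candidate Logical flag.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species = NA_character_,
                       family = c("other", "med", "end1", "end3"),
                       scaffold_id, strand, exons,
                       is_pseudogene_candidate = FALSE) {
  family <- match.arg(family)
  assert_that(strand %in% c("+", "-"), "gene ", gene_id, ": bad strand")
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2)
  assert_that(nrow(exons) >= 1L, "gene ", gene_id, ": needs >= 1 exon")
  assert_that(all(exons[, 2] > exons[, 1]),
              "gene ", gene_id, ": exon end must exceed start",
              class = "gatafam_validation_error")
  # transcription order
  ord <- order(exons[, 1], decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  by_pos <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(by_pos) > 1L) {
    assert_that(all(by_pos[-1, 1] >= by_pos[-nrow(by_pos), 2]),
                "gene ", gene_id, ": overlapping exons",
                class = "gatafam_validation_error")
  }
  cds_len <- sum(exons[, 2] - exons[, 1])
  if (!is_pseudogene_candidate && cds_len %% 3L != 0L) {
    log_debug("gene ", gene_id, ": CDS length ", cds_len,
              " not divisible by 3; flagged as pseudogene candidate")
    is_pseudogene_candidate <- TRUE
  }
  structure(
    list(gene_id = gene_id, species = species, family = family,
         scaffold_id = scaffold_id, strand = strand, exons = exons,
         is_pseudogene_candidate = is_pseudogene_candidate),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s) %s:%s %d exon(s), CDS %d bp%s\n",
              x$gene_id, x$family, x$species %||% "?", x$scaffold_id,
              x$strand, nrow(x$exons), cds_length(x),
              if (x$is_pseudogene_candidate) " [pseudogene candidate]" else ""))
  invisible(x)
}

#' Total CDS length of a gene model
#' @param model A [gene_model].
#' @return Integer, summed exon lengths in bp.
#' @export
cds_length <- function(model) sum(model$exons[, 2] - model$exons[, 1])

# Outermost extent [start, end) of a model on the forward strand.
model_extent <- function(model) {
  c(min(model$exons[, 1]), max(model$exons[, 2]))
}

# Genomic [start, end) intervals of introns, one row per intron, in
# transcription order.
intron_intervals <- function(model) {
  n <- nrow(model$exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  ex <- model$exons
  if (model$strand == "+") {
    cbind(ex[-n, 2], ex[-1, 1])
  } else {
    cbind(ex[-1, 2], ex[-n, 1])
  }
}

subseq_fwd <- function(seq, start, end) substr(seq, start + 1L, end)

#' Validate splice sites of a gene model
#'
#' Each intron is reported with its donor and acceptor dinucleotides read on
#' the transcribed strand; an intron is canonical iff the donor is `GT` and
#' the acceptor `AG`. Non-canonical introns are flagged, not rejected.
#'
#' @param model A [gene_model].
#' @param scaffold The scaffold [seq_record] (or plain DNA string).
#' @return Data.frame with one row per intron: `intron_index`,
#'   `donor_dinucleotide`, `acceptor_dinucleotide`, `length`, `canonical`,
#'   `protein_position`, `phase` (positions `NA` for frame-broken models).
#' @export
validate_splice_sites <- function(model, scaffold) {
  seq <- residues_of(scaffold)
  ext <- model_extent(model)
  assert_that(ext[1] >= 0L && ext[2] <= nchar(seq),
              "gene ", model$gene_id, ": exon outside scaffold bounds",
              class = "gatafam_bounds_error")
  iv <- intron_intervals(model)
  n_int <- nrow(iv)
  if (n_int == 0L) {
    return(data.frame(intron_index = integer(0),
                      donor_dinucleotide = character(0),
                      acceptor_dinucleotide = character(0),
                      length = integer(0), canonical = logical(0),
                      protein_position = integer(0), phase = integer(0)))
  }
  donor <- acceptor <- character(n_int)
  for (k in seq_len(n_int)) {
    s <- iv[k, 1]; e <- iv[k, 2]
    if (model$strand == "+") {
      donor[k] <- subseq_fwd(seq, s, s + 2L)
      acceptor[k] <- subseq_fwd(seq, e - 2L, e)
    } else {
      donor[k] <- revcomp(subseq_fwd(seq, e - 2L, e))
      acceptor[k] <- revcomp(subseq_fwd(seq, s, s + 2L))
    }
  }
  lens <- iv[, 2] - iv[, 1]
  exon_len <- model$exons[, 2] - model$exons[, 1]
  up <- cumsum(exon_len)[-nrow(model$exons)]
  frame_ok <- cds_length(model) %% 3L == 0L
  data.frame(
    intron_index = seq_len(n_int),
    donor_dinucleotide = donor,
    acceptor_dinucleotide = acceptor,
    length = as.integer(lens),
    canonical = donor == "GT" & acceptor == "AG",
    protein_position = if (frame_ok) as.integer(up %/% 3L) else NA_integer_,
    phase = if (frame_ok) as.integer(up %% 3L) else NA_integer_
  )
}

#' Assemble the coding sequence of a gene model
#'
#' Exon sequences are concatenated in transcription order; minus-strand
#' genes are reverse-complemented so the result reads 5' to 3' on the
#' transcript.
#'
#' @param model A [gene_model].
#' @param scaffold The scaffold [seq_record] (or plain DNA string).
#' @return A DNA [seq_record] named `<gene_id>_cds`.
#' @export
assemble_cds <- function(model, scaffold) {
  seq <- residues_of(scaffold)
  ext <- model_extent(model)
  assert_that(ext[1] >= 0L && ext[2] <= nchar(seq),
              "gene ", model$gene_id, ": exon outside scaffold bounds",
              class = "gatafam_bounds_error")
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    piece <- subseq_fwd(seq, model$exons[i, 1], model$exons[i, 2])
    if (model$strand == "-") revcomp(piece) else piece
  }, character(1))
  seq_record(paste0(model$gene_id, "_cds"), paste(parts, collapse = ""),
             "dna")
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code. The trailing stop codon (if any) is
#' dropped from the protein; internal stops are reported by 0-based codon
#' index and translated as `*`. A CDS whose length is not divisible by 3
#' has its frame flag cleared and the first `floor(length/3)` codons
#' translated.
#'
#' @param cds DNA [seq_record] or string, length >= 3.
#' @return List with `protein` (protein [seq_record]),
#'   `internal_stop_codons` (integer vector of 0-based codon indices),
#'   `frame_ok`, `starts_with_atg`.
#' @export
translate_cds <- function(cds) {
  seq <- residues_of(cds)
  assert_that(nchar(seq) >= 3L, "CDS shorter than one codon")
  n_codon <- nchar(seq) %/% 3L
  frame_ok <- nchar(seq) %% 3L == 0L
  codons <- substring(seq, 3L * (seq_len(n_codon) - 1L) + 1L,
                      3L * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  if (aa[n_codon] == "*") {
    aa <- aa[-n_codon]
  }
  internal <- which(aa == "*") - 1L
  id <- if (inherits(cds, "seq_record")) sub("_cds$", "", cds$id) else "protein"
  list(
    protein = seq_record(paste0(id, "_prot"), paste(aa, collapse = ""),
                         "protein"),
    internal_stop_codons = as.integer(internal),
    frame_ok = frame_ok,
    starts_with_atg = startsWith(seq, "ATG")
  )
}

#' Map intron positions into protein coordinates
#'
#' For each intron, `protein_position` is the 0-based index of the codon
#' the intron interrupts (`floor(upstream_cds_length / 3)`) and `phase` is
#' `upstream_cds_length mod 3`.
#'
#' @param model A [gene_model]; refused for pseudogene-flagged models whose
#'   frame cannot be trusted.
#' @return Data.frame with `intron_index`, `protein_position`, `phase`,
#'   `length`.
#' @export
map_intron_positions <- function(model) {
  if (model$is_pseudogene_candidate) {
    abort("gene ", model$gene_id, ": refusing to map intron positions on a ",
          "pseudogene candidate (reading frame unreliable)")
  }
  assert_that(cds_length(model) %% 3L == 0L,
              "gene ", model$gene_id, ": CDS length not divisible by 3")
  iv <- intron_intervals(model)
  exon_len <- model$exons[, 2] - model$exons[, 1]
  n <- nrow(model$exons)
  if (n < 2L) {
    return(data.frame(intron_index = integer(0),
                      protein_position = integer(0), phase = integer(0),
                      length = integer(0)))
  }
  up <- cumsum(exon_len)[-n]
  data.frame(
    intron_index = seq_len(n - 1L),
    protein_position = as.integer(up %/% 3L),
    phase = as.integer(up %% 3L),
    length = as.integer(iv[, 2] - iv[, 1])
  )
}

# Map a 0-based residue index to its alignment column (0-based) in a gapped
# row.
residue_to_column <- function(aligned_row, residue_index) {
  chars <- strsplit(aligned_row, "")[[1]]
  nongap <- which(chars != "-")
  assert_that(residue_index + 1L <= length(nongap),
              "residue index ", residue_index, " beyond aligned row")
  nongap[residue_index + 1L] - 1L
}

#' Compare intron positions across orthologs
#'
#' Introns are grouped into classes by the alignment column of the residue
#' following the splice together with the phase, so the grouping is robust
#' to indels in the alignment. Each class reports the set of genes carrying
#' it, reproducing the marking of an intron shared by a subset of family
#' members.
#'
#' @param models List of [gene_model] objects.
#' @param alignment Named character vector (or `seq_set`) of aligned
#'   proteins; names must include every model's `gene_id`.
#' @return Data.frame with `column`, `phase`, `genes` (comma-separated),
#'   `n_genes`.
#' @export
compare_intron_positions <- function(models, alignment) {
  if (inherits(alignment, "seq_set") || is.list(alignment)) {
    alignment <- vapply(alignment, residues_of, character(1))
  }
  classes <- list()
  for (m in models) {
    assert_that(m$gene_id %in% names(alignment),
                "gene ", m$gene_id, " not present in alignment",
                class = "gatafam_validation_error")
    row <- alignment[[m$gene_id]]
    ungapped <- gsub("-", "", row)
    n_res <- nchar(ungapped)
    n_codon <- cds_length(m) %/% 3L
    assert_that(n_res %in% c(n_codon, n_codon - 1L),
                "gene ", m$gene_id, ": aligned protein length ", n_res,
                " inconsistent with CDS (", n_codon, " codons)",
                class = "gatafam_validation_error")
    ips <- map_intron_positions(m)
    for (k in seq_len(nrow(ips))) {
      col <- residue_to_column(row, ips$protein_position[k])
      key <- paste0(col, "_", ips$phase[k])
      classes[[key]] <- c(classes[[key]], m$gene_id)
    }
  }
  if (length(classes) == 0L) {
    return(data.frame(column = integer(0), phase = integer(0),
                      genes = character(0), n_genes = integer(0)))
  }
  keys <- names(classes)
  parts <- do.call(rbind, strsplit(keys, "_"))
  out <- data.frame(
    column = as.integer(parts[, 1]),
    phase = as.integer(parts[, 2]),
    genes = vapply(classes, function(g) paste(sort(g), collapse = ","),
                   character(1)),
    n_genes = vapply(classes, length, integer(1)),
    row.names = NULL
  )
  out[order(out$column, out$phase), , drop = FALSE]
}
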