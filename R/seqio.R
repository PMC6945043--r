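# Readers and writers for the external formats the pipeline consumes:
# FASTA (scaffolds, CDS, proteins, promoters, alignments), GFF3 / TSV gene
# models, tabular motif-site listings, and BED6 site export.
#
# Internal coordinates are 0-based half-open on the forward strand of the
# scaffold; GFF3 I/O converts to and from 1-based inclusive.

#' Construct a sequence record
#'
#' The elementary sequence container used throughout the package. DNA
#' records are restricted to `ACGTN` (uppercased on construction); protein
#' records to the 20 amino acids plus `X` and `*`.
#'
#' @param id Record identifier (FASTA header word).
#' @param residues Sequence string.
#' @param alphabet_kind `"dna"` or `"protein"`.
#' @param description Free-text remainder of the FASTA header.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet_kind = c("dna", "protein"),
                       description = "") {
  alphabet_kind <- match.arg(alphabet_kind)
  assert_that(is.character(id) && length(id) == 1L && nzchar(id),
              "seq_record id must be a non-empty string")
  residues <- toupper(as.character(residues))
  assert_that(nchar(residues) > 0L, "seq_record '", id, "': residues empty")
  check_alphabet(residues, alphabet_kind, id)
  structure(
    list(id = id, description = description, residues = residues,
         alphabet_kind = alphabet_kind),
    class = "seq_record"
  )
}

check_alphabet <- function(residues, alphabet_kind, id, where = "") {
  allowed <- if (alphabet_kind == "dna") DNA_ALPHABET_STRICT else PROTEIN_ALPHABET
  chars <- unique(strsplit(residues, "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L) {
    abort("record '", id, "'", where, ": illegal ", alphabet_kind,
          " character(s): ", paste(bad, collapse = ", "),
          class = "gatafam_parse_error")
  }
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s, %d residues\n", x$alphabet_kind, x$id,
              nchar(x$residues)))
  invisible(x)
}

residues_of <- function(x) {
  if (inherits(x, "seq_record")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else if (inherits(x, "XString")) as.character(x)
  else abort("cannot extract residues from object of class ",
             paste(class(x), collapse = "/"))
}

#' Read a FASTA file
#'
#' Records come back in file order with residues uppercased. Scaffold input
#' rejects ambiguity codes other than `N`; ambiguous codes in motif
#' definitions are handled by the scanner, not by sequence records.
#'
#' @param path FASTA file.
#' @param alphabet_kind `"dna"` or `"protein"`.
#' @return Named list of [seq_record] objects (class `seq_set`).
#' @export
read_fasta <- function(path, alphabet_kind = c("dna", "protein")) {
  alphabet_kind <- match.arg(alphabet_kind)
  assert_that(file.exists(path), "no such file: ", path,
              class = "gatafam_io_error")
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(structure(list(), class = "seq_set", alphabet_kind = alphabet_kind))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    abort(path, ": line ", nonempty[1],
          ": expected FASTA header starting with '>'",
          class = "gatafam_parse_error")
  }
  allowed <- if (alphabet_kind == "dna") DNA_ALPHABET_STRICT else PROTEIN_ALPHABET
  for (i in nonempty) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (nchar(ln) < 2L) {
        abort(path, ": line ", i, ": malformed empty FASTA header",
              class = "gatafam_parse_error")
      }
    } else {
      bad <- setdiff(unique(strsplit(toupper(ln), "")[[1]]), allowed)
      if (length(bad) > 0L) {
        abort(path, ": line ", i, ": illegal character(s) ",
              paste(bad, collapse = ","), " for alphabet ", alphabet_kind,
              class = "gatafam_parse_error")
      }
    }
  }
  set <- Biostrings::readBStringSet(path)
  recs <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    seq_record(id, as.character(set[[i]]), alphabet_kind, desc)
  })
  names(recs) <- vapply(recs, `[[`, character(1), "id")
  log_info("read_fasta: ", length(recs), " record(s) from ", path)
  structure(recs, class = "seq_set", alphabet_kind = alphabet_kind)
}

#' Write sequence records as FASTA
#'
#' @param records A `seq_set`, a list of [seq_record], or a named character
#'   vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    assert_that(!is.null(names(records)), "named character vector required")
    seqs <- records
  } else {
    seqs <- vapply(records, residues_of, character(1))
    names(seqs) <- vapply(records, function(r) {
      if (inherits(r, "seq_record") && nzchar(r$description)) {
        paste(r$id, r$description)
      } else if (inherits(r, "seq_record")) r$id else NA_character_
    }, character(1))
    if (anyNA(names(seqs))) names(seqs) <- names(records)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  log_info("write_fasta: ", length(seqs), " record(s) to ", path)
  invisible(path)
}

# ---- site listings ---------------------------------------------------------

#' Default column aliases for motif-site listings
#'
#' The site-listing dialect is configurable because upstream tables vary in
#' their header names; these defaults cover the common variants.
#' @return Named list mapping canonical fields to accepted column names.
#' @export
site_listing_aliases <- function() {
  list(
    gene    = c("gene", "gene_id", "geneid", "id"),
    species = c("species", "organism"),
    motif   = c("motif", "motif_name", "site_name"),
    start   = c("start", "position", "pos", "location"),
    strand  = c("strand", "str", "orientation"),
    site    = c("site", "matched_text", "sequence", "match")
  )
}

#' Read a motif-site listing table
#'
#' Parses a tab- or comma-delimited table of motif sites on promoters. The
#' gene family is inferred from the gene identifier by configurable regular
#' expressions.
#'
#' @param path Delimited text file with a header row.
#' @param aliases Column-alias map, see [site_listing_aliases()].
#' @param family_patterns Named character vector of regexes matched (case-
#'   insensitively) against gene ids to assign the family.
#' @return A data.frame with columns `gene_id`, `species`, `family`,
#'   `motif_name`, `start`, `strand`, `matched_text`.
#' @export
read_site_listing <- function(path, aliases = site_listing_aliases(),
                              family_patterns = c(med = "med",
                                                  end1 = "end-?1",
                                                  end3 = "end-?3")) {
  assert_that(file.exists(path), "no such file: ", path,
              class = "gatafam_io_error")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  cols <- tolower(names(tab))
  pick <- function(field, required = TRUE) {
    hit <- which(cols %in% aliases[[field]])
    if (length(hit) == 0L) {
      if (required) {
        abort("site listing ", path, ": no column for required field '",
              field, "' (accepted: ", paste(aliases[[field]], collapse = ", "),
              ")", class = "gatafam_config_error")
      }
      return(NULL)
    }
    tab[[hit[1]]]
  }
  gene <- as.character(pick("gene"))
  motif <- as.character(pick("motif"))
  start_raw <- pick("start")
  strand <- as.character(pick("strand"))
  species <- pick("species", required = FALSE)
  site <- pick("site", required = FALSE)

  start <- suppressWarnings(as.integer(start_raw))
  bad <- which(is.na(start))
  if (length(bad) > 0L) {
    abort("site listing ", path, ": unparsable position '",
          start_raw[bad[1]], "' at data row ", bad[1],
          class = "gatafam_row_error")
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    abort("site listing ", path, ": invalid strand '", strand[bad[1]],
          "' at data row ", bad[1], class = "gatafam_row_error")
  }
  family <- infer_family(gene, family_patterns)
  out <- data.frame(
    gene_id = gene,
    species = if (is.null(species)) NA_character_ else as.character(species),
    family = family,
    motif_name = motif,
    start = start,
    strand = strand,
    matched_text = if (is.null(site)) NA_character_ else toupper(site),
    stringsAsFactors = FALSE
  )
  log_info("read_site_listing: ", nrow(out), " row(s) from ", path)
  out
}

infer_family <- function(gene_ids, family_patterns) {
  fam <- rep("other", length(gene_ids))
  # end1/end3 patterns are applied before the generic med pattern so that the
  # most specific match wins regardless of list order.
  ord <- order(nchar(family_patterns), decreasing = TRUE)
  for (i in ord) {
    hit <- grepl(family_patterns[i], gene_ids, ignore.case = TRUE)
    fam[hit & fam == "other"] <- names(family_patterns)[i]
  }
  fam
}

# ---- gene model I/O --------------------------------------------------------

#' Read gene models
#'
#' GFF3 input uses 1-based inclusive coordinates and is converted to the
#' internal 0-based half-open convention. The TSV dialect stores internal
#' coordinates directly (`exon_starts`/`exon_ends`, comma-separated).
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return List of [gene_model] objects.
#' @export
read_gene_models <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "no such file: ", path,
              class = "gatafam_io_error")
  models <- if (dialect == "gff3") read_gene_models_gff3(path)
            else read_gene_models_tsv(path)
  log_info("read_gene_models: ", length(models), " model(s) from ", path)
  models
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(gr$type)
  genes <- which(type == "gene")
  cds <- which(type %in% c("CDS", "exon"))
  parent <- vapply(seq_along(gr), function(i) {
    p <- meta$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }, character(1))
  out <- list()
  for (g in genes) {
    gid <- as.character(meta$ID[g])
    members <- cds[parent[cds] == gid]
    assert_that(length(members) > 0L,
                "gene ", gid, " has no CDS/exon children")
    starts <- GenomicRanges::start(gr)[members] - 1L  # to 0-based half-open
    ends <- GenomicRanges::end(gr)[members]
    strand <- as.character(GenomicRanges::strand(gr)[g])
    assert_that(strand %in% c("+", "-"), "gene ", gid, ": missing strand")
    ord <- order(starts, decreasing = (strand == "-"))
    species <- if ("species" %in% names(meta)) as.character(meta$species[g]) else NA_character_
    family <- if ("family" %in% names(meta)) as.character(meta$family[g]) else "other"
    if (is.na(family) || !family %in% c("med", "end1", "end3")) family <- "other"
    out[[gid]] <- gene_model(
      gene_id = gid,
      species = species,
      family = family,
      scaffold_id = as.character(GenomicRanges::seqnames(gr)[g]),
      strand = strand,
      exons = cbind(starts[ord], ends[ord])
    )
  }
  out
}

read_gene_models_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "family", "scaffold_id", "strand",
            "exon_starts", "exon_ends")
  missing_cols <- setdiff(need, names(tab))
  assert_that(length(missing_cols) == 0L,
              "gene model TSV missing column(s): ",
              paste(missing_cols, collapse = ", "),
              class = "gatafam_config_error")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    starts <- as.integer(strsplit(tab$exon_starts[i], ",")[[1]])
    ends <- as.integer(strsplit(tab$exon_ends[i], ",")[[1]])
    gene_model(
      gene_id = tab$gene_id[i],
      species = tab$species[i],
      family = tab$family[i],
      scaffold_id = tab$scaffold_id[i],
      strand = tab$strand[i],
      exons = cbind(starts, ends),
      is_pseudogene_candidate = isTRUE(tab$is_pseudogene_candidate[i])
    )
  })
  names(out) <- tab$gene_id
  out
}

#' Write gene models
#'
#' @param models List of [gene_model] objects.
#' @param path Output file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- data.frame(
      gene_id = vapply(models, `[[`, character(1), "gene_id"),
      species = vapply(models, function(m) m$species %||% NA_character_,
                       character(1)),
      family = vapply(models, `[[`, character(1), "family"),
      scaffold_id = vapply(models, `[[`, character(1), "scaffold_id"),
      strand = vapply(models, `[[`, character(1), "strand"),
      exon_starts = vapply(models, function(m)
        paste(m$exons[, 1], collapse = ","), character(1)),
      exon_ends = vapply(models, function(m)
        paste(m$exons[, 2], collapse = ","), character(1)),
      is_pseudogene_candidate = vapply(models, `[[`, logical(1),
                                       "is_pseudogene_candidate"),
      stringsAsFactors = FALSE
    )
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(models, function(m) {
    ext <- model_extent(m)
    n <- nrow(m$exons)
    lens <- m$exons[, 2] - m$exons[, 1]
    up <- c(0L, cumsum(lens))[seq_len(n)]
    data.frame(
      seqnames = rep(m$scaffold_id, n + 1L),
      start = c(ext[1] + 1L, m$exons[, 1] + 1L),
      end = c(ext[2], m$exons[, 2]),
      strand = rep(m$strand, n + 1L),
      type = c("gene", rep("CDS", n)),
      phase = c(NA_integer_, as.integer((3L - up %% 3L) %% 3L)),
      ID = c(m$gene_id, paste0(m$gene_id, ".cds", seq_len(n))),
      Parent = c(NA_character_, rep(m$gene_id, n)),
      species = c(m$species %||% NA_character_, rep(NA_character_, n)),
      family = c(m$family, rep(NA_character_, n)),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, unname(rows))
  all_gr <- GenomicRanges::GRanges(
    seqnames = tab$seqnames,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand, type = tab$type, phase = tab$phase,
    ID = tab$ID, Parent = tab$Parent, species = tab$species,
    family = tab$family
  )
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}

#' Export motif sites as BED6
#'
#' Coordinates are 0-based half-open; the score column carries
#' `-log10(p value)` when a `p_value` column is present (capped at 1000),
#' otherwise 0.
#'
#' @param sites Data.frame with columns `seqname` (or `gene_id`), `start`,
#'   `end`, `motif_name`, `strand` and optionally `p_value`.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
export_sites_bed <- function(sites, path) {
  chrom <- sites$seqname %||% sites$gene_id
  score <- if (!is.null(sites$p_value)) {
    pmin(round(-log10(pmax(sites$p_value, 1e-300)), 3), 1000)
  } else {
    rep(0, nrow(sites))
  }
  bed <- data.frame(chrom = chrom, start = sites$start, end = sites$end,
                    name = sites$motif_name, score = score,
                    strand = sites$strand, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
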