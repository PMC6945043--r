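test_that("FASTA reading preserves order, uppercases, and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first", "acgt", ">b", "TTggAA", "cc", ">c", "NNNACGT"), f)
  recs <- read_fasta(f, "dna")
  expect_length(recs, 3L)
  expect_identical(names(recs), c("a", "b", "c"))
  expect_identical(recs$a$residues, "ACGT")
  expect_identical(recs$b$residues, "TTGGAACC")
  expect_identical(recs$a$description, "first")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f2)
  again <- read_fasta(f2, "dna")
  expect_identical(lapply(again, `[[`, "residues"),
                   lapply(recs, `[[`, "residues"))
  expect_identical(names(again), names(recs))
})

test_that("FASTA edge cases: empty file, bad characters, bad header", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_length(read_fasta(f, "dna"), 0L)

  writeLines(c(">x", "ACGU"), f)
  err <- tryCatch(read_fasta(f, "dna"), error = identity)
  expect_s3_class(err, "gatafam_parse_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(c("ACGT"), f)
  expect_error(read_fasta(f, "dna"), "header",
               class = "gatafam_parse_error")

  writeLines(c(">p", "MKWX*"), f)
  expect_identical(read_fasta(f, "protein")$p$residues, "MKWX*")
})

test_that("site-listing parser recovers all generator rows and rejects bad rows", {
  tiny <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmotif\tposition\tstrand",
               "sp01_med.1\tskn1_core\t42\t+"), tiny)
  one <- read_site_listing(tiny)
  expect_equal(nrow(one), 1L)
  expect_identical(one$family, "med")
  expect_identical(one$start, 42L)

  ds <- shared_dataset()
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  parsed <- read_site_listing(file.path(d, "sites.tsv"))
  expect_equal(nrow(parsed), nrow(ds$site_listing))
  expect_identical(parsed$gene_id, ds$site_listing$gene_id)
  expect_identical(parsed$start, as.integer(ds$site_listing$start))
  expect_identical(parsed$strand, ds$site_listing$strand)
  expect_identical(parsed$matched_text, ds$site_listing$site)
  fam_true <- ifelse(grepl("end1", ds$site_listing$gene_id), "end1",
                     ifelse(grepl("end3", ds$site_listing$gene_id), "end3",
                            "med"))
  expect_identical(parsed$family, fam_true)

  writeLines(c("gene\tmotif\tposition\tstrand",
               "sp01_med.1\tskn1_core\t42\t0"), tiny)
  expect_error(read_site_listing(tiny), "strand",
               class = "gatafam_row_error")
  writeLines(c("gene\tmotif\tstrand", "sp01_med.1\tskn1_core\t+"), tiny)
  expect_error(read_site_listing(tiny), "start",
               class = "gatafam_config_error")
})

test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "scaf1\ttest\tgene\t101\t200\t.\t+\t.\tID=g1;family=med;species=spA",
    "scaf1\ttest\tCDS\t101\t200\t.\t+\t0\tID=g1.c1;Parent=g1",
    "scaf1\ttest\tgene\t301\t520\t.\t-\t.\tID=g2;family=end1;species=spA",
    "scaf1\ttest\tCDS\t301\t400\t.\t-\t0\tID=g2.c1;Parent=g2",
    "scaf1\ttest\tCDS\t461\t520\t.\t-\t0\tID=g2.c2;Parent=g2"
  ), f)
  models <- read_gene_models(f, "gff3")
  expect_identical(unname(models$g1$exons[1, ]), c(100L, 200L))
  # minus-strand exons come back in transcription order (decreasing start)
  expect_identical(unname(models$g2$exons[, 1]), c(460L, 300L))
  expect_identical(models$g2$strand, "-")

  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(models, f2, "gff3")
  again <- read_gene_models(f2, "gff3")
  expect_identical(again$g1$exons, models$g1$exons)
  expect_identical(again$g2$exons, models$g2$exons)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(models, f3, "tsv")
  tsv <- read_gene_models(f3, "tsv")
  expect_identical(tsv$g2$exons, models$g2$exons)
})

test_that("invalid gene geometry is rejected", {
  expect_error(gene_model("bad", scaffold_id = "s", strand = "+",
                          exons = rbind(c(10, 5))),
               class = "gatafam_validation_error")
  expect_error(gene_model("bad", scaffold_id = "s", strand = "+",
                          exons = rbind(c(0, 30), c(20, 60))),
               "overlapping", class = "gatafam_validation_error")
})
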