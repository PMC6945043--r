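test_that("splice-site validation reads donors/acceptors on the transcribed strand", {
  fx <- two_exon_fixture("+")
  ss <- validate_splice_sites(fx$model, fx$scaffold)
  expect_equal(nrow(ss), 1L)
  expect_identical(ss$donor_dinucleotide, "GT")
  expect_identical(ss$acceptor_dinucleotide, "AG")
  expect_true(ss$canonical)
  expect_equal(ss$length, 17L)

  fm <- two_exon_fixture("-")
  ssm <- validate_splice_sites(fm$model, fm$scaffold)
  expect_true(ssm$canonical)

  # GC donor: flagged non-canonical, not rejected
  gc <- two_exon_fixture("+", intron = "GCAAGTTTTTTTCTCAG")
  ssgc <- validate_splice_sites(gc$model, gc$scaffold)
  expect_false(ssgc$canonical)
  expect_identical(ssgc$donor_dinucleotide, "GC")

  single <- gene_model("one", scaffold_id = "scafP", strand = "+",
                       exons = rbind(c(0, 9)))
  expect_equal(nrow(validate_splice_sites(single, fx$scaffold)), 0L)

  out <- gene_model("oob", scaffold_id = "scafP", strand = "+",
                    exons = rbind(c(0, 3000)))
  expect_error(validate_splice_sites(out, fx$scaffold),
               class = "gatafam_bounds_error")
})

test_that("CDS assembly concatenates exons and honours strand", {
  plus1 <- gene_model("g", scaffold_id = "s", strand = "+",
                      exons = rbind(c(0, 9)))
  expect_identical(assemble_cds(plus1, "ATGAAATAA")$residues, "ATGAAATAA")

  fx <- two_exon_fixture("+")
  expect_identical(assemble_cds(fx$model, fx$scaffold)$residues, fx$cds)
  fm <- two_exon_fixture("-")
  expect_identical(assemble_cds(fm$model, fm$scaffold)$residues, fx$cds)
})

test_that("generator gene models reassemble to their planted CDS", {
  ds <- shared_dataset()
  ids <- names(ds$models)[c(1, 25, 60, 100, 140)]
  for (gid in ids) {
    m <- ds$models[[gid]]
    got <- assemble_cds(m, ds$scaffolds[[m$scaffold_id]])
    expect_identical(got$residues, ds$cds[[gid]]$residues)
    expect_equal(cds_length(m), nchar(ds$cds[[gid]]$residues))
  }
})

test_that("translation follows the standard code and flags defects", {
  tr <- translate_cds("ATGAAATAA")
  expect_identical(tr$protein$residues, "MK")
  expect_length(tr$internal_stop_codons, 0L)
  expect_true(tr$frame_ok)
  expect_true(tr$starts_with_atg)

  tr2 <- translate_cds("ATGTAAAAA")
  expect_identical(tr2$internal_stop_codons, 1L)
  expect_identical(tr2$protein$residues, "M*K")

  tr3 <- translate_cds("ATGAAAT")
  expect_false(tr3$frame_ok)
  expect_identical(tr3$protein$residues, "MK")

  set.seed(42)
  for (rep in 1:5) {
    cds <- paste0("ATG", rnd_dna(297))
    mine <- translate_cds(cds)$protein$residues
    oracle <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), if.fuzzy.codon = "X"))
    if (substr(oracle, 100, 100) == "*") oracle <- substr(oracle, 1, 99)
    expect_identical(mine, oracle)
  }
})

test_that("intron positions map by cumulative CDS arithmetic", {
  mk <- function(len1) {
    gene_model("g", scaffold_id = "s", strand = "+",
               exons = rbind(c(0, len1), c(len1 + 50, len1 + 50 +
                                             (93 - len1))))
  }
  m30 <- mk(30)
  ip <- map_intron_positions(m30)
  expect_equal(ip$protein_position, 10L)
  expect_equal(ip$phase, 0L)
  expect_equal(ip$length, 50L)
  ip31 <- map_intron_positions(mk(31))
  expect_equal(ip31$protein_position, 10L)
  expect_equal(ip31$phase, 1L)

  ps <- gene_model("p", scaffold_id = "s", strand = "+",
                   exons = rbind(c(0, 31)), is_pseudogene_candidate = TRUE)
  expect_error(map_intron_positions(ps), "pseudogene")
})

test_that("exon length sums and phases are consistent on generator models", {
  ds <- shared_dataset()
  checked <- 0L
  for (gid in names(ds$models)) {
    m <- ds$models[[gid]]
    if (m$is_pseudogene_candidate || nrow(m$exons) < 2L) next
    ip <- map_intron_positions(m)
    lens <- m$exons[, 2] - m$exons[, 1]
    up <- cumsum(lens)[-length(lens)]
    expect_identical(ip$phase, as.integer(up %% 3L))
    expect_identical(ip$protein_position, as.integer(up %/% 3L))
    tr <- ds$truth$introns[[gid]]
    expect_identical(ip$protein_position, as.integer(tr$protein_position))
    expect_identical(ip$phase, as.integer(tr$phase))
    expect_identical(ip$length, as.integer(tr$length))
    checked <- checked + 1L
  }
  expect_gt(checked, 40L)
})

test_that("intron classes group by alignment column and survive gap shifts", {
  m1 <- gene_model("gA", scaffold_id = "s", strand = "+",
                   exons = rbind(c(0, 30), c(100, 130)))
  m2 <- gene_model("gB", scaffold_id = "s2", strand = "+",
                   exons = rbind(c(0, 30), c(90, 120)))
  aln <- c(gA = strrep("A", 19), gB = strrep("A", 19))
  classes <- compare_intron_positions(list(m1, m2), aln)
  expect_equal(nrow(classes), 1L)
  expect_identical(classes$genes, "gA,gB")

  # the same proteins with a shared gap column: classes unchanged in
  # membership (position measured in alignment columns)
  aln_gap <- c(gA = paste0(strrep("A", 5), "--", strrep("A", 14)),
               gB = paste0(strrep("A", 5), "--", strrep("A", 14)))
  cl2 <- compare_intron_positions(list(m1, m2), aln_gap)
  expect_identical(cl2$genes, "gA,gB")
  expect_equal(cl2$phase, classes$phase)

  # planted loss: a third ortholog without the intron lacks membership
  m3 <- gene_model("gC", scaffold_id = "s3", strand = "+",
                   exons = rbind(c(0, 60)))
  cl3 <- compare_intron_positions(list(m1, m2, m3),
                                  c(aln, gC = strrep("A", 19)))
  expect_false(grepl("gC", cl3$genes[1]))

  expect_error(compare_intron_positions(list(m1), c(gZ = strrep("A", 19))),
               class = "gatafam_validation_error")
})

test_that("shared zinc-finger intron maps to one aligned class across a family", {
  ds <- shared_dataset()
  reps <- sprintf("sp%02d_end3.1", 1:20)
  models <- ds$models[reps]
  aln <- ds$alignments$end3
  classes <- compare_intron_positions(models, aln)
  # the zinc-finger intron (phase 1, inside the finger) is carried by all
  full <- classes[classes$n_genes == length(reps), , drop = FALSE]
  expect_gte(nrow(full), 1L)
  zf_pos <- ds$truth$ancestors$end3$zf_intron_pos
  expect_true(zf_pos %in% full$column)
})
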