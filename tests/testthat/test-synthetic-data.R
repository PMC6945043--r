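test_that("promoter generation honors composition and planted placements", {
  set.seed(2)
  gc_frac <- replicate(200, {
    pr <- generate_promoter(600, c(A = .25, C = .25, G = .25, T = .25))
    chars <- strsplit(pr$sequence, "")[[1]]
    mean(chars %in% c("G", "C"))
  })
  se <- sqrt(0.25 / 600)
  expect_lt(abs(mean(gc_frac) - 0.5), 3 * se / sqrt(200))

  pr <- generate_promoter(600, c(A = .25, C = .25, G = .25, T = .25),
                          planted = data.frame(text = "ATCATCAT",
                                               strand = "+", start = 100L))
  mot <- motif_definition("skn1_double", "RTCATCAT")
  hits <- scan_iupac(pr$sequence, mot)
  expect_true(100L %in% hits$start)

  # an overlapping double site scans as two core sites at its offsets
  core <- motif_definition("skn1_core", "RTCAT")
  expect_gte(sum(scan_iupac(pr$sequence, core, "top")$start %in%
                   c(100L, 103L)), 2L)
})

test_that("datasets are byte-identical under one seed and differ across seeds", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  generate_dataset(family_spec(seed = 5), outdir = d1)
  generate_dataset(family_spec(seed = 5), outdir = d2)
  generate_dataset(family_spec(seed = 6), outdir = d3)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "scaffolds.fasta"))),
    unname(tools::md5sum(file.path(d3, "scaffolds.fasta")))))
})

test_that("planted features exist exactly once in the truth tables", {
  ds <- shared_dataset()
  tg <- ds$truth$genes
  expect_equal(anyDuplicated(tg$gene_id), 0L)
  expect_setequal(tg$gene_id, names(ds$models))
  expect_setequal(tg$gene_id, names(ds$proteins))
  # every planted site row refers to a representative promoter
  expect_true(all(ds$site_listing$gene_id %in%
                    tg$gene_id[tg$is_representative]))
  # per-species copy numbers in the truth table match the gene set
  per_sp <- table(tg$species, tg$family)
  expect_true(all(per_sp[, "end3"] == ds$truth$species$n_end3))
  expect_true(all(per_sp[, "med"] == ds$truth$species$n_med))
})

test_that("evolve_family applies rates along trees and preserves alignment", {
  anc <- rnd_prot_row(80)
  ev0 <- evolve_family(anc, 4L, rate = 0)
  expect_true(all(ev0$sequences == anc))

  set.seed(14)
  rates <- c(med = 0.3, end3 = 0.15, end1 = 0.04)
  inv <- vapply(rates, function(r) {
    ev <- evolve_family(anc, 12L, rate = r)
    prof <- profile_alignment(ev$sequences)
    sum(prof$columns$invariant)
  }, numeric(1))
  expect_true(inv[["end1"]] > inv[["end3"]])
  expect_true(inv[["end3"]] > inv[["med"]])

  # branch lengths scale divergence on a phylo tree
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ev_t <- evolve_family(anc, tree, rate = 0.05)
  expect_setequal(names(ev_t$sequences), c("a", "b", "c", "d"))
  expect_true(all(nchar(ev_t$sequences) == nchar(anc)))
})

test_that("a pre-speciation duplication leaves orthologs closer than paralogs", {
  set.seed(23)
  anc <- rnd_prot_row(120)
  # duplication before speciation: two paralog lineages diverge first
  dup <- evolve_family(anc, 2L, rate = 0.25,
                       leaf_names = c("para1", "para2"))
  leaves <- list()
  for (p in c("para1", "para2")) {
    sp <- evolve_family(dup$sequences[[p]], 2L, rate = 0.02,
                        leaf_names = paste0(p, c("_spA", "_spB")))
    leaves <- c(leaves, as.list(sp$sequences))
  }
  aln <- unlist(leaves)
  d <- p_distance(aln)
  # cross-species orthologs
  expect_lt(d["para1_spA", "para1_spB"], d["para1_spA", "para2_spA"])
  expect_lt(d["para2_spA", "para2_spB"], d["para2_spB", "para1_spB"])
})

test_that("a zero-pseudogene-rate dataset classifies everything functional", {
  ds0 <- generate_dataset(family_spec(seed = 19, pseudogene_rate = 0))
  expect_true(all(ds0$truth$genes$status != "pseudogene"))
  rep0 <- run_characterize(ds0)
  expect_false(any(rep0$gene_table$status == "pseudogene"))
})

test_that("an infeasible spec is rejected up front", {
  expect_error(family_spec(n_species = 3),
               class = "gatafam_validation_error")
  expect_error(family_spec(pseudogene_rate = 2),
               class = "gatafam_validation_error")
  expect_error(family_spec(polys_tcn_split = c(TCT = 1, TCC = 1,
                                               TCA = 0, TCG = 0)),
               class = "gatafam_validation_error")
})
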