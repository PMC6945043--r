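test_that("alignment profiles report identity, gaps, invariance and consensus", {
  aln <- c(s1 = "MKWAA", s2 = "MKWAA")
  prof <- profile_alignment(aln)
  expect_true(all(prof$columns$invariant))
  expect_identical(prof$consensus, "MKWAA")

  aln2 <- c(s1 = "A-K", s2 = "AAK", s3 = "AGK")
  p2 <- profile_alignment(aln2)
  expect_equal(p2$columns$identity_fraction[2], 0.5)  # among non-gap rows
  expect_equal(p2$columns$gap_fraction[2], 1 / 3)
  expect_false(p2$columns$invariant[2])  # any gap blocks invariance
  expect_true(p2$columns$invariant[1])

  aln3 <- c(s1 = "AAG", s2 = "AAG", s3 = "AGG")
  p3 <- profile_alignment(aln3)
  expect_equal(p3$columns$identity_fraction[2], 2 / 3)
  expect_false(p3$columns$invariant[2])

  expect_error(profile_alignment(c(a = "AAA", b = "AA")),
               "ragged", class = "gatafam_validation_error")
})

test_that("invariant counts respect intervals and shrink when rows are added", {
  aln <- c(a = strrep("K", 10), b = strrep("K", 10))
  expect_equal(count_invariant(profile_alignment(aln)), 10L)
  expect_equal(count_invariant(profile_alignment(aln), c(2L, 7L)), 5L)

  set.seed(4)
  base <- c(a = rnd_prot_row(40), b = rnd_prot_row(40), c = rnd_prot_row(40))
  n0 <- count_invariant(profile_alignment(base))
  extra <- c(base, d = rnd_prot_row(40))
  expect_lte(count_invariant(profile_alignment(extra)), n0)
})

test_that("invariant truth columns of the generated alignments are recovered", {
  ds <- shared_dataset()
  for (fam in c("med", "end1", "end3")) {
    prof <- profile_alignment(ds$alignments[[fam]])
    got <- which(prof$columns$invariant) - 1L
    expect_identical(got, ds$truth$invariant_columns[[fam]])
  }
  # substitution rates ordered med > end3 > end1 give the reverse
  # ordering of invariant fractions over the DBD columns
  frac <- vapply(c("med", "end3", "end1"), function(fam) {
    p <- profile_alignment(ds$alignments[[fam]])
    dbd <- ds$truth$ancestors[[fam]]$dbd
    count_invariant(p, dbd) / (dbd[2] - dbd[1])
  }, numeric(1))
  expect_true(frac[["end1"]] > frac[["end3"]])
  expect_true(frac[["end3"]] > frac[["med"]])
})

test_that("contact-position conservation counts invariant and conserved sites", {
  rows <- vapply(1:20, function(i) {
    chars <- rep("A", 18)
    chars[8:18] <- sample(AA_POOL_TEST, 11, replace = TRUE)  # noisy tail
    paste(chars, collapse = "")
  }, character(1))
  names(rows) <- paste0("r", 1:20)
  prof <- profile_alignment(rows)
  cc <- contact_conservation(prof, 0:6)
  expect_equal(cc$n_invariant, 7L)
  expect_equal(cc$n_conserved, 7L)

  # planted conservation at 7 of 18 positions
  cc18 <- contact_conservation(prof, 0:17)
  expect_equal(cc18$n_invariant, 7L)
  set.seed(8)
  rand_prof <- profile_alignment(
    setNames(vapply(1:20, function(i) rnd_prot_row(18), character(1)),
             paste0("q", 1:20)))
  cc_rand <- contact_conservation(rand_prof, 0:17)
  expect_lte(cc_rand$n_conserved, 2L)
})

test_that("conserved blocks cover planted invariant runs and nothing random", {
  set.seed(21)
  block <- "FGQYF"
  rows <- vapply(1:20, function(i) {
    paste0(rnd_prot_row(30), block, rnd_prot_row(30))
  }, character(1))
  names(rows) <- paste0("r", 1:20)
  prof <- profile_alignment(rows)
  blocks <- conserved_blocks(prof)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$interval, c(30L, 35L))

  # row order does not matter
  prof_rev <- profile_alignment(rev(rows))
  blocks_rev <- conserved_blocks(prof_rev)
  expect_equal(blocks_rev[[1]]$interval, blocks[[1]]$interval)

  # a fully random 20-row alignment yields no blocks at the defaults
  rand_rows <- setNames(vapply(1:20, function(i) rnd_prot_row(80),
                               character(1)), paste0("q", 1:20))
  expect_length(conserved_blocks(profile_alignment(rand_rows)), 0L)

  # fully invariant alignment is one block spanning all columns
  inv <- c(a = strrep("W", 12), b = strrep("W", 12))
  expect_equal(conserved_blocks(profile_alignment(inv))[[1]]$interval,
               c(0L, 12L))
})

test_that("p-distance uses pairwise deletion", {
  aln <- c(a = "AAKK", b = "AA-K", c = "GGKK")
  d <- p_distance(aln)
  expect_equal(d["a", "b"], 0)        # gapped column dropped pairwise
  expect_equal(d["a", "c"], 0.5)
  expect_equal(d["b", "c"], 2 / 3)
  dc <- p_distance(aln, deletion = "complete")
  expect_equal(dc["b", "c"], 2 / 3)
})

test_that("neighbor joining reproduces additive trees exactly", {
  # 4-leaf additive matrix from a known tree ((A:1,B:2):1,(C:3,D:1):2)
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 1 + 1 + 2 + 3
  dm["A", "D"] <- dm["D", "A"] <- 1 + 1 + 2 + 1
  dm["B", "C"] <- dm["C", "B"] <- 2 + 1 + 2 + 3
  dm["B", "D"] <- dm["D", "B"] <- 2 + 1 + 2 + 1
  dm["C", "D"] <- dm["D", "C"] <- 4
  tr <- ape::nj(dm)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), rownames(dm)] -
                         dm)), 0, tolerance = 1e-12)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want))[1], 0)

  # 5-leaf additive case
  tree5 <- ape::read.tree(text = "((A:1,B:2):1,((C:1,D:2):1,E:4):1);")
  dm5 <- ape::cophenetic.phylo(tree5)
  tr5 <- ape::nj(dm5)
  expect_equal(max(abs(ape::cophenetic.phylo(tr5)[rownames(dm5),
                                                  rownames(dm5)] - dm5)),
               0, tolerance = 1e-12)
  expect_equal(ape::dist.topo(ape::unroot(tr5),
                              ape::unroot(tree5))[1], 0)
})

test_that("pdistance trees separate well-diverged families with purity 1", {
  set.seed(17)
  fams <- list()
  labels <- character(0)
  for (f in c("famA", "famB", "famC")) {
    anc <- rnd_prot_row(60)
    ev <- evolve_family(anc, 5L, rate = 0.03,
                        leaf_names = paste0(f, "_", 1:5))
    fams <- c(fams, as.list(ev$sequences))
    labels <- c(labels, setNames(rep(f, 5), names(ev$sequences)))
  }
  aln <- unlist(fams)
  res <- pdistance_tree(aln, labels)
  expect_equal(res$purity, 1)

  # identical sequences end up as sibling leaves
  twin <- c(aln, famA_dup = aln[["famA_1"]])
  labels2 <- c(labels, famA_dup = "famA")
  res2 <- pdistance_tree(twin, labels2)
  sib <- ape::cophenetic.phylo(res2$tree)["famA_1", "famA_dup"]
  expect_equal(unname(sib), 0, tolerance = 1e-12)
})
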