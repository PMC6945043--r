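mk_gene <- function(id, scaf, strand, start, end) {
  gene_model(id, scaffold_id = scaf, strand = strand,
             exons = rbind(c(start, end)), is_pseudogene_candidate = TRUE)
}

test_that("pair linkage measures extent gaps and detects unlinked pairs", {
  a <- mk_gene("a", "s1", "+", 1000, 2000)
  b <- mk_gene("b", "s1", "+", 32000, 33000)
  p <- pair_linkage(a, b)
  expect_true(p$same_scaffold)
  expect_equal(p$gap_bp, 30000L)
  expect_identical(p$orientation, "same_strand_ab")

  q <- pair_linkage(a, mk_gene("c", "s2", "+", 0, 1000))
  expect_false(q$same_scaffold)
  expect_true(is.na(q$gap_bp))
  expect_identical(q$orientation, "n/a")

  # symmetric gap
  expect_equal(pair_linkage(b, a)$gap_bp, 30000L)
})

test_that("all four orientation classes follow the strand/order truth table", {
  # left gene [100,200), right gene [500,600)
  cases <- list(
    list(sa = "+", sb = "+", a_left = TRUE,  want = "same_strand_ab"),
    list(sa = "+", sb = "+", a_left = FALSE, want = "same_strand_ba"),
    list(sa = "-", sb = "-", a_left = TRUE,  want = "same_strand_ba"),
    list(sa = "-", sb = "-", a_left = FALSE, want = "same_strand_ab"),
    list(sa = "+", sb = "-", a_left = TRUE,  want = "convergent"),
    list(sa = "-", sb = "+", a_left = TRUE,  want = "divergent"),
    list(sa = "-", sb = "+", a_left = FALSE, want = "convergent"),
    list(sa = "+", sb = "-", a_left = FALSE, want = "divergent")
  )
  for (cs in cases) {
    a <- mk_gene("a", "s", cs$sa,
                 if (cs$a_left) 100 else 500, if (cs$a_left) 200 else 600)
    b <- mk_gene("b", "s", cs$sb,
                 if (cs$a_left) 500 else 100, if (cs$a_left) 600 else 200)
    expect_identical(classify_orientation(a, b), cs$want)
  }
  # swap rule: a<->b swaps ab/ba and fixes convergent/divergent
  a <- mk_gene("a", "s", "+", 100, 200)
  b <- mk_gene("b", "s", "+", 500, 600)
  expect_identical(classify_orientation(b, a), "same_strand_ba")
  cv <- mk_gene("c", "s", "-", 500, 600)
  expect_identical(classify_orientation(a, cv), "convergent")
  expect_identical(classify_orientation(cv, a), "convergent")

  expect_error(classify_orientation(a, mk_gene("o", "s", "+", 150, 250)),
               "overlap", class = "gatafam_validation_error")
})

test_that("generator-planted linkage layouts are recovered exactly", {
  ds <- shared_dataset()
  truth <- ds$truth$linkage
  for (i in seq_len(nrow(truth))) {
    a <- ds$models[[truth$gene_a[i]]]
    b <- ds$models[[truth$gene_b[i]]]
    p <- pair_linkage(a, b)
    expect_equal(p$same_scaffold, truth$same_scaffold[i])
    if (truth$same_scaffold[i]) {
      expect_equal(p$gap_bp, truth$gap_bp[i])
      expect_identical(p$orientation, truth$orientation[i])
    }
  }
})

test_that("single-linkage clustering chains genes by gap threshold", {
  g <- function(id, start) mk_gene(id, "s", "+", start, start + 1000)
  three <- list(g("a", 0), g("b", 5000), g("c", 10000))  # gaps 4k, 4k
  cl <- find_clusters(three, 5000)
  expect_length(cl, 1L)
  expect_length(cl[[1]]$member_gene_ids, 3L)
  expect_equal(cl[[1]]$span_bp, 11000L)

  mixed <- list(g("a", 0), g("b", 5000), g("c", 12000))  # gaps 4k, 6k
  cl2 <- find_clusters(mixed, 5000)
  expect_length(cl2, 1L)
  expect_identical(cl2[[1]]$member_gene_ids, c("a", "b"))

  # invariance under whole-scaffold translation
  shifted <- list(g("a", 70000), g("b", 75000), g("c", 80000))
  cl3 <- find_clusters(shifted, 5000)
  expect_identical(cl3[[1]]$member_gene_ids, cl[[1]]$member_gene_ids)
  expect_equal(cl3[[1]]$span_bp, cl[[1]]$span_bp)
})

test_that("the planted 9-gene 23-kbp cluster is recovered as one cluster", {
  ds <- shared_dataset()
  truth <- ds$truth$clusters
  big <- truth[truth$n_genes == 9L, ]
  expect_equal(nrow(big), 1L)
  med_models <- ds$models[ds$truth$genes$gene_id[ds$truth$genes$family ==
                                                   "med"]]
  cl <- find_clusters(med_models, 5000)
  hit <- Filter(function(x) x$scaffold_id == big$scaffold_id, cl)
  expect_length(hit, 1L)
  expect_length(hit[[1]]$member_gene_ids, 9L)
  expect_equal(hit[[1]]$span_bp, 23000L)
  expect_setequal(hit[[1]]$member_gene_ids,
                  strsplit(big$members, ",")[[1]])
})

test_that("genes near a scaffold end are flagged for broken-linkage caution", {
  ds <- shared_dataset()
  edge_gene <- ds$models[["sp06_end1.1"]]
  expect_true(near_scaffold_edge(edge_gene,
                                 ds$scaffolds[[edge_gene$scaffold_id]]))
})
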