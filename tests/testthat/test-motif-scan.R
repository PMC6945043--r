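lex <- read_motif_lexicon()

test_that("IUPAC scanning counts every offset, both strands, N never matches", {
  hits <- scan_iupac("ATCATGTCAT", lex$skn1_core, strands = "top")
  expect_identical(hits$start, c(0L, 5L))

  # overlapping occurrences are all counted: the double SKN-1 site
  # contains two core sites
  double_site <- "ATCATCAT"
  expect_equal(nrow(scan_iupac(double_site, lex$skn1_core, "top")), 2L)

  # N at a required position blocks the match
  expect_equal(nrow(scan_iupac("ATCNT", lex$skn1_core, "top")), 0L)
  expect_equal(nrow(scan_iupac("NTCAT", lex$skn1_core, "top")), 0L)

  # palindromic interval reported once, strand '+'
  pal <- motif_definition("pal", "ACGCGT")
  ph <- scan_iupac("TTACGCGTTT", pal, "both")
  expect_equal(nrow(ph), 1L)
  expect_identical(ph$strand, "+")

  # minus-strand matched text reads on the minus strand
  mh <- scan_iupac(revcomp("AGTATAC"), lex$med_site, "both")
  expect_identical(mh$strand, "-")
  expect_identical(mh$matched_text, "AGTATAC")
})

test_that("scanning agrees with a brute-force oracle and is strand-symmetric", {
  set.seed(99)
  motifs <- list(lex$skn1_core, lex$med_site, lex$tctkcac, lex$patc_like)
  for (i in 1:25) {
    seq <- rnd_dna(300, c(A = .32, C = .18, G = .18, T = .32))
    for (mot in motifs) {
      got <- scan_iupac(seq, mot, "both")
      want <- oracle_scan(seq, mot$consensus, "both")
      expect_identical(got$start, want$start)
      expect_identical(got$strand, want$strand)
      # strand symmetry of the count
      expect_equal(nrow(got), nrow(scan_iupac(revcomp(seq), mot, "both")))
    }
  }
})

test_that("Poisson enrichment matches the closed form and is monotone", {
  e0 <- poisson_enrichment(strrep("G", 100), lex$med_site)
  expect_equal(e0$observed, 0L)
  expect_equal(e0$p_value, 1)

  # uniform-composition analytic case: unambiguous 5-mer, both strands
  m5 <- motif_definition("m5", "ACGTC")
  seq <- rnd_dna(600)
  e <- poisson_enrichment(seq, m5, background = "given",
                          composition = c(A = 1, C = 1, G = 1, T = 1))
  expect_equal(e$lambda, 2 * 596 * (1 / 4)^5)

  lam <- 0.8
  ps <- ppois(0:5, lam, lower.tail = FALSE)  # upper tail at k-1
  expect_true(all(diff(ps) < 0))

  expect_error(poisson_enrichment("ACG", m5),
               class = "gatafam_validation_error")
  expect_error(poisson_enrichment(strrep("ACGTC", 10), m5, k = 99L),
               class = "gatafam_validation_error")
})

test_that("promoter extraction takes the transcribed-strand upstream window", {
  scaffold <- seq_record("s", rnd_dna(1500), "dna")
  m <- gene_model("g", scaffold_id = "s", strand = "+",
                  exons = rbind(c(1000, 1099)))
  pr <- extract_promoter(m, scaffold)
  expect_equal(pr$length, 600L)
  expect_false(pr$truncated)
  expect_identical(pr$sequence, substr(scaffold$residues, 401, 1000))

  # strand mirror: the same gene on the reverse-complemented scaffold
  L <- 1500L
  scaffold_rc <- seq_record("src", revcomp(scaffold$residues), "dna")
  m_rc <- gene_model("g", scaffold_id = "src", strand = "-",
                     exons = rbind(c(L - 1099, L - 1000)))
  expect_identical(extract_promoter(m_rc, scaffold_rc)$sequence,
                   pr$sequence)

  short <- gene_model("g2", scaffold_id = "s", strand = "+",
                      exons = rbind(c(100, 199)))
  prs <- extract_promoter(short, scaffold)
  expect_equal(prs$length, 100L)
  expect_true(prs$truncated)

  edge <- gene_model("g3", scaffold_id = "s", strand = "+",
                     exons = rbind(c(0, 99)))
  expect_error(extract_promoter(edge, scaffold),
               class = "gatafam_bounds_error")
})

test_that("PPY tract detection is symmetric and matches enumeration", {
  top <- detect_ppy_tracts("CTCTCTCTCTCT")
  expect_equal(nrow(top), 1L)
  expect_identical(top$strand, "+")
  bot <- detect_ppy_tracts(revcomp("CTCTCTCTCTCT"))
  expect_equal(nrow(bot), 1L)
  expect_identical(bot$strand, "-")

  # brute enumeration oracle on short random sequences
  oracle_tracts <- function(seq, min_len, min_fraction, bases) {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    sat <- list()
    for (s0 in 0:(n - min_len)) {
      for (e0 in (s0 + min_len):n) {
        if (mean(chars[(s0 + 1):e0] %in% bases) >= min_fraction) {
          sat[[length(sat) + 1L]] <- c(s0, e0)
        }
      }
    }
    if (length(sat) == 0L) return(matrix(integer(0), ncol = 2))
    iv <- unique(do.call(rbind, sat))
    keep <- vapply(seq_len(nrow(iv)), function(i) {
      !any(iv[, 1] <= iv[i, 1] & iv[, 2] >= iv[i, 2] &
             (iv[, 1] != iv[i, 1] | iv[, 2] != iv[i, 2]))
    }, logical(1))
    iv[keep, , drop = FALSE]
  }
  set.seed(12)
  for (i in 1:10) {
    seq <- rnd_dna(120)
    got <- detect_ppy_tracts(seq, min_len = 8L, min_fraction = 0.85)
    want_top <- oracle_tracts(seq, 8L, 0.85, c("C", "T"))
    gt <- got[got$strand == "+", , drop = FALSE]
    expect_equal(nrow(gt), nrow(want_top))
    if (nrow(gt) > 0) {
      expect_identical(gt$start, sort(want_top[, 1]))
    }
  }
})

test_that("family summaries compute coverage, means, spacing and strand bias", {
  one <- data.frame(gene_id = "g1", species = "spA", start = 550L,
                    strand = "+", upstream = 50L)
  s1 <- summarize_family(one, "med_site", "end3", d_atg = 200L)
  expect_equal(s1$n_species_with_site, 1L)
  expect_equal(s1$mean_sites_per_gene_with_site, 1)
  expect_true(is.na(s1$mean_nearest_spacing))
  expect_equal(s1$fraction_within_d_of_atg, 1)

  expect_error(summarize_family(one[0, ], "x"),
               class = "gatafam_validation_error")

  # planted PPY split from the generated site listing: 30/34 top strand
  ds <- shared_dataset()
  ppy <- ds$site_listing[ds$site_listing$motif == "ppy", ]
  ppy$motif_name <- ppy$motif
  s2 <- summarize_family(ppy, "ppy", "end1", d_atg = 300L)
  expect_equal(s2$n_sites, 34L)
  expect_equal(s2$top_strand_fraction, 30 / 34)
})

test_that("planted per-gene site counts are recovered within sampling error", {
  ds <- shared_dataset()
  sl <- ds$site_listing
  planted_mean <- function(fam, motif) {
    sub <- sl[sl$family == fam & sl$motif == motif, ]
    nrow(sub) / length(unique(sub$gene_id))
  }
  expect_lt(abs(planted_mean("end3", "med_site") - 2.6), 0.1)
  expect_lt(abs(planted_mean("end1", "med_site") - 1.2), 0.1)
  expect_lt(abs(planted_mean("med", "skn1_double") - 3.5), 0.2)
  expect_lt(abs(planted_mean("end1", "skn1_degenerate") - 1.5), 0.1)

  # scan-measured counts are never below planted counts
  for (gid in unique(sl$gene_id[sl$family == "end3"])[1:8]) {
    planted <- sum(sl$gene_id == gid & sl$motif == "med_site")
    got <- nrow(scan_iupac(ds$promoters[[gid]], lex$med_site))
    expect_gte(got, planted)
  }
})
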