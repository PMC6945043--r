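test_that("C4 finger detection reports spacings and tandem fingers", {
  bg <- strrep("A", 30)
  finger <- paste0("C", "AA", "C", strrep("L", 18), "C", "NP", "C")
  zf <- find_zinc_fingers(paste0(bg, finger, bg))
  expect_length(zf, 1L)
  expect_equal(zf[[1]]$inner_spacing, 18L)
  expect_equal(zf[[1]]$amino_gap, 2L)
  expect_identical(zf[[1]]$amino_gap_sequence, "AA")
  expect_equal(zf[[1]]$interval, c(30L, 30L + nchar(finger)))
  expect_identical(substring(paste0(bg, finger, bg),
                             zf[[1]]$cys_positions + 1L,
                             zf[[1]]$cys_positions + 1L),
                   rep("C", 4L))

  expect_length(find_zinc_fingers(strrep("A", 60)), 0L)

  two <- paste0(bg, finger, strrep("G", 8), finger, bg)
  expect_length(find_zinc_fingers(two), 2L)

  # extended END-1-type amino gap
  zf_ext <- find_zinc_fingers(paste0(bg, "C", "SNPN", "C", strrep("L", 17),
                                     "C", "NP", "C", bg))
  expect_equal(zf_ext[[1]]$amino_gap, 4L)
  expect_identical(zf_ext[[1]]$amino_gap_sequence, "SNPN")
})

test_that("finger detection is invariant to the flanking sequence", {
  finger <- paste0("C", "TT", "C", strrep("K", 17), "C", "VK", "C")
  for (bg in c(strrep("A", 25), strrep("G", 40),
               paste0(strrep("LMN", 12)))) {
    zf <- find_zinc_fingers(paste0(bg, finger, bg))
    expect_length(zf, 1L)
    expect_equal(zf[[1]]$inner_spacing, 17L)
    expect_equal(zf[[1]]$amino_gap, 2L)
  }
})

test_that("finger spacing classes follow the inner spacing and amino gap", {
  mk <- function(inner, gap_seq) {
    find_zinc_fingers(paste0(strrep("A", 25), "C", gap_seq, "C",
                             strrep("L", inner), "C", "NP", "C",
                             strrep("A", 25)))[[1]]
  }
  c18 <- classify_finger(mk(18, "AA"))
  expect_identical(c18$label, "X18")
  expect_identical(c18$amino_gap_class, "standard")
  c17 <- classify_finger(mk(17, "SNPN"))
  expect_identical(c17$label, "X17")
  expect_identical(c17$amino_gap_class, "extended")
  expect_identical(classify_finger(mk(16, "AA"))$label, "X16")
  expect_identical(classify_finger(mk(15, "AA"))$label, "other")
})

test_that("poly-serine detection finds amino-terminal serine clusters", {
  d <- detect_poly_s(paste0("MK", strrep("S", 5), strrep("A", 20)))
  expect_equal(d$interval, c(2L, 7L))
  expect_gte(d$stats$defining_fraction, 0.5)

  expect_null(detect_poly_s(strrep("A", 40)))
  # a late serine run does not qualify
  expect_null(detect_poly_s(paste0(strrep("A", 15), strrep("S", 6),
                                   strrep("A", 10))))

  # Ser/Thr mode for the MED-type region
  st <- detect_poly_s(paste0("M", "STSTSTST", strrep("A", 20)),
                      mode = "ser_thr")
  expect_equal(st$interval[1], 1L)
  expect_null(detect_poly_s(paste0("M", "TTTTTT", strrep("A", 20)),
                            mode = "serine_only"))
})

test_that("poly-serine output respects the window rule on generator proteins", {
  set.seed(31)
  spec <- family_spec(seed = 31)
  iou <- numeric(100)
  for (i in 1:100) {
    fam <- sample(c("end1", "end3"), 1)
    anc <- build_ancestor_for_tests(fam, spec)
    d <- detect_poly_s(anc$protein)
    expect_false(is.null(d))
    expect_lte(d$interval[1], 10L)
    expect_gte(d$stats$defining_fraction, 0.5)
    tr <- anc$polys
    inter <- max(0, min(d$interval[2], tr[2]) - max(d$interval[1], tr[1]))
    uni <- max(d$interval[2], tr[2]) - min(d$interval[1], tr[1])
    iou[i] <- inter / uni
  }
  expect_gte(mean(iou), 0.95)
})

test_that("EGD is the 25 residues upstream of the finger, truncating at the edge", {
  prot <- paste0(strrep("A", 100), "C", "SN", "C", strrep("L", 17),
                 "C", "NP", "C", strrep("A", 10))
  zf <- find_zinc_fingers(prot)[[1]]
  egd <- locate_egd(prot, zf)
  expect_equal(egd$interval, c(75L, 100L))
  expect_false(egd$stats$truncated)

  short <- paste0(strrep("A", 10), "C", "SN", "C", strrep("L", 17),
                  "C", "NP", "C", strrep("A", 10))
  zf2 <- find_zinc_fingers(short)[[1]]
  egd2 <- locate_egd(short, zf2)
  expect_equal(egd2$interval, c(0L, 10L))
  expect_true(egd2$stats$truncated)
})

test_that("pseudogene classification assigns each lesion its reason", {
  finger <- paste0("C", "SN", "C", strrep("L", 17), "C", "NP", "C")
  intact <- paste0("M", strrep("A", 160), finger, strrep("K", 10))
  dbd <- c(161L, nchar(intact))
  lens <- rep(nchar(intact), 5)

  call <- classify_pseudogene(NULL, intact, dbd, family_lengths = lens)
  expect_identical(call$status, "functional")

  mut <- sub("CSNC", "CSNY", intact)  # second finger cysteine lost
  call2 <- classify_pseudogene(NULL, mut, dbd, family_lengths = lens)
  expect_identical(call2$status, "pseudogene")
  expect_identical(call2$reasons, "missing_finger_cysteine")

  trunc <- substr(intact, 1, 60)
  call3 <- classify_pseudogene(NULL, trunc, c(25, 60), family_lengths = lens)
  expect_true("truncated" %in% call3$reasons)

  stopped <- paste0(substr(intact, 1, 170), "*",
                    substr(intact, 172, nchar(intact)))
  call4 <- classify_pseudogene(NULL, stopped, dbd, family_lengths = lens)
  expect_true("internal_stop_in_dbd" %in% call4$reasons)

  # near-identical same-species peer of equal length
  peer <- sub("AAAAA", "AAAAG", intact)
  call5 <- classify_pseudogene(NULL, intact, dbd,
                               family_peers = list(peer),
                               family_lengths = lens)
  expect_identical(call5$status, "unresolved_duplicate")
  expect_true("near_identical_duplicate" %in% call5$reasons)
})
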