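# Shared fixtures and independent oracles. The default synthetic dataset
# is generated once per session and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(family_spec(seed = 7))
  }
  .fixture_env$ds
}

shared_report <- function() {
  if (is.null(.fixture_env$report)) {
    .fixture_env$report <- run_characterize(shared_dataset())
  }
  .fixture_env$report
}

# Brute-force IUPAC scan oracle: checks every substring against a locally
# defined code table, independent of the package's matcher.
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_scan <- function(seq, consensus, strands = "both") {
  chars <- strsplit(seq, "")[[1]]
  match_at <- function(cons) {
    cc <- strsplit(cons, "")[[1]]
    w <- length(cc)
    hits <- integer(0)
    for (s in seq_len(length(chars) - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!chars[s + j - 1L] %in% ORACLE_IUPAC[[cc[j]]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, s - 1L)
    }
    hits
  }
  plus <- match_at(consensus)
  if (strands == "top") {
    return(data.frame(start = plus, strand = rep("+", length(plus))))
  }
  minus <- match_at(oracle_revcomp(consensus))
  minus <- setdiff(minus, plus)  # palindromic interval reported once as '+'
  out <- data.frame(start = c(plus, minus),
                    strand = c(rep("+", length(plus)),
                               rep("-", length(minus))))
  out[order(out$start, out$strand), , drop = FALSE]
}

build_ancestor_for_tests <- function(family, spec) {
  gatafam:::build_ancestor(family, spec)
}

AA_POOL_TEST <- strsplit("ADEFGHIKLMNPQRVWY", "")[[1]]

rnd_prot_row <- function(n) {
  paste(sample(AA_POOL_TEST, n, replace = TRUE), collapse = "")
}

# Random DNA under a named composition (test-local).
rnd_dna <- function(n, comp = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

# A small planted two-exon gene on a scaffold, for splice/CDS tests.
# Returns model, scaffold record, and the planted CDS.
two_exon_fixture <- function(strand = "+", intron = "GTAAGTTTTTTTCTCAG") {
  exon1 <- "ATGAAACCCGGG"          # 12 bp
  exon2 <- "TTTGACGATTGGTAA"       # 15 bp
  pad5 <- strrep("A", 30)
  pad3 <- strrep("C", 30)
  fwd <- paste0(pad5, exon1, intron, exon2, pad3)
  s1 <- nchar(pad5)
  e1 <- s1 + nchar(exon1)
  s2 <- e1 + nchar(intron)
  e2 <- s2 + nchar(exon2)
  if (strand == "+") {
    scaffold <- seq_record("scafP", fwd, "dna")
    exons <- rbind(c(s1, e1), c(s2, e2))
  } else {
    L <- nchar(fwd)
    scaffold <- seq_record("scafM", revcomp(fwd), "dna")
    exons <- rbind(c(L - e1, L - s1), c(L - e2, L - s2))
  }
  model <- gene_model("toy", species = "spX", family = "other",
                      scaffold_id = scaffold$id, strand = strand,
                      exons = exons)
  list(model = model, scaffold = scaffold, cds = paste0(exon1, exon2))
}
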