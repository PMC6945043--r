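# Serine codon tallies in protein-coordinate intervals and chi-square
# goodness-of-fit tests for the poly-serine codon bias.
#
# Serine is encoded by six codons: the TCN quartet (TCT, TCC, TCA, TCG)
# and the AGY pair (AGT, AGC). The poly-serine domains of the END proteins
# use TCN almost exclusively, with TCT/TCC over-represented within TCN.

SERINE_CODONS <- c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")
TCN_CODONS <- c("TCT", "TCC", "TCA", "TCG")

#' Tally serine codons within a protein interval
#'
#' @param cds DNA [seq_record] or string; length divisible by 3.
#' @param protein_interval 0-based half-open `[start, end)` interval in
#'   codon (protein) coordinates; `NULL` tallies the whole CDS.
#' @return A `codon_tally`: list with `counts` (named over the six serine
#'   codons), `total` and `tcn_total`.
#' @export
tally_serine_codons <- function(cds, protein_interval = NULL) {
  seq <- residues_of(cds)
  assert_that(nchar(seq) %% 3L == 0L, "CDS length not divisible by 3",
              class = "gatafam_validation_error")
  n_codon <- nchar(seq) %/% 3L
  if (is.null(protein_interval)) protein_interval <- c(0L, n_codon)
  assert_that(protein_interval[1] >= 0L && protein_interval[2] <= n_codon &&
                protein_interval[1] < protein_interval[2],
              "protein interval out of CDS range",
              class = "gatafam_validation_error")
  idx <- seq(protein_interval[1], protein_interval[2] - 1L)
  codons <- substring(seq, 3L * idx + 1L, 3L * idx + 3L)
  ser <- codons[codons %in% SERINE_CODONS]
  counts <- vapply(SERINE_CODONS, function(cd) sum(ser == cd), integer(1))
  structure(list(counts = counts, total = sum(counts),
                 tcn_total = sum(counts[TCN_CODONS])),
            class = "codon_tally")
}

#' Background serine codon usage tables
#'
#' The named table `"celegans_genscript"` carries genome-wide Caenorhabditis
#' elegans serine usage: TCN is 75% of serine codons, and within TCN the
#' TCT and TCC codons account for 28% and 18%. The within-TCN split of the
#' remaining mass between TCA and TCG is not part of the published summary
#' and is divided evenly by default (override via `fraction_tca`).
#'
#' @param name Table name, or pass explicit fractions.
#' @param fraction_tcn,fraction_tct,fraction_tcc,fraction_tca Fractions:
#'   `fraction_tcn` of all serine codons; the others within TCN.
#' @return A `background_usage` list.
#' @export
background_usage <- function(name = "celegans_genscript",
                             fraction_tcn = NULL, fraction_tct = NULL,
                             fraction_tcc = NULL, fraction_tca = NULL) {
  if (is.null(fraction_tcn)) {
    assert_that(name == "celegans_genscript", "unknown background table: ",
                name, class = "gatafam_config_error")
    fraction_tcn <- 0.75
    fraction_tct <- 0.28
    fraction_tcc <- 0.18
  }
  if (is.null(fraction_tca)) fraction_tca <- (1 - fraction_tct - fraction_tcc) / 2
  assert_that(all(c(fraction_tcn, fraction_tct, fraction_tcc,
                    fraction_tca) >= 0) &&
                fraction_tcn <= 1 && fraction_tct + fraction_tcc +
                fraction_tca <= 1,
              "inconsistent background fractions",
              class = "gatafam_config_error")
  structure(list(fraction_tcn = fraction_tcn, fraction_tct = fraction_tct,
                 fraction_tcc = fraction_tcc, fraction_tca = fraction_tca,
                 source = name),
            class = "background_usage")
}

#' Chi-square test for serine codon-usage bias
#'
#' Two modes. `tcn_vs_agy` tests the split of serine codons between the
#' TCN quartet and the AGY pair against the background TCN fraction
#' (1 df). `within_tcn` tests the four TCN counts against the background
#' TCN-internal proportions (3 df). Both are Pearson goodness-of-fit tests
#' with the p-value from the chi-square upper tail; when any expected cell
#' is below 1 the result carries a warning flag (the test is still
#' computed).
#'
#' @param tally A `codon_tally` from [tally_serine_codons()].
#' @param background A `background_usage`.
#' @param mode `"tcn_vs_agy"` (default) or `"within_tcn"`.
#' @return A `codon_bias_result`: list with `mode`, `statistic`, `df`,
#'   `p_value`, `expected`, `observed`, `low_expected_warning`.
#' @export
chisq_codon_bias <- function(tally, background = background_usage(),
                             mode = c("tcn_vs_agy", "within_tcn")) {
  mode <- match.arg(mode)
  assert_that(tally$total >= 1L, "empty codon tally",
              class = "gatafam_validation_error")
  if (mode == "tcn_vs_agy") {
    observed <- c(tcn = tally$tcn_total,
                  agy = tally$total - tally$tcn_total)
    probs <- c(background$fraction_tcn, 1 - background$fraction_tcn)
    expected <- tally$total * probs
    df <- 1L
  } else {
    observed <- tally$counts[TCN_CODONS]
    assert_that(tally$tcn_total >= 1L, "no TCN codons in tally",
                class = "gatafam_validation_error")
    ptcg <- 1 - background$fraction_tct - background$fraction_tcc -
      background$fraction_tca
    probs <- c(background$fraction_tct, background$fraction_tcc,
               background$fraction_tca, ptcg)
    expected <- tally$tcn_total * probs
    df <- 3L
  }
  statistic <- sum((observed - expected)^2 / expected)
  structure(list(mode = mode, statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 observed = observed, expected = expected,
                 low_expected_warning = any(expected < 1)),
            class = "codon_bias_result")
}

#' @export
print.codon_bias_result <- function(x, ...) {
  cat(sprintf("<codon_bias_result %s> X-squared = %.4g, df = %d, p = %.4g%s\n",
              x$mode, x$statistic, x$df, x$p_value,
              if (x$low_expected_warning) " [expected cell < 1]" else ""))
  invisible(x)
}
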