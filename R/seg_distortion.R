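# Single-locus segregation distortion: Williams-corrected G goodness-of-fit
# against Mendelian 1:2:1 F2 expectations, the segregation distortion value
# (SDV = -log10 p), and a sequential allele-balance / genotype-distribution
# test diagnosing gametic vs zygotic selection.

#' @noRd
check_counts <- function(counts) {
  assert_that(is.numeric(counts) && length(counts) == 3L,
              "`counts` must be the three genotype counts (RR, RI, II)")
  assert_that(all(!is.na(counts)) && all(counts >= 0), "negative or NA counts")
  n <- sum(counts)
  assert_that(n >= 1, "total count must be at least 1")
  n
}

#' Williams-corrected G goodness-of-fit test for genotype counts
#'
#' Tests observed genotype counts (RR, RI, II) against expected proportions,
#' by default the Mendelian F2 ratio 1:2:1. The raw statistic
#' `G = 2 * sum(O * ln(O/E))` (zero counts contribute nothing, the
#' `x*log(x) -> 0` limit) is divided by the Williams small-sample correction
#' `q = 1 + (k^2 - 1) / (6 * N * (k - 1))` for `k = 3` categories, and
#' referred to a chi-squared distribution with 2 degrees of freedom. The
#' segregation distortion value SDV is `-log10(p)`, computed on the log
#' scale so that it stays finite for extreme distortion.
#'
#' @param counts numeric of length 3: counts of RR, RI, II.
#' @param expected probabilities for the three classes, summing to 1.
#' @return List with `G`, `q_williams`, `df`, `p`, `SDV` and the inputs.
#' @examples
#' williams_g_test(c(92, 56, 0))  # strong distortion, G = 135.77
#' @export
williams_g_test <- function(counts, expected = c(0.25, 0.5, 0.25)) {
  n <- check_counts(counts)
  assert_that(length(expected) == length(counts) &&
                abs(sum(expected) - 1) < 1e-8,
              "`expected` must be probabilities summing to 1")
  e <- expected * n
  pos <- counts > 0
  g_raw <- 2 * sum(counts[pos] * log(counts[pos] / e[pos]))
  k <- length(counts)
  q <- 1 + (k^2 - 1) / (6 * n * (k - 1))
  g <- g_raw / q
  df <- k - 1
  log_p <- stats::pchisq(g, df = df, lower.tail = FALSE, log.p = TRUE)
  list(G = g, G_raw = g_raw, q_williams = q, df = df,
       p = exp(log_p), SDV = -log_p / log(10),
       counts = counts, expected = expected, N = n)
}

#' Allele-balance chi-squared (first stage of the sequential test)
#'
#' Tests whether the two orientations are transmitted at equal frequency:
#' with `nR = 2*RR + RI` reference and `nI = RI + 2*II` inverted alleles out
#' of `2N`, the statistic is `(nR - N)^2/N + (nI - N)^2/N = 2*(nR - N)^2/N`,
#' referred to chi-squared with 1 df. Zero when `RR = II`.
#'
#' @inheritParams williams_g_test
#' @return List with `chi1`, `df`, `p`, `nR`, `nI`.
#' @export
allele_balance_chi2 <- function(counts) {
  n <- check_counts(counts)
  nR <- 2 * counts[1] + counts[2]
  nI <- counts[2] + 2 * counts[3]
  stat <- (nR - n)^2 / n + (nI - n)^2 / n
  list(chi1 = stat, df = 1L,
       p = stats::pchisq(stat, 1, lower.tail = FALSE),
       nR = nR, nI = nI)
}

#' Sequential selection-mode test (gametic vs zygotic distortion)
#'
#' Second stage of the sequential diagnosis. The literature does not pin a
#' single formula for the genotype-distribution statistic, so it is a
#' strategy point with two documented variants: `"one_two_one"` compares
#' genotype counts to the Mendelian expectation (N/4, N/2, N/4) with 2 df;
#' `"hwe_conditional"` compares them to Hardy-Weinberg proportions at the
#' observed allele frequency (conditioning out the stage-1 signal), 1 df.
#' Classification: `gametic` when the allele balance is disturbed but the
#' genotype distribution (given variant) is not; `zygotic` when the genotype
#' distribution is disturbed; `none` otherwise.
#'
#' @inheritParams williams_g_test
#' @param variant `"one_two_one"` or `"hwe_conditional"`.
#' @param level significance level used for the classification.
#' @return List with `chi1`, `p1`, `chi2`, `p2`, `df2`, `mode`, `variant`.
#' @export
selection_mode_test <- function(counts,
                                variant = c("one_two_one", "hwe_conditional"),
                                level = 0.05) {
  variant <- match.arg(variant)
  n <- check_counts(counts)
  ab <- allele_balance_chi2(counts)
  if (variant == "one_two_one") {
    e <- c(n / 4, n / 2, n / 4)
    chi2 <- sum((counts - e)^2 / e)
    df2 <- 2L
  } else {
    p_hat <- ab$nR / (2 * n)
    if (p_hat <= 0 || p_hat >= 1) {
      chi2 <- NA_real_
      df2 <- NA_integer_
    } else {
      q_hat <- 1 - p_hat
      e <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
      chi2 <- sum((counts - e)^2 / e)
      df2 <- 1L
    }
  }
  p2 <- if (is.na(chi2)) NA_real_ else
    stats::pchisq(chi2, df2, lower.tail = FALSE)
  mode <- if (!is.na(p2) && p2 < level) "zygotic"
  else if (ab$p < level && (is.na(p2) || p2 >= level)) "gametic"
  else "none"
  if (is.na(chi2) && ab$p >= level) mode <- "none"
  list(chi1 = ab$chi1, p1 = ab$p, chi2 = chi2, p2 = p2, df2 = df2,
       mode = mode, variant = variant,
       degenerate = is.na(chi2))
}

#' Per-locus segregation distortion table for a cross
#'
#' Runs the Williams-corrected G test and the sequential selection-mode test
#' on every segregating locus of a cross and adjusts the G-test p-values
#' with Benjamini-Hochberg within the cross. Missing calls are dropped per
#' locus.
#'
#' @param m a [genotype_matrix()].
#' @param expected Mendelian class probabilities (default 1:2:1).
#' @param variant selection-mode variant, see [selection_mode_test()].
#' @param level significance level for the mode classification.
#' @return data.frame sorted by p with columns `locus`, `cross`, `n_RR`,
#'   `n_RI`, `n_II`, `N`, `G`, `p`, `SDV`, `chi1`, `p1`, `chi2`, `p2`,
#'   `mode`, `p_adj`.
#' @export
sd_table <- function(m, expected = c(0.25, 0.5, 0.25),
                     variant = c("one_two_one", "hwe_conditional"),
                     level = 0.05) {
  variant <- match.arg(variant)
  locs <- segregating_loci(m)
  assert_that(length(locs) > 0, "no segregating loci in matrix")
  rows <- lapply(locs, function(l) {
    g <- m$genotypes[, l]
    counts <- vapply(GENOTYPE_CODES, function(code) sum(g == code, na.rm = TRUE),
                     numeric(1))
    gt <- williams_g_test(counts, expected)
    sm <- selection_mode_test(counts, variant = variant, level = level)
    data.frame(locus = l, cross = m$cross_id,
               n_RR = counts[1], n_RI = counts[2], n_II = counts[3],
               N = gt$N, G = gt$G, p = gt$p, SDV = gt$SDV,
               chi1 = sm$chi1, p1 = sm$p1, chi2 = sm$chi2, p2 = sm$p2,
               mode = sm$mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
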