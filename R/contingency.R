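# 3x3 contingency analysis for inversion pairs: omnibus chi-squared with a
# Monte-Carlo p-value, per-cell standardized-residual post hocs with
# Benjamini-Yekutieli correction, relative contributions, and a G test of
# independence shared with the replicated-G machinery.

#' Build the 3x3 genotype contingency table for a locus pair
#'
#' Rows are the genotypes of `locusA` and columns those of `locusB`, in the
#' fixed order RR, RI, II. Individuals missing at either locus are dropped
#' for this pair only (pairwise-complete deletion); the number dropped is
#' attached as attribute `n_dropped`.
#'
#' @param m a [genotype_matrix()].
#' @param locusA,locusB locus ids.
#' @return 3x3 integer matrix with dimnames, attribute `n_dropped`.
#' @export
pair_table3x3 <- function(m, locusA, locusB) {
  assert_that(all(c(locusA, locusB) %in% loci(m)), "locus not in matrix")
  a <- m$genotypes[, locusA]
  b <- m$genotypes[, locusB]
  keep <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[keep], levels = GENOTYPE_CODES),
               factor(b[keep], levels = GENOTYPE_CODES))
  out <- matrix(as.integer(tab), 3, 3,
                dimnames = list(GENOTYPE_CODES, GENOTYPE_CODES))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Expected counts for a 3x3 table
#'
#' `margins` mode takes the usual independence expectation from the observed
#' margins; `mendelian` mode takes the product of Mendelian F2 genotype
#' frequencies (1/4, 1/2, 1/4) at both loci.
#' @noRd
expected_counts <- function(observed, expectation = c("margins", "mendelian")) {
  expectation <- match.arg(expectation)
  n <- sum(observed)
  if (expectation == "margins") {
    outer(rowSums(observed), colSums(observed)) / n
  } else {
    f <- c(0.25, 0.5, 0.25)
    outer(f, f, `*`) * n
  }
}

#' @noRd
chi2_stat <- function(observed, expected) {
  ok <- expected > 0
  sum((observed[ok] - expected[ok])^2 / expected[ok])
}

#' Omnibus chi-squared test with Monte-Carlo p-value
#'
#' Computes `X^2 = sum((O - E)^2 / E)` over cells with positive expectation
#' and calibrates it by simulation rather than the asymptotic chi-squared
#' distribution (expected counts are often small in F2 inversion pairs).
#' Under `margins` expectations the null replicates are uniform random
#' tables with both margins fixed (Patefield's algorithm, [r2dtable()]);
#' under `mendelian` expectations they are multinomial draws from the
#' product of Mendelian frequencies. The Monte-Carlo p-value is
#' `(1 + #(X2* >= X2)) / (B + 1)`.
#'
#' @param observed 3x3 (or general) matrix of counts.
#' @param B number of null replicates (default 10000).
#' @param seed optional integer seed for reproducible replicates.
#' @param expectation `"margins"` or `"mendelian"`.
#' @return List with `statistic`, `p_mc`, `expected`, `B`, `expectation`,
#'   and `degenerate` (TRUE when a whole row/column is empty under margins
#'   mode and the statistic was computed over the non-degenerate cells).
#' @export
omnibus_chi2_mc <- function(observed, B = 10000, seed = NULL,
                            expectation = c("margins", "mendelian")) {
  expectation <- match.arg(expectation)
  assert_that(is.matrix(observed) && all(observed >= 0), "invalid count table")
  n <- sum(observed)
  assert_that(n >= 1, "empty table")
  assert_that(B >= 1, "B must be >= 1")
  e <- expected_counts(observed, expectation)
  degenerate <- expectation == "margins" &&
    (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
  stat <- chi2_stat(observed, e)

  null_stats <- with_seed(seed, {
    if (expectation == "margins") {
      reps <- stats::r2dtable(B, rowSums(observed), colSums(observed))
      vapply(reps, chi2_stat, numeric(1), expected = e)
    } else {
      f <- as.vector(e / n)
      draws <- stats::rmultinom(B, n, f)
      colSums((draws - as.vector(e))^2 / as.vector(e))
    }
  })
  p <- (1 + sum(null_stats >= stat - 1e-12)) / (B + 1)
  list(statistic = stat, p_mc = p, expected = e, B = B,
       expectation = expectation, degenerate = degenerate, N = n)
}

#' Standardized-residual post hoc analysis of a contingency table
#'
#' For each cell, the standardized residual
#' `SR = (O - E) / sqrt(E * (1 - r_i/N) * (1 - c_j/N))` is referred to the
#' standard normal two-sided; the nine p-values are corrected with
#' Benjamini-Yekutieli (the cells of one table are not independent). The
#' relative contribution `RC = 100 * ((O - E)^2 / E) / X^2` says what share
#' of the omnibus statistic a cell carries.
#'
#' @param observed matrix of counts.
#' @param expectation `"margins"` or `"mendelian"` (see [omnibus_chi2_mc()]).
#' @return data.frame with one row per cell: `row`, `col`, `cell` (row-major
#'   index), `observed`, `expected`, `SR`, `RC`, `p_raw`, `p_BY`. Cells with
#'   zero expectation get `NA` residuals.
#' @export
posthoc_residuals <- function(observed, expectation = c("margins", "mendelian")) {
  expectation <- match.arg(expectation)
  n <- sum(observed)
  assert_that(n >= 1, "empty table")
  e <- expected_counts(observed, expectation)
  stat <- chi2_stat(observed, e)
  ri <- rowSums(observed) / n
  cj <- colSums(observed) / n
  denom <- sqrt(e * outer(1 - ri, 1 - cj))
  sr <- ifelse(e > 0 & denom > 0, (observed - e) / denom, NA_real_)
  rc <- ifelse(e > 0, 100 * ((observed - e)^2 / e) / stat, NA_real_)
  if (stat == 0) rc <- ifelse(e > 0, 0, NA_real_)
  # row-major cell index: cell 9 = (II, II), cell 8 = (II, RI)
  grid <- expand.grid(col = seq_len(ncol(observed)),
                      row = seq_len(nrow(observed)))[, c("row", "col")]
  out <- data.frame(
    row = rownames(observed)[grid$row] %||% as.character(grid$row),
    col = colnames(observed)[grid$col] %||% as.character(grid$col),
    cell = seq_len(nrow(grid)),
    observed = observed[cbind(grid$row, grid$col)],
    expected = e[cbind(grid$row, grid$col)],
    SR = sr[cbind(grid$row, grid$col)],
    RC = rc[cbind(grid$row, grid$col)],
    stringsAsFactors = FALSE
  )
  out$p_raw <- 2 * stats::pnorm(-abs(out$SR))
  out$p_BY <- stats::p.adjust(out$p_raw, method = "BY")
  out
}

#' G test of independence for a contingency table
#'
#' `G = 2 * sum(O * ln(O / E))` with expectations from the margins; zero
#' cells contribute nothing. Rows/columns with zero margin are dropped
#' before computing degrees of freedom; a table left with fewer than two
#' rows or columns is degenerate (`G = 0`, `df = 0`, `p = NA`).
#'
#' @param observed matrix of counts (typically 2x2).
#' @return List with `G`, `df`, `p`, `degenerate`.
#' @export
g_independence <- function(observed) {
  assert_that(is.matrix(observed) && all(observed >= 0), "invalid count table")
  n <- sum(observed)
  assert_that(n >= 1, "empty table")
  keep_r <- rowSums(observed) > 0
  keep_c <- colSums(observed) > 0
  o <- observed[keep_r, keep_c, drop = FALSE]
  if (nrow(o) < 2 || ncol(o) < 2) {
    return(list(G = 0, df = 0L, p = NA_real_, degenerate = TRUE))
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  pos <- o > 0
  g <- 2 * sum(o[pos] * log(o[pos] / e[pos]))
  df <- (nrow(o) - 1L) * (ncol(o) - 1L)
  list(G = g, df = df, p = stats::pchisq(g, df, lower.tail = FALSE),
       degenerate = FALSE)
}
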