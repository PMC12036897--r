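# Zero-centered co-occurrence indexes on binary dosage-state vectors:
# the centered Jaccard/Tanimoto index with a bootstrap test, and the
# affinity score (log-odds maximizer of the noncentral hypergeometric
# likelihood) with an exact test. A driver decomposes a locus pair's 3x3
# table into its four 2x2 state contrasts.

#' 2x2 co-occurrence table from two binary vectors
#'
#' Pairwise-complete: positions missing in either vector are dropped.
#'
#' @param x,y binary (0/1) vectors of equal length, `NA` allowed.
#' @return Named numeric vector `c(n11, n10, n01, n00)` with attributes
#'   `n`, `mA`, `mB`.
#' @export
table2x2 <- function(x, y) {
  assert_that(length(x) == length(y), "vectors must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 1, "no pairwise-complete observations")
  out <- c(n11 = sum(x == 1 & y == 1), n10 = sum(x == 1 & y == 0),
           n01 = sum(x == 0 & y == 1), n00 = sum(x == 0 & y == 0))
  attr(out, "n") <- length(x)
  attr(out, "mA") <- out[["n11"]] + out[["n10"]]
  attr(out, "mB") <- out[["n11"]] + out[["n01"]]
  out
}

#' @noRd
as_counts2x2 <- function(t) {
  if (is.matrix(t)) {
    assert_that(all(dim(t) == c(2, 2)), "expected a 2x2 table")
    t <- c(n11 = t[1, 1], n10 = t[1, 2], n01 = t[2, 1], n00 = t[2, 2])
  }
  assert_that(length(t) == 4 && all(t >= 0), "invalid 2x2 counts")
  unname(t[c("n11", "n10", "n01", "n00")] %||% t)
}

#' Centered Jaccard/Tanimoto index from 2x2 counts (vectorized)
#'
#' `J = n11 / (n11 + n10 + n01)` minus its expectation under independence,
#' `E[J] = p*q / (p + q - p*q)` with `p = mA/n`, `q = mB/n`. Equals 0 by
#' convention when no individual carries either state.
#' @noRd
cjt_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p <- (n11 + n10) / n
  q <- (n11 + n01) / n
  union <- n11 + n10 + n01
  j <- ifelse(union > 0, n11 / union, 0)
  ej <- ifelse(p + q - p * q > 0, p * q / (p + q - p * q), 0)
  j - ej
}

#' Centered Jaccard/Tanimoto co-occurrence index
#'
#' Observed Jaccard similarity of two presence/absence vectors minus its
#' expectation under independent assortment at the observed prevalences.
#' Positive values indicate coupling (states co-occur more often than
#' expected), negative values repulsion.
#'
#' @param x,y binary vectors of equal length (`NA` dropped pairwise), each
#'   containing at least one 1.
#' @return The centered index, a number in (-1, 1).
#' @export
centered_jaccard <- function(x, y) {
  t <- table2x2(x, y)
  assert_that(t[["n11"]] + t[["n10"]] > 0 && t[["n11"]] + t[["n01"]] > 0,
              "all-zero vector: contrast invalid")
  cjt_from_counts(t[["n11"]], t[["n10"]], t[["n01"]], t[["n00"]])
}

#' Bootstrap test for the centered Jaccard/Tanimoto index
#'
#' The null model permutes one vector uniformly against the other, which
#' fixes both margins; consequently the permuted co-occurrence count `n11*`
#' is exactly hypergeometric, and the default `"hypergeometric"` method
#' samples it directly (`B` draws), which is distributionally identical to
#' explicit permutation (`method = "permutation"`) but much faster. The
#' two-sided p-value is `(1 + #(|cJT*| >= |cJT|)) / (B + 1)`; ties count as
#' exceedances (conservative).
#'
#' @param x,y binary vectors as in [centered_jaccard()].
#' @param B number of bootstrap replicates (default 10000).
#' @param seed optional integer seed.
#' @param method `"hypergeometric"` (sufficient-statistic sampling) or
#'   `"permutation"` (explicit shuffles).
#' @return List with `cJT`, `p`, `B`, `method`.
#' @export
jaccard_bootstrap_test <- function(x, y, B = 10000, seed = NULL,
                                   method = c("hypergeometric", "permutation")) {
  method <- match.arg(method)
  t <- table2x2(x, y)
  n <- attr(t, "n"); mA <- attr(t, "mA"); mB <- attr(t, "mB")
  assert_that(mA > 0 && mB > 0, "all-zero vector: contrast invalid")
  obs <- cjt_from_counts(t[["n11"]], t[["n10"]], t[["n01"]], t[["n00"]])
  null_cjt <- with_seed(seed, {
    if (method == "hypergeometric") {
      n11s <- stats::rhyper(B, mA, n - mA, mB)
      cjt_from_counts(n11s, mA - n11s, mB - n11s, n - mA - mB + n11s)
    } else {
      keep <- !is.na(x) & !is.na(y)
      xx <- x[keep]; yy <- y[keep]
      vapply(seq_len(B), function(b) {
        ys <- sample(yy)
        n11 <- sum(xx == 1 & ys == 1)
        cjt_from_counts(n11, mA - n11, mB - n11, n - mA - mB + n11)
      }, numeric(1))
    }
  })
  p <- (1 + sum(abs(null_cjt) >= abs(obs) - 1e-12)) / (B + 1)
  list(cJT = obs, p = p, B = B, method = method)
}

#' @noRd
nchg_log_weights <- function(support, mA, mB, n, a) {
  lchoose(mA, support) + lchoose(n - mA, mB - support) + a * support
}

#' @noRd
nchg_mean <- function(mA, mB, n, a) {
  support <- max(0, mA + mB - n):min(mA, mB)
  lw <- nchg_log_weights(support, mA, mB, n, a)
  w <- exp(lw - max(lw))
  sum(support * w) / sum(w)
}

#' Affinity score for a 2x2 co-occurrence table
#'
#' The affinity score `alpha` is the log odds ratio of the 2x2 table
#' estimated under the Fisher noncentral hypergeometric model with both
#' margins fixed: the maximizer over `a` of `P(n11 | n, mA, mB, odds = e^a)`.
#' This conditional MLE is prevalence-insensitive. Tables whose `n11` sits
#' on the boundary of its attainable range have an infinite MLE and are
#' reported as `+cap`/`-cap` (default 10, matching the convention of
#' printing +/-10.00 for boundary tables). The p-value is the two-sided
#' exact central hypergeometric test of `n11` using the minimum-likelihood
#' tail rule (optionally the mid-p variant).
#'
#' @param t 2x2 counts: either a 2x2 matrix or a named vector
#'   `c(n11, n10, n01, n00)` (e.g. from [table2x2()]).
#' @param cap absolute bound for `alpha` (default 10).
#' @param midp use the mid-p correction for the exact test (default FALSE).
#' @return List with `alpha`, `p`, `capped`, `n11`, `bounds` (attainable
#'   range of `n11`).
#' @export
affinity_alpha <- function(t, cap = 10, midp = FALSE) {
  counts <- as_counts2x2(t)
  n11 <- counts[1]; n10 <- counts[2]; n01 <- counts[3]; n00 <- counts[4]
  n <- sum(counts)
  mA <- n11 + n10
  mB <- n11 + n01
  assert_that(mA > 0 && mA < n && mB > 0 && mB < n,
              "degenerate margin: contrast invalid")
  assert_that(cap > 0, "`cap` must be positive")
  lo <- max(0, mA + mB - n)
  hi <- min(mA, mB)

  if (n11 >= hi) {
    alpha <- cap; capped <- TRUE
  } else if (n11 <= lo) {
    alpha <- -cap; capped <- TRUE
  } else {
    f <- function(a) nchg_mean(mA, mB, n, a) - n11
    if (f(cap) < 0) {
      alpha <- cap; capped <- TRUE
    } else if (f(-cap) > 0) {
      alpha <- -cap; capped <- TRUE
    } else {
      alpha <- stats::uniroot(f, c(-cap, cap), tol = 1e-9)$root
      capped <- FALSE
    }
  }

  support <- lo:hi
  d <- stats::dhyper(support, mA, n - mA, mB)
  d_obs <- stats::dhyper(n11, mA, n - mA, mB)
  in_tail <- d <= d_obs * (1 + 1e-7)
  p <- sum(d[in_tail])
  if (midp) p <- p - 0.5 * d_obs
  p <- min(1, max(p, 0))
  list(alpha = alpha, p = p, capped = capped, n11 = n11,
       bounds = c(lo, hi), n = n, mA = mA, mB = mB)
}

#' Extract a 2x2 state contrast from a 3x3 genotype table
#'
#' The 2x2 submatrix for a dosage-state pair is the conditional subtable
#' over genotype pairs `{RR, stateA} x {RR, stateB}`: presence is the
#' state's genotype, absence is the reference homozygote `RR`, and
#' individuals carrying the locus's *other* non-reference genotype are
#' excluded from the contrast (not folded into absence). This conditioning
#' is what makes the four submatrices separate channels: a viability
#' perturbation of one genotype-pair cell disturbs only the submatrices
#' whose subtable contains that cell, leaving the others exactly
#' independent.
#'
#' @param t3 3x3 table with RR/RI/II rows and columns.
#' @param stateA,stateB `"HET"` or `"HOM_INV"` for the row and column locus.
#' @return Named counts as in [table2x2()]: `n11` = (stateA, stateB),
#'   `n10` = (stateA, RR), `n01` = (RR, stateB), `n00` = (RR, RR).
#' @export
table2x2_from_table3x3 <- function(t3, stateA, stateB) {
  i <- match(state_code(stateA), rownames(t3))
  j <- match(state_code(stateB), colnames(t3))
  r <- match("RR", rownames(t3))
  c0 <- match("RR", colnames(t3))
  out <- c(n11 = t3[i, j], n10 = t3[i, c0], n01 = t3[r, j], n00 = t3[r, c0])
  attr(out, "n") <- sum(out)
  attr(out, "mA") <- out[["n11"]] + out[["n10"]]
  attr(out, "mB") <- out[["n11"]] + out[["n01"]]
  out
}

#' Restricted 2x2 table for a dosage-state pair of two loci
#'
#' Builds the conditional subtable of [table2x2_from_table3x3()] straight
#' from a genotype matrix: individuals missing at either locus, or carrying
#' the other non-reference genotype at either locus, are dropped for this
#' contrast.
#'
#' @param m a [genotype_matrix()].
#' @param locusA,locusB locus ids.
#' @param stateA,stateB `"HET"` or `"HOM_INV"`.
#' @return Named counts `c(n11, n10, n01, n00)` with margin attributes.
#' @export
state_pair_table2x2 <- function(m, locusA, stateA, locusB, stateB) {
  table2x2_from_table3x3(pair_table3x3(m, locusA, locusB), stateA, stateB)
}

# Fixed submatrix indexing of the four state contrasts of a locus pair.
SUBMATRIX_STATES <- list(
  `1` = c("HET", "HET"),
  `2` = c("HOM_INV", "HOM_INV"),
  `3` = c("HET", "HOM_INV"),
  `4` = c("HOM_INV", "HET")
)

#' Four-way co-occurrence contrasts for a locus pair
#'
#' Builds the pairwise-complete 3x3 genotype table once, runs the omnibus
#' Monte-Carlo chi-squared test and the standardized-residual post hoc,
#' then decomposes the pair into its four dosage-state contrasts
#' (submatrix 1 = HET/HET, 2 = HOM/HOM, 3 = HET/HOM, 4 = HOM/HET). Each
#' contrast gets the centered Jaccard/Tanimoto index with its bootstrap
#' p-value, the affinity score with its exact p-value, and the matching
#' post hoc cell's standardized residual and BY-corrected p-value. State
#' pairs whose binary vector is constant are skipped with a reason. A
#' contrast is flagged `detected_by_all` when the cJ/T, affinity, and post
#' hoc raw p-values are all below `level`.
#'
#' @param m a [genotype_matrix()].
#' @param locusA,locusB segregating loci (on different chromosomes if
#'   `meta` is supplied, which is then enforced).
#' @param B bootstrap/Monte-Carlo replicates (default 10000).
#' @param seed optional integer seed (submatrix streams are derived from it).
#' @param level significance level for the detection flag (default 0.05).
#' @param cap affinity cap (default 10).
#' @param expectation omnibus expectation mode, see [omnibus_chi2_mc()].
#' @param meta optional locus metadata to enforce the different-chromosome
#'   requirement.
#' @return data.frame with one row per submatrix (columns `cross`,
#'   `locusA`, `stateA`, `labelA`, `locusB`, `stateB`, `labelB`,
#'   `submatrix`, the 2x2 counts, `cJT`, `cJT_p`, `alpha`, `alpha_p`, `SR`,
#'   `posthoc_p`, `RC`, `omnibus_chi2`, `omnibus_p`, `detected_by_all`,
#'   `skipped`, `skip_reason`), with the omnibus result attached as
#'   attribute `omnibus`.
#' @export
pairwise_contrasts <- function(m, locusA, locusB, B = 10000, seed = NULL,
                               level = 0.05, cap = 10,
                               expectation = c("margins", "mendelian"),
                               meta = NULL) {
  expectation <- match.arg(expectation)
  seg <- segregating_loci(m)
  assert_that(locusA %in% seg && locusB %in% seg,
              "both loci must segregate in the cross")
  assert_that(locusA != locusB, "a locus cannot be paired with itself")
  if (!is.null(meta)) {
    chrom <- stats::setNames(meta$chromosome, meta$locus_id)
    assert_that(chrom[[locusA]] != chrom[[locusB]],
                "loci on the same chromosome: pair invalid")
  }
  t3 <- pair_table3x3(m, locusA, locusB)
  omni <- omnibus_chi2_mc(t3, B = B, seed = child_seed(seed, 0),
                          expectation = expectation)
  ph <- posthoc_residuals(t3, expectation = expectation)

  rows <- lapply(seq_along(SUBMATRIX_STATES), function(k) {
    st <- SUBMATRIX_STATES[[k]]
    t2 <- table2x2_from_table3x3(t3, st[1], st[2])
    cell <- ph[ph$row == state_code(st[1]) & ph$col == state_code(st[2]), ]
    base <- data.frame(
      cross = m$cross_id,
      locusA = locusA, stateA = st[1], labelA = state_label(locusA, st[1]),
      locusB = locusB, stateB = st[2], labelB = state_label(locusB, st[2]),
      submatrix = k,
      n11 = t2[["n11"]], n10 = t2[["n10"]], n01 = t2[["n01"]], n00 = t2[["n00"]],
      cJT = NA_real_, cJT_p = NA_real_, alpha = NA_real_, alpha_p = NA_real_,
      SR = cell$SR, posthoc_p = cell$p_BY, posthoc_p_raw = cell$p_raw,
      RC = cell$RC,
      omnibus_chi2 = omni$statistic, omnibus_p = omni$p_mc,
      detected_by_all = FALSE, skipped = FALSE, skip_reason = "",
      stringsAsFactors = FALSE
    )
    mA <- attr(t2, "mA"); mB <- attr(t2, "mB"); n <- attr(t2, "n")
    if (mA == 0 || mA == n || mB == 0 || mB == n) {
      base$skipped <- TRUE
      base$skip_reason <- "constant state vector"
      return(base)
    }
    base$cJT <- cjt_from_counts(t2[["n11"]], t2[["n10"]], t2[["n01"]], t2[["n00"]])
    boot_seed <- child_seed(seed, k)
    null_cjt <- with_seed(boot_seed, {
      n11s <- stats::rhyper(B, mA, n - mA, mB)
      cjt_from_counts(n11s, mA - n11s, mB - n11s, n - mA - mB + n11s)
    })
    base$cJT_p <- (1 + sum(abs(null_cjt) >= abs(base$cJT) - 1e-12)) / (B + 1)
    aff <- affinity_alpha(t2, cap = cap)
    base$alpha <- aff$alpha
    base$alpha_p <- aff$p
    base$detected_by_all <-
      !is.na(base$cJT_p) && base$cJT_p < level &&
      base$alpha_p < level &&
      !is.na(base$posthoc_p_raw) && base$posthoc_p_raw < level
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "omnibus") <- omni
  attr(out, "table3x3") <- t3
  out
}
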