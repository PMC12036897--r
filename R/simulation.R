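# Survival-rate contingency-table simulator and the type-I error / power
# characterization of the three testing frameworks (omnibus 3x3 test,
# centered Jaccard/Tanimoto, affinity), plus plain two-locus LD metrics
# for comparison.

#' Mendelian F2 expectations for a two-locus 3x3 genotype table
#'
#' Product of independent 1:2:1 genotype frequencies at each locus. Cells
#' are indexed row-major with rows = locus A (RR, RI, II): cell 9 is the
#' double inverted homozygote (II, II), cell 8 is (II, RI).
#'
#' @return 3x3 matrix of probabilities summing to 1.
#' @export
mendelian_f2_probs <- function() {
  f <- c(RR = 0.25, RI = 0.5, II = 0.25)
  outer(f, f, `*`)
}

#' Survival-modified expected frequencies
#'
#' Multiplies each cell's expected frequency by a genotype-specific survival
#' rate and renormalizes over the nine cells:
#' `f_mod_i = f_e_i * s_i / sum_j(f_e_j * s_j)`. A survival rate of 1 means
#' no deviation; below 1, reduced survival (deflation). The result is
#' invariant to rescaling all survival rates by a constant.
#'
#' @param f_e expected frequencies (3x3 matrix or length-9 row-major
#'   vector) summing to 1.
#' @param s survival rates, same shape/order, non-negative, not all zero.
#' @return 3x3 matrix of modified frequencies summing to 1.
#' @export
modified_expectation <- function(f_e, s) {
  f_e <- as_cell_matrix(f_e)
  s <- as_cell_matrix(s)
  assert_that(abs(sum(f_e) - 1) < 1e-8, "`f_e` must sum to 1")
  assert_that(all(s >= 0), "survival rates must be non-negative")
  w <- f_e * s
  total <- sum(w)
  assert_that(total > 0, "all-zero joint survival")
  w / total
}

#' Coerce a length-9 row-major vector (or 3x3 matrix) to a 3x3 matrix
#' @noRd
as_cell_matrix <- function(x) {
  if (is.matrix(x)) {
    assert_that(all(dim(x) == c(3, 3)), "expected a 3x3 matrix")
    m <- x
  } else {
    assert_that(length(x) == 9, "expected 9 cells")
    m <- matrix(x, 3, 3, byrow = TRUE)
  }
  dimnames(m) <- list(GENOTYPE_CODES, GENOTYPE_CODES)
  m
}

#' Survival scenario for table simulation
#'
#' Bundles the nine survival rates (row-major cell order) with the sample
#' size and replicate count. Presets mirror the calibration study:
#' `null` (all rates 1), `alt1` (cell 9, the double inverted homozygote,
#' deflated to survival 0.2), and `alt2` (cell 8 deflated to 0.2, cell 9 at
#' 1, remaining cells at 0.7).
#'
#' @param name scenario label, or one of the presets `"null"`, `"alt1"`,
#'   `"alt2"` (which then fixes `survival`).
#' @param survival nine survival rates, row-major (ignored for presets).
#' @param n_individuals individuals per table (default 400).
#' @param n_tables number of tables to draw.
#' @param seed integer seed.
#' @return Object of class `survival_scenario`.
#' @export
survival_scenario <- function(name = c("null", "alt1", "alt2", "custom"),
                              survival = NULL, n_individuals = 400,
                              n_tables = 1000, seed = 1) {
  if (is.character(name) && name[1] %in% c("null", "alt1", "alt2")) {
    name <- name[1]
    survival <- switch(name,
      null = rep(1, 9),
      alt1 = c(rep(1, 8), 0.2),
      alt2 = c(rep(0.7, 7), 0.2, 1)
    )
  } else {
    name <- as.character(name)[1]
    assert_that(!is.null(survival), "custom scenario needs survival rates")
  }
  s <- as_cell_matrix(survival)
  assert_that(any(s > 0), "at least one survival rate must be positive")
  assert_that(n_individuals >= 1 && n_tables >= 1, "invalid sizes")
  structure(list(name = name, survival = s,
                 n_individuals = as.integer(n_individuals),
                 n_tables = as.integer(n_tables), seed = seed),
            class = "survival_scenario")
}

#' Simulate 3x3 genotype tables under a survival scenario
#'
#' Each table distributes `n_individuals` over the nine cells by a
#' multinomial draw from the survival-modified Mendelian expectation
#' (the natural sampling law for zygotic viability selection acting on
#' independent Mendelian zygotes).
#'
#' @param sc a [survival_scenario()].
#' @return 9 x n_tables integer matrix (each column a table, row-major cell
#'   order) with attributes `f_mod` and `scenario`.
#' @export
simulate_tables <- function(sc) {
  assert_that(inherits(sc, "survival_scenario"), "expected a survival_scenario")
  f_mod <- modified_expectation(mendelian_f2_probs(), sc$survival)
  probs <- as.vector(t(f_mod))  # row-major cell order
  draws <- with_seed(sc$seed,
                     stats::rmultinom(sc$n_tables, sc$n_individuals, probs))
  attr(draws, "f_mod") <- f_mod
  attr(draws, "scenario") <- sc$name
  draws
}

#' @noRd
cells_to_matrix <- function(cells) matrix(cells, 3, 3, byrow = TRUE,
                                          dimnames = list(GENOTYPE_CODES,
                                                          GENOTYPE_CODES))

#' Apply the three testing frameworks to a stream of simulated tables
#'
#' For every table: one Monte-Carlo p-value from the omnibus chi-squared
#' test and, for each of the four dosage-state submatrices, a bootstrap
#' p-value for the centered Jaccard/Tanimoto index and an exact p-value for
#' the affinity score — nine p-value streams in total. Submatrices with a
#' degenerate margin in a given table yield `NA` for that table.
#'
#' @param tables 9 x n matrix from [simulate_tables()] (or any row-major
#'   cell matrix).
#' @param B_inner Monte-Carlo/bootstrap replicates per table (default 1000
#'   in simulation mode).
#' @param seed integer seed.
#' @param expectation omnibus expectation mode (see [omnibus_chi2_mc()]).
#' @return Object of class `pvalue_distributions`: list of nine numeric
#'   vectors (`omnibus`, `cJT_sub1..4`, `alpha_sub1..4`).
#' @export
evaluate_frameworks <- function(tables, B_inner = 1000, seed = 1,
                                expectation = c("margins", "mendelian")) {
  expectation <- match.arg(expectation)
  assert_that(is.matrix(tables) && nrow(tables) == 9 && ncol(tables) >= 1,
              "`tables` must be a 9 x n cell matrix")
  n_tab <- ncol(tables)
  out <- list(omnibus = numeric(n_tab))
  for (k in 1:4) {
    out[[paste0("cJT_sub", k)]] <- numeric(n_tab)
    out[[paste0("alpha_sub", k)]] <- numeric(n_tab)
  }
  with_seed(seed, {
    for (i in seq_len(n_tab)) {
      t3 <- cells_to_matrix(tables[, i])
      n <- sum(t3)
      # omnibus: inline MC to avoid per-table seeding overhead
      e <- expected_counts(t3, expectation)
      stat <- chi2_stat(t3, e)
      if (expectation == "margins") {
        reps <- stats::r2dtable(B_inner, rowSums(t3), colSums(t3))
        null_stats <- vapply(reps, chi2_stat, numeric(1), expected = e)
      } else {
        f <- as.vector(e / n)
        draws <- stats::rmultinom(B_inner, n, f)
        null_stats <- colSums((draws - as.vector(e))^2 / as.vector(e))
      }
      out$omnibus[i] <- (1 + sum(null_stats >= stat - 1e-12)) / (B_inner + 1)
      for (k in 1:4) {
        st <- SUBMATRIX_STATES[[k]]
        t2 <- table2x2_from_table3x3(t3, st[1], st[2])
        mA <- attr(t2, "mA"); mB <- attr(t2, "mB"); n <- attr(t2, "n")
        if (n == 0 || mA == 0 || mA == n || mB == 0 || mB == n) {
          out[[paste0("cJT_sub", k)]][i] <- NA_real_
          out[[paste0("alpha_sub", k)]][i] <- NA_real_
          next
        }
        obs <- cjt_from_counts(t2[["n11"]], t2[["n10"]], t2[["n01"]], t2[["n00"]])
        n11s <- stats::rhyper(B_inner, mA, n - mA, mB)
        null_cjt <- cjt_from_counts(n11s, mA - n11s, mB - n11s,
                                    n - mA - mB + n11s)
        out[[paste0("cJT_sub", k)]][i] <-
          (1 + sum(abs(null_cjt) >= abs(obs) - 1e-12)) / (B_inner + 1)
        # exact affinity p (central hypergeometric, minimum-likelihood rule)
        lo <- max(0, mA + mB - n); hi <- min(mA, mB)
        d <- stats::dhyper(lo:hi, mA, n - mA, mB)
        d_obs <- stats::dhyper(t2[["n11"]], mA, n - mA, mB)
        out[[paste0("alpha_sub", k)]][i] <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
      }
    }
  })
  structure(out, class = "pvalue_distributions",
            scenario = attr(tables, "scenario"),
            B_inner = B_inner, expectation = expectation)
}

#' Summarize p-value distributions
#'
#' Per framework: number of non-missing p-values, rejection rate at `level`,
#' and the Kolmogorov-Smirnov distance from the uniform distribution.
#'
#' @param object a `pvalue_distributions` object.
#' @param level rejection level (default 0.05).
#' @param ... unused.
#' @return data.frame with columns `framework`, `n`, `rejection_rate`, `ks`.
#' @export
summary.pvalue_distributions <- function(object, level = 0.05, ...) {
  rows <- lapply(names(object), function(nm) {
    p <- object[[nm]]
    p <- p[!is.na(p)]
    ks <- if (length(p)) {
      u <- sort(p)
      i <- seq_along(u)
      max(pmax(i / length(u) - u, u - (i - 1) / length(u)))
    } else NA_real_
    data.frame(framework = nm, n = length(p),
               rejection_rate = mean(p < level),
               ks = ks, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-locus linkage disequilibrium metrics from gamete frequencies
#'
#' The classical haplotype-level measures for two biallelic loci:
#' `D = p_AB - p_A * p_B` and the normalized `D' = D / D_max`, where
#' `D_max = min(p_A (1 - p_B), (1 - p_A) p_B)` for positive D and
#' `min(p_A p_B, (1 - p_A)(1 - p_B))` for negative D; `D' = 0` when D is 0.
#'
#' @param gamete_freqs four gamete probabilities in order
#'   `(p_AB, p_Ab, p_aB, p_ab)`, summing to 1.
#' @return List with `D`, `Dprime`, `p_A`, `p_B`; both metrics are `NA`
#'   (with a warning) when either locus is monomorphic.
#' @export
ld_metrics <- function(gamete_freqs) {
  assert_that(length(gamete_freqs) == 4 && all(gamete_freqs >= 0) &&
                abs(sum(gamete_freqs) - 1) < 1e-8,
              "gamete frequencies must be 4 probabilities summing to 1")
  p_AB <- gamete_freqs[1]
  p_A <- gamete_freqs[1] + gamete_freqs[2]
  p_B <- gamete_freqs[1] + gamete_freqs[3]
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1)) {
    warning("monomorphic locus: D and D' undefined", call. = FALSE)
    return(list(D = NA_real_, Dprime = NA_real_, p_A = p_A, p_B = p_B))
  }
  d <- p_AB - p_A * p_B
  dmax <- if (d > 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
  else if (d < 0) min(p_A * p_B, (1 - p_A) * (1 - p_B))
  else NA_real_
  dprime <- if (d == 0) 0 else d / dmax
  list(D = d, Dprime = dprime, p_A = p_A, p_B = p_B)
}
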