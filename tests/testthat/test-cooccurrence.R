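# Centered Jaccard/Tanimoto, its bootstrap test, the affinity score, and
# the four-way decomposition of a locus pair.

vec_from_counts <- function(n11, n10, n01, n00) {
  list(x = rep(c(1, 1, 0, 0), c(n11, n10, n01, n00)),
       y = rep(c(1, 0, 1, 0), c(n11, n10, n01, n00)))
}

test_that("centered Jaccard is zero at exact independence and signed correctly", {
  v <- vec_from_counts(25, 25, 25, 25)
  expect_equal(centered_jaccard(v$x, v$y), 0)
  # identical vectors at prevalence 1/2: J = 1, E[J] = 1/3
  x <- rep(c(1, 0), 50)
  expect_equal(centered_jaccard(x, x), 2 / 3)
  # complementary vectors: J = 0, cJT = -E[J] < 0
  v2 <- vec_from_counts(0, 30, 30, 0)
  ej <- (0.5 * 0.5) / (0.5 + 0.5 - 0.25)
  expect_equal(centered_jaccard(v2$x, v2$y), -ej)
  expect_error(centered_jaccard(rep(0, 10), rep(c(0, 1), 5)), "all-zero")
})

test_that("centered Jaccard is symmetric and permutation-equivariant", {
  set.seed(8)
  for (i in 1:10) {
    x <- rbinom(40, 1, 0.4); y <- rbinom(40, 1, 0.6)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(centered_jaccard(x, y), centered_jaccard(y, x))
    perm <- sample(40)
    expect_equal(centered_jaccard(x[perm], y[perm]), centered_jaccard(x, y))
  }
})

test_that("bootstrap test: identical vectors reach the resolution floor", {
  x <- rep(c(1, 0), 50)
  r <- jaccard_bootstrap_test(x, x, B = 2000, seed = 3)
  expect_equal(r$cJT, 2 / 3)
  expect_equal(r$p, 1 / 2001)
})

test_that("bootstrap p agrees with the exhaustive placement oracle at n = 8", {
  cases <- list(c(3, 1, 1, 3), c(2, 2, 2, 2), c(4, 0, 1, 3))
  for (counts in cases) {
    v <- do.call(vec_from_counts, as.list(counts))
    exact <- exact_jaccard_perm_p(v$x, v$y)
    B <- 20000
    for (method in c("hypergeometric", "permutation")) {
      r <- jaccard_bootstrap_test(v$x, v$y, B = B, seed = 17, method = method)
      se <- sqrt(exact * (1 - exact) / B)
      expect_lt(abs(r$p - exact), 3 * se + 1 / (B + 1))
    }
  }
})

test_that("bootstrap test holds its size on independent vectors", {
  set.seed(12)
  n_rep <- 400
  ps <- vapply(seq_len(n_rep), function(i) {
    x <- rbinom(200, 1, 0.5); y <- rbinom(200, 1, 0.25)
    if (sum(x) %in% c(0, 200) || sum(y) %in% c(0, 200)) return(NA_real_)
    jaccard_bootstrap_test(x, y, B = 400, seed = 9000 + i)$p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  rate <- mean(ps < 0.05)
  # discrete + conservative ties: accept the nominal band extended to the
  # exact binomial floor at half nominal
  expect_lte(rate, binom99(length(ps), 0.05)[["hi"]])
  expect_gte(rate, binom99(length(ps), 0.025)[["lo"]])
})

test_that("affinity score: null, boundary, and grid-oracle cases", {
  expect_equal(affinity_alpha(c(n11 = 25, n10 = 25, n01 = 25, n00 = 25))$alpha, 0,
               tolerance = 1e-6)
  r_up <- affinity_alpha(c(n11 = 10, n10 = 0, n01 = 0, n00 = 10))
  expect_equal(r_up$alpha, 10)
  expect_true(r_up$capped)
  r_dn <- affinity_alpha(c(n11 = 0, n10 = 10, n01 = 10, n00 = 0))
  expect_equal(r_dn$alpha, -10)
  expect_equal(affinity_alpha(c(n11 = 10, n10 = 0, n01 = 0, n00 = 10),
                              cap = 5)$alpha, 5)
  # interior MLE against the dense-grid likelihood maximizer
  for (counts in list(c(8, 2, 3, 7), c(5, 9, 4, 12), c(12, 3, 8, 7))) {
    r <- affinity_alpha(stats::setNames(counts, c("n11", "n10", "n01", "n00")))
    want <- grid_alpha_oracle(counts[1], counts[2], counts[3], counts[4])
    expect_lt(abs(r$alpha - want), 1e-3)
  }
  expect_error(affinity_alpha(c(n11 = 5, n10 = 5, n01 = 0, n00 = 0)),
               "degenerate margin")
})

test_that("affinity matches the conditional-MLE and exact p of an established implementation", {
  for (counts in list(c(8, 2, 3, 7), c(15, 5, 10, 20), c(3, 11, 7, 9))) {
    r <- affinity_alpha(stats::setNames(counts, c("n11", "n10", "n01", "n00")))
    ft <- stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))
    expect_equal(r$alpha, log(unname(ft$estimate)), tolerance = 1e-4)
    expect_equal(r$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("affinity is antisymmetric under column swap and sign-linked to cJT", {
  set.seed(30)
  for (i in 1:25) {
    counts <- rmultinom(1, 80, c(0.2, 0.3, 0.25, 0.25))[, 1]
    if (any(c(counts[1] + counts[2], counts[1] + counts[3]) %in% c(0, 80))) next
    names(counts) <- c("n11", "n10", "n01", "n00")
    r <- affinity_alpha(counts)
    swapped <- counts[c("n10", "n11", "n00", "n01")]
    names(swapped) <- c("n11", "n10", "n01", "n00")
    r2 <- affinity_alpha(swapped)
    if (!r$capped && !r2$capped) {
      expect_equal(r$alpha, -r2$alpha, tolerance = 1e-6)
    }
    cjt <- cjt <- centered_jaccard(
      rep(c(1, 1, 0, 0), counts), rep(c(1, 0, 1, 0), counts))
    # sign(cJT) = sign(n11*n - mA*mB) = sign of the odds-ratio log
    if (abs(cjt) > 1e-10 && !r$capped && abs(r$alpha) > 1e-8) {
      expect_equal(sign(cjt), sign(r$alpha))
    }
  }
})

test_that("mid-p option shrinks the exact p by half the observed mass", {
  counts <- c(n11 = 8, n10 = 2, n01 = 3, n00 = 7)
  r <- affinity_alpha(counts)
  rm <- affinity_alpha(counts, midp = TRUE)
  expect_lt(rm$p, r$p)
})

test_that("pairwise contrasts recover a planted double-homozygote repulsion", {
  loci_df <- data.frame(locus_id = c("A", "B", "C"),
                        chromosome = c("chr1", "chr2", "chr3"),
                        segregating = TRUE)
  s <- matrix(1, 3, 3); s[3, 3] <- 0.2
  cfg <- cross_config("x", 400, loci_df,
                      pair_survival = list(list(locusA = "A", locusB = "B",
                                                survival = s)),
                      seed = 77)
  m <- simulate_f2_cross(cfg)
  res <- pairwise_contrasts(m, "A", "B", B = 2000, seed = 5)
  sub2 <- res[res$submatrix == 2, ]
  expect_lt(sub2$cJT, 0)
  expect_lt(sub2$alpha, 0)
  expect_lt(sub2$SR, 0)
  # the result is deterministic under a fixed seed
  res2 <- pairwise_contrasts(m, "A", "B", B = 2000, seed = 5)
  expect_identical(res$cJT_p, res2$cJT_p)
})

test_that("contrasts with a missing genotype class are skipped with a reason", {
  m <- toy_matrix(list(
    c("RR", "RI", "II", "RI", "RR", "II", "RI", "RR"),
    c("RR", "RI", "RR", "RI", "RI", "RR", "RI", "RR")  # no II at locus B
  ), loci_names = c("A", "B"))
  res <- pairwise_contrasts(m, "A", "B", B = 100, seed = 1)
  expect_true(all(res$skipped[res$submatrix %in% c(2, 3)]))
  expect_false(any(res$skipped[res$submatrix %in% c(1, 4)]))
  expect_match(res$skip_reason[res$submatrix == 2], "constant")
})

test_that("a Mendelian pair yields no coordinated detection", {
  loci_df <- data.frame(locus_id = c("A", "B"),
                        chromosome = c("chr1", "chr2"),
                        segregating = TRUE)
  hits <- vapply(1:30, function(r) {
    m <- simulate_f2_cross(cross_config("x", 200, loci_df, seed = 400 + r))
    res <- pairwise_contrasts(m, "A", "B", B = 300, seed = r)
    sum(res$detected_by_all, na.rm = TRUE)
  }, numeric(1))
  # triple-coincidence detections under the null are rare (each test ~5%,
  # strongly correlated, 4 contrasts/pair): a loose a-priori ceiling
  expect_lte(mean(hits > 0), 0.25)
})
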