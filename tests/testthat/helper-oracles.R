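# Independent oracles used across the suite: brute-force enumerations and
# closed-form computations that never share code paths with the package
# implementation they check.

# --- small genotype fixtures -------------------------------------------------

toy_matrix <- function(codes, cross = "toy", loci_names = NULL) {
  # codes: list of per-locus character vectors, all the same length
  g <- do.call(cbind, codes)
  colnames(g) <- loci_names %||% sprintf("Inv_%02d", seq_along(codes))
  rownames(g) <- sprintf("ind%03d", seq_len(nrow(g)))
  genotype_matrix(g, cross_id = cross)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- exact fixed-margin chi-squared p (exhaustive enumeration) --------------

# Enumerates every 3x3 table with the given margins; each table's null
# probability is the multivariate hypergeometric mass
#   prod(r_i!) prod(c_j!) / (N! prod(o_ij!)).
# Returns P(X2 >= observed X2) with expectations from the margins.
exact_margin_chi2_p <- function(observed) {
  r <- rowSums(observed); c <- colSums(observed); n <- sum(observed)
  e <- outer(r, c) / n
  stat_of <- function(o) sum((o[e > 0] - e[e > 0])^2 / e[e > 0])
  obs_stat <- stat_of(observed)
  log_base <- sum(lfactorial(r)) + sum(lfactorial(c)) - lfactorial(n)
  p <- 0
  for (a11 in 0:min(r[1], c[1])) for (a12 in 0:min(r[1] - a11, c[2])) {
    a13 <- r[1] - a11 - a12
    if (a13 < 0 || a13 > c[3]) next
    for (a21 in 0:min(r[2], c[1] - a11)) for (a22 in 0:min(r[2] - a21, c[2] - a12)) {
      a23 <- r[2] - a21 - a22
      if (a23 < 0 || a23 > c[3] - a13) next
      a31 <- c[1] - a11 - a21
      a32 <- c[2] - a12 - a22
      a33 <- c[3] - a13 - a23
      if (a31 < 0 || a32 < 0 || a33 < 0 || a31 + a32 + a33 != r[3]) next
      o <- matrix(c(a11, a21, a31, a12, a22, a32, a13, a23, a33), 3, 3)
      if (stat_of(o) >= obs_stat - 1e-9) {
        p <- p + exp(log_base - sum(lfactorial(o)))
      }
    }
  }
  p
}

# --- exact permutation p for the centered Jaccard test at tiny n ------------

# All arrangements of y against x collapse to the distribution of n11 over
# the C(n, mB) equally likely placements of y's ones; enumerated directly.
exact_jaccard_perm_p <- function(x, y) {
  n <- length(x); mB <- sum(y)
  placements <- utils::combn(n, mB)
  cjt_of <- function(n11, mA, mB, n) {
    union <- mA + mB - n11
    j <- if (union > 0) n11 / union else 0
    p <- mA / n; q <- mB / n
    j - p * q / (p + q - p * q)
  }
  mA <- sum(x)
  obs <- cjt_of(sum(x == 1 & y == 1), mA, mB, n)
  stats <- apply(placements, 2, function(pos) {
    ys <- integer(n); ys[pos] <- 1L
    cjt_of(sum(x == 1 & ys == 1), mA, mB, n)
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# --- dense-grid maximizer of the noncentral hypergeometric likelihood -------

grid_alpha_oracle <- function(n11, n10, n01, n00, lim = 10, step = 1e-4) {
  mA <- n11 + n10; mB <- n11 + n01; n <- n11 + n10 + n01 + n00
  support <- max(0, mA + mB - n):min(mA, mB)
  lw0 <- lchoose(mA, support) + lchoose(n - mA, mB - support)
  grid <- seq(-lim, lim, by = step)
  loglik <- vapply(grid, function(a) {
    lw <- lw0 + a * support
    a * n11 - (max(lw) + log(sum(exp(lw - max(lw)))))
  }, numeric(1))
  grid[which.max(loglik)]
}

# --- brute-force motif census over all node subsets -------------------------

brute_motif_census <- function(g, sizes = c(3, 4)) {
  labels <- c("3|2|1,1,2" = "path3", "3|3|2,2,2" = "triangle",
              "4|3|1,1,2,2" = "path4", "4|3|1,1,1,3" = "star4",
              "4|4|2,2,2,2" = "cycle4", "4|4|1,2,2,3" = "tadpole",
              "4|5|2,2,3,3" = "diamond", "4|6|3,3,3,3" = "clique4")
  counts <- stats::setNames(rep(0, length(labels)), names(labels))
  vs <- seq_len(igraph::vcount(g))
  for (size in sizes) {
    if (length(vs) < size) next
    subsets <- utils::combn(vs, size)
    for (i in seq_len(ncol(subsets))) {
      h <- igraph::induced_subgraph(g, subsets[, i])
      if (!igraph::is_connected(h)) next
      key <- paste(size, igraph::ecount(h),
                   paste(sort(igraph::degree(h)), collapse = ","), sep = "|")
      counts[[key]] <- counts[[key]] + 1
    }
  }
  stats::setNames(as.numeric(counts), unname(labels))
}

# --- exact attained level of the discrete 2x2 tests -------------------------

# Given the restricted 2x2 margins (mA, mB, n), the permutation null of n11
# is hypergeometric. For the exact affinity test the rejection probability
# at nominal `level` is the null mass of {k : p_exact(k) < level}. For the
# B-replicate bootstrap of the centered Jaccard index, rejection requires
# (1 + C)/(B + 1) < level with C ~ Binomial(B, q_k),
# q_k = P(|cJT*| >= |cJT(k)|), averaged over the null distribution of k.
attained_level_2x2 <- function(mA, mB, n, B = 1000, level = 0.05) {
  if (mA <= 0 || mA >= n || mB <= 0 || mB >= n) {
    return(c(alpha = NA_real_, cjt = NA_real_))
  }
  support <- max(0, mA + mB - n):min(mA, mB)
  d <- stats::dhyper(support, mA, n - mA, mB)
  p_exact <- vapply(d, function(dk) sum(d[d <= dk * (1 + 1e-7)]), numeric(1))
  alpha_level <- sum(d[p_exact < level])
  cjt_of <- function(k) {
    union <- mA + mB - k
    j <- ifelse(union > 0, k / union, 0)
    p <- mA / n; q <- mB / n
    j - p * q / (p + q - p * q)
  }
  a <- abs(cjt_of(support))
  q_k <- pmin(1, vapply(a, function(ak) sum(d[a >= ak - 1e-12]), numeric(1)))
  c_max <- ceiling(level * (B + 1)) - 2  # reject iff 1 + C <= this + 1
  cjt_level <- sum(d * stats::pbinom(c_max, B, q_k))
  c(alpha = alpha_level, cjt = cjt_level)
}

# Average attained level of each submatrix stream over a stream of tables
# (uses only each table's restricted margins; independent of the package's
# p-value code paths).
attained_levels_for_tables <- function(tables, B = 1000, level = 0.05) {
  subs <- list(c(2, 2), c(3, 3), c(2, 3), c(3, 2))  # (row, col) of state codes
  out <- matrix(NA_real_, ncol(tables), 8)
  for (i in seq_len(ncol(tables))) {
    t3 <- matrix(tables[, i], 3, 3, byrow = TRUE)
    for (k in 1:4) {
      rc <- subs[[k]]
      n11 <- t3[rc[1], rc[2]]; n10 <- t3[rc[1], 1]
      n01 <- t3[1, rc[2]]; n00 <- t3[1, 1]
      n <- n11 + n10 + n01 + n00
      lev <- attained_level_2x2(n11 + n10, n11 + n01, n, B = B, level = level)
      out[i, k] <- lev["cjt"]
      out[i, 4 + k] <- lev["alpha"]
    }
  }
  colnames(out) <- c(paste0("cJT_sub", 1:4), paste0("alpha_sub", 1:4))
  colMeans(out, na.rm = TRUE)
}

# Exact binomial 99% acceptance region for a rate
binom99 <- function(n, p) {
  c(lo = stats::qbinom(0.005, n, p) / n, hi = stats::qbinom(0.995, n, p) / n)
}
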