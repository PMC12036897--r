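# Networks, motif census/enrichment, replicated G, SDV-interaction summary.

make_contrast_df <- function(labels, cJT, cJT_p, omnibus_p = 0.5,
                             cross = "c1") {
  data.frame(cross = cross,
             locusA = sub("_[12]$", "", labels[, 1]),
             stateA = ifelse(grepl("_1$", labels[, 1]), "HET", "HOM_INV"),
             labelA = labels[, 1],
             locusB = sub("_[12]$", "", labels[, 2]),
             stateB = ifelse(grepl("_1$", labels[, 2]), "HET", "HOM_INV"),
             labelB = labels[, 2],
             cJT = cJT, cJT_p = cJT_p, omnibus_p = omnibus_p,
             skipped = FALSE, stringsAsFactors = FALSE)
}

test_that("network construction carries weights, flags, and centrality", {
  labels <- cbind(c("A_1", "A_1", "B_2"), c("B_2", "C_1", "C_1"))
  d <- make_contrast_df(labels, cJT = c(0.1, -0.2, 0.05),
                        cJT_p = c(0.6, 0.2, 0.9))
  g <- build_network(d)
  expect_equal(igraph::ecount(g), 3)
  expect_false(any(igraph::E(g)$significant))
  expect_equal(igraph::ecount(significant_subgraph(g)), 0)
  expect_equal(sort(igraph::E(g)$sign), c(-1, 1, 1))
  expect_true(all(is.finite(igraph::V(g)$centrality)))
  # centrality is invariant under node relabeling
  d2 <- d
  d2$labelA <- sub("A", "Z", d2$labelA); d2$labelB <- sub("A", "Z", d2$labelB)
  g2 <- build_network(d2)
  expect_equal(sort(igraph::V(g2)$centrality), sort(igraph::V(g)$centrality),
               tolerance = 1e-9)
})

test_that("a planted repulsion pair appears as a significant negative edge", {
  loci_df <- data.frame(locus_id = c("A", "B", "C"),
                        chromosome = c("chr1", "chr2", "chr3"),
                        segregating = TRUE)
  s <- matrix(1, 3, 3); s[3, 3] <- 0.05
  m <- simulate_f2_cross(cross_config("x", 1500, loci_df,
                                      pair_survival = list(list(
                                        locusA = "A", locusB = "B",
                                        survival = s)),
                                      seed = 123))
  res <- rbind(pairwise_contrasts(m, "A", "B", B = 1000, seed = 1),
               pairwise_contrasts(m, "A", "C", B = 1000, seed = 2),
               pairwise_contrasts(m, "B", "C", B = 1000, seed = 3))
  g <- build_network(res)
  sig <- significant_subgraph(g)
  ends <- igraph::as_data_frame(sig, what = "edges")
  planted <- ends[(ends$from == "A_2" & ends$to == "B_2") |
                    (ends$from == "B_2" & ends$to == "A_2"), ]
  expect_equal(nrow(planted), 1)
  expect_lt(planted$weight, 0)
})

test_that("motif census matches hand counts on canonical graphs", {
  k3 <- igraph::make_full_graph(3)
  c3 <- motif_census(k3)
  expect_equal(c3$observed[c3$motif == "triangle"], 1)
  expect_equal(c3$observed[c3$motif == "path3"], 0)
  star <- igraph::make_star(4, mode = "undirected")  # hub + 3 leaves
  cs <- motif_census(star)
  expect_equal(cs$observed[cs$motif == "path3"], 3)
  expect_equal(cs$observed[cs$motif == "triangle"], 0)
  expect_equal(cs$observed[cs$motif == "star4"], 1)
  expect_equal(cs$observed[cs$motif == "path4"], 0)
  # alias ordering: edge count then degree sequence
  expect_equal(cs$alias[cs$motif == "triangle"], "s.3.2")
  expect_equal(cs$alias[cs$motif == "clique4"], "s.4.6")
})

test_that("motif census equals brute-force subset enumeration on random graphs", {
  set.seed(19)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.6))
    got <- motif_census(g)
    want <- brute_motif_census(g)
    expect_equal(stats::setNames(got$observed, got$motif), want[got$motif])
  }
})

test_that("rewiring null preserves every node's degree", {
  set.seed(23)
  g <- igraph::sample_gnp(15, 0.3)
  for (r in 1:20) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    expect_identical(igraph::degree(gr), igraph::degree(g))
  }
})

test_that("motif enrichment flags structured graphs and not random ones", {
  # disjoint triangles: far more triangles than any degree-preserving rewire
  tri <- igraph::make_full_graph(3)
  g <- igraph::disjoint_union(tri, tri, tri, tri, tri)
  res <- motif_enrichment(g, R = 300, min_count = 0, seed = 31)
  row <- res[res$motif == "triangle", ]
  expect_equal(row$observed, 5)
  expect_gt(row$Z, 3)
  expect_lt(row$p_perm, 0.05)
  expect_gt(row$ratio, 1.5)
  # a plain random graph shows no enrichment at FDR 0.05
  set.seed(33)
  er <- igraph::sample_gnp(40, 0.2)
  calib <- motif_enrichment(er, R = 300, min_count = 0, seed = 35)
  expect_true(all(calib$p_adj >= 0.05, na.rm = TRUE))
  # min_count filter excludes scarce motifs from correction
  filt <- motif_enrichment(g, R = 50, min_count = 200, seed = 37)
  expect_false(any(filt$included))
  expect_true(all(is.na(filt$p_adj)))
})

test_that("replicated G decomposes exactly and nulls out on proportional tables", {
  prop <- matrix(c(20, 10, 10, 5), 2, 2)  # rank-1: independent
  r0 <- replicated_g(list(a = prop, b = 2 * prop, c = prop))
  expect_equal(r0$G, c(0, 0, 0), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    tabs <- lapply(1:5, function(j) matrix(rpois(4, 10) + 1, 2, 2))
    r <- replicated_g(tabs)
    expect_equal(r$G[r$component == "total"],
                 r$G[r$component == "pooled"] + r$G[r$component == "het"],
                 tolerance = 1e-9)
    expect_equal(r$df, c(5, 1, 4))
  }
  # degenerate cross contributes G = 0 with df 0
  degen <- matrix(c(4, 0, 6, 0), 2, 2)
  r2 <- replicated_g(list(a = matrix(c(8, 3, 2, 9), 2, 2), b = degen,
                          c = matrix(c(5, 6, 7, 2), 2, 2)))
  expect_equal(r2$df[r2$component == "total"], 2)
  per <- attr(r2, "per_cross")
  expect_equal(per$G[per$cross == "b"], 0)
  expect_equal(per$df[per$cross == "b"], 0)
})

test_that("SDV-interaction summary computes Spearman links and handles degenerate input", {
  sd <- data.frame(locus = c("A", "B", "C", "D"), SDV = c(4, 3, 2, 1))
  pw <- data.frame(locusA = c("A", "A", "B", "C"),
                   locusB = c("B", "C", "D", "D"),
                   p = c(0.01, 0.02, 0.2, 0.6))
  r <- sdv_interaction_summary(sd, pw)
  expect_equal(r$per_locus$n_significant[r$per_locus$locus == "A"], 2)
  # perfect rank agreement fixture
  sd2 <- data.frame(locus = c("A", "B", "C"), SDV = c(3, 2, 1))
  pw2 <- data.frame(locusA = c("A", "B", "C"), locusB = c("B", "C", "A"),
                    p = c(0.9, 0.9, 0.9))
  # counts are tied here; use mean_p instead for the exact-rank check
  pw3 <- data.frame(locusA = c("A", "A", "B"), locusB = c("B", "C", "C"),
                    p = c(0.1, 0.2, 0.5))
  r3 <- sdv_interaction_summary(sd2, pw3)
  mean_p_rho <- r3$correlations$rho[r3$correlations$metric == "mean_p"]
  expect_equal(abs(mean_p_rho), 1)
  # constant SDV: correlation undefined
  sd4 <- data.frame(locus = c("A", "B", "C"), SDV = c(2, 2, 2))
  r4 <- sdv_interaction_summary(sd4, pw2)
  expect_true(all(is.na(r4$correlations$rho)))
})

test_that("single-locus and pairwise effects stay uncoupled in the summary", {
  # generator truth: the planted SD locus is not the planted pair locus,
  # so SDV rank and interaction count are essentially unrelated
  bundle <- simulate_study_bundle(seed = 3, missing_rate = 0)
  m <- bundle$matrices[["155"]]
  meta <- bundle$meta
  sd <- sd_table(m)
  pairs <- enumerate_valid_pairs(m, meta, level = "locus")
  pairs <- pairs[seq_len(min(60, nrow(pairs))), ]
  pw <- data.frame(locusA = pairs$locusA, locusB = pairs$locusB,
                   p = vapply(seq_len(nrow(pairs)), function(i) {
                     omnibus_chi2_mc(pair_table3x3(m, pairs$locusA[i],
                                                   pairs$locusB[i]),
                                     B = 200, seed = i)$p_mc
                   }, numeric(1)))
  r <- sdv_interaction_summary(sd, pw)
  expect_true(is.finite(r$correlations$rho[1]))
  expect_lt(abs(r$correlations$rho[1]), 0.6)
})
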