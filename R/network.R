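# Co-occurrence networks, motif census and enrichment under a
# degree-preserving rewiring null, the replicated G heterogeneity test, and
# the segregation-distortion vs interaction summary.

#' Build a co-occurrence network from state-pair contrasts
#'
#' Nodes are dosage states (or loci) and edges carry the centered
#' Jaccard/Tanimoto index as weight, its raw bootstrap p-value, a
#' significance flag (`p < alpha_level`), and the omnibus-significance flag
#' of the parent locus pair. Node importance is the eigenvector centrality
#' of the absolute-weight graph. At `locus` granularity the contrast with
#' the smallest cJ/T p-value represents each pair.
#'
#' @param contrasts data.frame of state-pair results, as produced by
#'   [pairwise_contrasts()] (rows from several pairs may be rbind-ed);
#'   skipped contrasts are ignored.
#' @param alpha_level edge significance level on the raw cJ/T p (default 0.05).
#' @param granularity `"state"` (default) or `"locus"`.
#' @param meta optional locus metadata; chromosomes become node attributes.
#' @param omnibus_level level for the omnibus flag (default `alpha_level`).
#' @return An `igraph` object (undirected, simple) with edge attributes
#'   `weight` (cJT), `abs_weight`, `sign`, `p`, `significant`,
#'   `omnibus_significant`, and node attributes `centrality`, `chromosome`,
#'   `cross`.
#' @export
build_network <- function(contrasts, alpha_level = 0.05,
                          granularity = c("state", "locus"),
                          meta = NULL, omnibus_level = alpha_level) {
  granularity <- match.arg(granularity)
  keep <- !contrasts$skipped & !is.na(contrasts$cJT)
  d <- contrasts[keep, , drop = FALSE]
  if (granularity == "locus" && nrow(d) > 0) {
    key <- paste(d$cross, d$locusA, d$locusB)
    d <- do.call(rbind, lapply(split(d, key), function(g) {
      g[which.min(g$cJT_p), , drop = FALSE]
    }))
  }
  if (nrow(d) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (granularity == "state") {
    from <- d$labelA; to <- d$labelB
    node_locus <- stats::setNames(c(d$locusA, d$locusB), c(from, to))
  } else {
    from <- d$locusA; to <- d$locusB
    node_locus <- stats::setNames(c(d$locusA, d$locusB), c(from, to))
  }
  edges <- data.frame(from = from, to = to,
                      weight = d$cJT,
                      abs_weight = abs(d$cJT),
                      sign = sign(d$cJT),
                      p = d$cJT_p,
                      significant = d$cJT_p < alpha_level,
                      omnibus_significant = d$omnibus_p < omnibus_level,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  igraph::V(g)$cross <- d$cross[1]
  locus_of <- node_locus[!duplicated(names(node_locus))]
  igraph::V(g)$locus <- unname(locus_of[igraph::V(g)$name])
  if (!is.null(meta)) {
    chrom <- stats::setNames(meta$chromosome, meta$locus_id)
    igraph::V(g)$chromosome <- unname(chrom[igraph::V(g)$locus])
  }
  cent <- igraph::eigen_centrality(g, weights = igraph::E(g)$abs_weight)
  igraph::V(g)$centrality <- cent$vector
  g
}

#' Subgraph of significant co-occurrence edges
#'
#' @param g network from [build_network()].
#' @param use `"significant"` (raw cJ/T p below the build-time level) or
#'   `"omnibus_significant"`.
#' @return The edge-induced subgraph.
#' @export
significant_subgraph <- function(g, use = c("significant", "omnibus_significant")) {
  use <- match.arg(use)
  igraph::subgraph_from_edges(g, igraph::E(g)[igraph::edge_attr(g, use)],
                              delete.vertices = FALSE)
}

# Canonical labels for the connected undirected isomorphism classes on 3 and
# 4 nodes, ordered within each size by edge count then ascending sorted
# degree sequence. Aliases s.3.x / s.4.x follow that order.
motif_class_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rows <- list()
    names_by_sig <- c(
      "3|2|1,1,2" = "path3",   "3|3|2,2,2" = "triangle",
      "4|3|1,1,2,2" = "path4", "4|3|1,1,1,3" = "star4",
      "4|4|2,2,2,2" = "cycle4", "4|4|1,2,2,3" = "tadpole",
      "4|5|2,2,3,3" = "diamond", "4|6|3,3,3,3" = "clique4"
    )
    for (size in c(3L, 4L)) {
      n_class <- length(igraph::motifs(igraph::make_full_graph(size), size))
      info <- lapply(seq_len(n_class) - 1L, function(cls) {
        h <- igraph::graph_from_isomorphism_class(size, cls, directed = FALSE)
        list(class = cls, connected = igraph::is_connected(h),
             edges = igraph::ecount(h),
             degseq = paste(sort(igraph::degree(h)), collapse = ","))
      })
      info <- Filter(function(x) x$connected, info)
      df <- data.frame(size = size,
                       class = vapply(info, `[[`, integer(1), "class"),
                       edges = vapply(info, `[[`, numeric(1), "edges"),
                       degseq = vapply(info, `[[`, character(1), "degseq"),
                       stringsAsFactors = FALSE)
      df <- df[order(df$edges, df$degseq), , drop = FALSE]
      df$alias <- sprintf("s.%d.%d", size, seq_len(nrow(df)))
      df$motif <- names_by_sig[paste(df$size, df$edges, df$degseq, sep = "|")]
      rows[[as.character(size)]] <- df
    }
    cache <<- do.call(rbind, rows)
    rownames(cache) <- NULL
    cache
  }
})

#' Census of connected 3- and 4-node motifs
#'
#' Counts connected induced subgraphs of the given sizes per isomorphism
#' class: on 3 nodes the path and the triangle; on 4 nodes the path, star,
#' cycle, tadpole, diamond and complete graph. Disconnected node subsets
#' are not counted. Aliases `s.3.1`, `s.3.2`, `s.4.1` .. `s.4.6` order the
#' classes within a size by edge count, then degree sequence.
#'
#' @param g simple undirected `igraph` graph.
#' @param sizes subgraph orders to census (subset of `c(3, 4)`).
#' @return data.frame with columns `motif`, `alias`, `size`, `edges`,
#'   `degseq`, `observed`.
#' @export
motif_census <- function(g, sizes = c(3, 4)) {
  assert_that(all(sizes %in% c(3, 4)), "motif sizes 3 and 4 are supported")
  classes <- motif_class_table()
  classes <- classes[classes$size %in% sizes, , drop = FALSE]
  counts <- numeric(nrow(classes))
  for (size in unique(classes$size)) {
    m <- if (igraph::vcount(g) >= size) igraph::motifs(g, size = size) else NULL
    sel <- classes$size == size
    counts[sel] <- if (is.null(m)) 0 else m[classes$class[sel] + 1L]
  }
  counts[is.na(counts)] <- 0
  data.frame(motif = classes$motif, alias = classes$alias,
             size = classes$size, edges = classes$edges,
             degseq = classes$degseq, observed = counts,
             stringsAsFactors = FALSE)
}

#' Motif enrichment against a degree-preserving rewiring null
#'
#' Generates `R` null networks by double-edge swaps that preserve every
#' node's degree (`swaps_per_edge * ecount(g)` attempted swaps each),
#' counts motifs in each, and reports for every motif class the null mean
#' and sd, the Z-score, the observed/expected ratio, and a one-sided
#' overrepresentation permutation p-value
#' `(1 + #(null >= observed)) / (R + 1)`. Classes observed fewer than
#' `min_count` times are excluded before the Benjamini-Hochberg correction
#' (`included = FALSE`, `p_adj = NA`).
#'
#' @param g simple undirected graph with at least one edge.
#' @param R number of rewired replicates (default 1000).
#' @param swaps_per_edge attempted swaps per edge per replicate (default 10).
#' @param min_count minimum observed count for a class to enter the FDR
#'   correction (default 200, mirroring the scarce-motif exclusion rule).
#' @param sizes motif orders (default `c(3, 4)`).
#' @param seed optional integer seed.
#' @return data.frame per motif class: observed, `null_mean`, `null_sd`,
#'   `Z`, `ratio`, `p_perm`, `p_adj`, `included`, plus a `rewire_failed`
#'   attribute set when the graph is too sparse to rewire.
#' @export
motif_enrichment <- function(g, R = 1000, swaps_per_edge = 10,
                             min_count = 200, sizes = c(3, 4), seed = NULL) {
  assert_that(igraph::ecount(g) >= 1, "graph has no edges")
  obs <- motif_census(g, sizes = sizes)
  n_swaps <- max(1L, as.integer(swaps_per_edge * igraph::ecount(g)))
  rewirable <- igraph::ecount(g) >= 2
  null_counts <- with_seed(seed, {
    vapply(seq_len(R), function(r) {
      gr <- if (rewirable) {
        igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
      } else g
      motif_census(gr, sizes = sizes)$observed
    }, numeric(nrow(obs)))
  })
  null_counts <- matrix(null_counts, nrow = nrow(obs))
  obs$null_mean <- rowMeans(null_counts)
  obs$null_sd <- apply(null_counts, 1, stats::sd)
  obs$Z <- ifelse(obs$null_sd > 0, (obs$observed - obs$null_mean) / obs$null_sd,
                  NA_real_)
  obs$ratio <- ifelse(obs$null_mean > 0, obs$observed / obs$null_mean, NA_real_)
  obs$p_perm <- (1 + rowSums(null_counts >= obs$observed)) / (R + 1)
  obs$included <- obs$observed >= min_count
  obs$p_adj <- NA_real_
  if (any(obs$included)) {
    obs$p_adj[obs$included] <- stats::p.adjust(obs$p_perm[obs$included],
                                               method = "BH")
  }
  attr(obs, "rewire_failed") <- !rewirable
  attr(obs, "R") <- R
  obs
}

#' Replicated G test of independence across crosses
#'
#' Decomposes the evidence for association of one state pair replicated
#' over crosses: `G_total` is the sum of the per-cross independence G
#' statistics (df = sum of per-cross dfs), `G_pooled` is the independence G
#' of the element-wise summed table (df 1 for 2x2 input), and the
#' heterogeneity component is `G_het = G_total - G_pooled`
#' (df = df_total - df_pooled). A cross with a degenerate margin
#' contributes G = 0 with df 0.
#'
#' @param tables named list (one per cross) of 2x2 count matrices for the
#'   same state pair.
#' @return data.frame with one row per component (`total`, `pooled`,
#'   `het`): `G`, `df`, `p`; attribute `per_cross` holds the per-cross
#'   results.
#' @export
replicated_g <- function(tables) {
  assert_that(is.list(tables) && length(tables) >= 2,
              "need tables from at least 2 crosses")
  per <- lapply(tables, g_independence)
  g_i <- vapply(per, `[[`, numeric(1), "G")
  df_i <- vapply(per, function(x) as.numeric(x$df), numeric(1))
  g_total <- sum(g_i)
  df_total <- sum(df_i)
  pooled_tab <- Reduce(`+`, tables)
  pooled <- g_independence(pooled_tab)
  g_het <- g_total - pooled$G
  df_het <- df_total - pooled$df
  p_of <- function(g, df) if (df >= 1) stats::pchisq(g, df, lower.tail = FALSE)
  else NA_real_
  out <- data.frame(
    component = c("total", "pooled", "het"),
    G = c(g_total, pooled$G, g_het),
    df = c(df_total, pooled$df, df_het),
    p = c(p_of(g_total, df_total), p_of(pooled$G, pooled$df),
          p_of(g_het, df_het)),
    stringsAsFactors = FALSE
  )
  attr(out, "per_cross") <- data.frame(
    cross = names(tables) %||% as.character(seq_along(tables)),
    G = g_i, df = df_i, row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Replicated G for a state pair straight from genotype matrices
#'
#' Convenience wrapper building the per-cross conditional 2x2 subtables
#' for one dosage state pair (see [state_pair_table2x2()]) and delegating
#' to [replicated_g()].
#'
#' @param matrices list of [genotype_matrix()] objects (one per cross).
#' @param locusA,locusB locus ids shared by all crosses.
#' @param stateA,stateB `"HET"` or `"HOM_INV"`.
#' @return See [replicated_g()].
#' @export
replicated_g_states <- function(matrices, locusA, stateA, locusB, stateB) {
  tables <- lapply(matrices, function(m) {
    t2 <- state_pair_table2x2(m, locusA, stateA, locusB, stateB)
    matrix(c(t2[["n11"]], t2[["n01"]], t2[["n10"]], t2[["n00"]]), 2, 2,
           dimnames = list(A = c("present", "absent"),
                           B = c("present", "absent")))
  })
  names(tables) <- vapply(matrices, function(m) m$cross_id, character(1))
  replicated_g(tables)
}

#' Relationship between segregation distortion and pairwise interaction
#'
#' For every locus: its SDV, the number of pairwise omnibus tests involving
#' it with raw p below `level`, and its mean pairwise p-value; then the
#' Spearman correlations of SDV with both metrics. Loci with no valid pairs
#' are excluded; a constant SDV vector yields `NA` correlations.
#'
#' @param sd data.frame from [sd_table()] (columns `locus`, `SDV`).
#' @param pairwise data.frame of omnibus results with columns `locusA`,
#'   `locusB`, `p` (one row per tested pair).
#' @param level significance level for the count metric (default 0.05).
#' @return List with `per_locus` (data.frame `locus`, `SDV`, `n_significant`,
#'   `mean_p`, `n_pairs`) and `correlations` (data.frame `metric`, `rho`,
#'   `p`).
#' @export
sdv_interaction_summary <- function(sd, pairwise, level = 0.05) {
  locus_ids <- intersect(sd$locus, unique(c(pairwise$locusA, pairwise$locusB)))
  per <- do.call(rbind, lapply(locus_ids, function(l) {
    ps <- pairwise$p[pairwise$locusA == l | pairwise$locusB == l]
    if (!length(ps)) return(NULL)
    data.frame(locus = l, SDV = sd$SDV[match(l, sd$locus)],
               n_significant = sum(ps < level), mean_p = mean(ps),
               n_pairs = length(ps), stringsAsFactors = FALSE)
  }))
  spearman <- function(x, y) {
    if (length(unique(x)) < 2 || length(unique(y)) < 2 || length(x) < 3) {
      return(c(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  c1 <- spearman(per$SDV, per$n_significant)
  c2 <- spearman(per$SDV, per$mean_p)
  list(per_locus = per,
       correlations = data.frame(
         metric = c("n_significant", "mean_p"),
         rho = c(c1["rho"], c2["rho"]),
         p = c(c1["p"], c2["p"]),
         row.names = NULL, stringsAsFactors = FALSE))
}
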