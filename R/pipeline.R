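# End-to-end orchestration: per cross, the segregation-distortion table,
# valid-pair enumeration, omnibus + post hoc + four-way co-occurrence
# contrasts, network and motif statistics; across crosses, the replicated G
# heterogeneity test for universally segregating state pairs and the
# SDV-vs-interaction summary. Every stage writes a plain-text artifact.

#' Run the full analysis pipeline on a set of crosses
#'
#' @param matrices named list of [genotype_matrix()] objects (one per
#'   cross), or a character vector of genotype TSV paths.
#' @param meta locus metadata data.frame (`locus_id`, `chromosome`) or a
#'   TSV path.
#' @param out_dir output directory for the report bundle.
#' @param B Monte-Carlo / bootstrap replicates per test (default 10000;
#'   reduce for exploratory runs).
#' @param seed integer master seed; per-stage seeds are derived from it so
#'   reruns are byte-identical.
#' @param level significance level (default 0.05).
#' @param expectation omnibus expectation mode (see [omnibus_chi2_mc()]).
#' @param cap affinity cap (default 10).
#' @param motif_R,swaps_per_edge,min_count motif enrichment parameters
#'   (see [motif_enrichment()]).
#' @param sd_variant selection-mode variant (see [selection_mode_test()]).
#' @return Invisibly, a list with the per-stage data frames and the paths
#'   of all written artifacts.
#' @export
run_pipeline <- function(matrices, meta, out_dir, B = 10000, seed = 1,
                         level = 0.05,
                         expectation = c("margins", "mendelian"),
                         cap = 10, motif_R = 1000, swaps_per_edge = 10,
                         min_count = 200,
                         sd_variant = c("one_two_one", "hwe_conditional")) {
  expectation <- match.arg(expectation)
  sd_variant <- match.arg(sd_variant)
  if (is.character(matrices)) {
    matrices <- lapply(matrices, read_genotype_matrix)
    names(matrices) <- vapply(matrices, function(m) m$cross_id, character(1))
  }
  if (is.character(meta)) meta <- read_locus_meta(meta)
  assert_that(length(matrices) >= 1, "no input crosses")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  log <- list(seed = seed, B = B, level = level, expectation = expectation)
  paths <- character(0)

  sd_all <- stage("sd", do.call(rbind, lapply(matrices, sd_table,
                                              variant = sd_variant,
                                              level = level)))
  paths["sd"] <- write_tsv(sd_all, "sd_table.tsv")

  contrasts_all <- list()
  omnibus_all <- list()
  networks <- list()
  motifs_all <- list()
  for (ci in seq_along(matrices)) {
    m <- matrices[[ci]]
    cross <- m$cross_id
    pairs <- stage("pairs", enumerate_valid_pairs(m, meta, level = "locus"))
    log[[paste0("valid_pairs_", cross)]] <- nrow(pairs)
    if (nrow(pairs) == 0) next
    res <- stage("cooccur", lapply(seq_len(nrow(pairs)), function(i) {
      pairwise_contrasts(m, pairs$locusA[i], pairs$locusB[i], B = B,
                         seed = child_seed(seed, ci * 100000 + i),
                         level = level, cap = cap,
                         expectation = expectation)
    }))
    omni <- data.frame(
      cross = cross, locusA = pairs$locusA, locusB = pairs$locusB,
      chi2 = vapply(res, function(r) attr(r, "omnibus")$statistic, numeric(1)),
      p = vapply(res, function(r) attr(r, "omnibus")$p_mc, numeric(1)),
      stringsAsFactors = FALSE
    )
    omni$p_adj <- stats::p.adjust(omni$p, method = "BH")  # BH within cross
    omnibus_all[[cross]] <- omni
    contrasts <- do.call(rbind, res)
    key <- paste(contrasts$locusA, contrasts$locusB)
    omni_key <- paste(omni$locusA, omni$locusB)
    contrasts$omnibus_p_adj <- omni$p_adj[match(key, omni_key)]
    contrasts_all[[cross]] <- contrasts
    log[[paste0("skipped_contrasts_", cross)]] <- sum(contrasts$skipped)
    log[[paste0("valid_contrasts_", cross)]] <- sum(!contrasts$skipped)

    g <- stage("network", build_network(contrasts, alpha_level = level,
                                        meta = meta))
    networks[[cross]] <- g
    if (igraph::ecount(g) > 0) {
      gml <- file.path(out_dir, sprintf("network_%s.graphml", cross))
      igraph::write_graph(g, gml, format = "graphml")
      paths[paste0("network_", cross)] <- gml
      sub <- significant_subgraph(g)
      if (igraph::ecount(sub) >= 2) {
        mot <- stage("motifs", motif_enrichment(
          sub, R = motif_R, swaps_per_edge = swaps_per_edge,
          min_count = min_count, seed = child_seed(seed, 7000 + ci)))
        mot <- data.frame(network = cross, mot, stringsAsFactors = FALSE)
        motifs_all[[cross]] <- mot
      }
    }
  }
  if (length(omnibus_all)) {
    paths["omnibus"] <- write_tsv(do.call(rbind, omnibus_all), "omnibus.tsv")
  }
  if (length(contrasts_all)) {
    paths["contrasts"] <- write_tsv(do.call(rbind, contrasts_all),
                                    "contrasts.tsv")
  }
  if (length(motifs_all)) {
    paths["motifs"] <- write_tsv(do.call(rbind, motifs_all), "motifs.tsv")
  }

  # replicated G across crosses for state pairs of loci segregating everywhere
  repg <- NULL
  if (length(matrices) >= 2) {
    shared <- Reduce(intersect, lapply(matrices, segregating_loci))
    chrom <- stats::setNames(meta$chromosome, meta$locus_id)
    repg <- stage("replicated_g", {
      rows <- list()
      if (length(shared) >= 2) {
        lp <- utils::combn(shared, 2)
        for (j in seq_len(ncol(lp))) {
          a <- lp[1, j]; b <- lp[2, j]
          if (chrom[[a]] == chrom[[b]]) next
          for (sa in c("HET", "HOM_INV")) for (sb in c("HET", "HOM_INV")) {
            r <- replicated_g_states(matrices, a, sa, b, sb)
            rows[[length(rows) + 1]] <- data.frame(
              labelA = state_label(a, sa), labelB = state_label(b, sb),
              Gtotal = r$G[1], dftotal = r$df[1], ptotal = r$p[1],
              Gpooled = r$G[2], dfpooled = r$df[2], ppooled = r$p[2],
              Ghet = r$G[3], dfhet = r$df[3], phet = r$p[3],
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(repg)) paths["replicated_g"] <- write_tsv(repg,
                                                           "replicated_g.tsv")
  }

  # SDV vs interaction, per cross then pooled report
  sdv <- NULL
  if (length(omnibus_all)) {
    sdv <- stage("sdv_summary", {
      per <- lapply(names(omnibus_all), function(cross) {
        s <- sdv_interaction_summary(sd_all[sd_all$cross == cross, ],
                                     omnibus_all[[cross]], level = level)
        if (!is.null(s$per_locus) && nrow(s$per_locus)) {
          data.frame(cross = cross, s$per_locus, stringsAsFactors = FALSE)
        }
      })
      do.call(rbind, per)
    })
    if (!is.null(sdv)) paths["sdv"] <- write_tsv(sdv, "sdv_interaction.tsv")
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["log"] <- file.path(out_dir, "run_log.json")

  invisible(list(sd = sd_all,
                 omnibus = if (length(omnibus_all)) do.call(rbind, omnibus_all),
                 contrasts = if (length(contrasts_all))
                   do.call(rbind, contrasts_all),
                 motifs = if (length(motifs_all)) do.call(rbind, motifs_all),
                 replicated_g = repg,
                 sdv = sdv,
                 networks = networks,
                 paths = paths, log = log))
}
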