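# Synthetic F2 cross generator: Mendelian segregation at unlinked inversion
# loci distorted by zygotic viability selection at single loci and at
# cross-chromosome locus pairs. Serves both as a first-class simulator and
# as the test fixture generator, returning the planted ground truth
# alongside the genotypes.

#' Configuration for a simulated F2 cross
#'
#' @param cross_id cross label.
#' @param n_individuals target number of surviving F2 individuals.
#' @param loci data.frame with columns `locus_id`, `chromosome` and logical
#'   `segregating` (non-segregating loci are emitted as monomorphic RR).
#' @param single_locus_survival named list: locus id -> length-3 survival
#'   rates `(s_RR, s_RI, s_II)` in `[0, 1]`.
#' @param pair_survival list of lists with elements `locusA`, `locusB`
#'   (different chromosomes) and `survival` (3x3 matrix or row-major
#'   length-9 vector of rates in `[0, 1]`, rows = genotype of `locusA`).
#' @param missing_rate probability that a surviving call is set missing.
#' @param seed integer seed.
#' @return Object of class `cross_config`.
#' @export
cross_config <- function(cross_id, n_individuals, loci,
                         single_locus_survival = list(),
                         pair_survival = list(),
                         missing_rate = 0, seed = 1) {
  assert_that(all(c("locus_id", "chromosome", "segregating") %in% names(loci)),
              "`loci` needs locus_id, chromosome, segregating columns")
  assert_that(!anyDuplicated(loci$locus_id), "duplicated locus ids")
  assert_that(n_individuals >= 1, "need at least one individual")
  assert_that(missing_rate >= 0 && missing_rate < 1, "invalid missing rate")
  chrom <- stats::setNames(loci$chromosome, loci$locus_id)
  for (l in names(single_locus_survival)) {
    s <- single_locus_survival[[l]]
    assert_that(l %in% loci$locus_id, sprintf("unknown locus %s", l))
    assert_that(length(s) == 3 && all(s >= 0 & s <= 1) && any(s > 0),
                sprintf("invalid survival rates for locus %s", l))
  }
  for (p in pair_survival) {
    assert_that(all(c(p$locusA, p$locusB) %in% loci$locus_id),
                "pair effect on unknown locus")
    assert_that(chrom[[p$locusA]] != chrom[[p$locusB]],
                "pair effects only between different chromosomes")
    s <- as_cell_matrix(p$survival)
    assert_that(all(s >= 0 & s <= 1) && any(s > 0),
                "invalid pair survival rates")
  }
  structure(list(cross_id = as.character(cross_id),
                 n_individuals = as.integer(n_individuals),
                 loci = loci,
                 single_locus_survival = single_locus_survival,
                 pair_survival = pair_survival,
                 missing_rate = missing_rate, seed = seed),
            class = "cross_config")
}

#' Simulate one F2 cross under zygotic viability selection
#'
#' Zygotes draw independent 1:2:1 genotypes at every segregating locus
#' (loci are unlinked). Each zygote survives with probability equal to the
#' product of the applicable single-locus and pairwise survival rates;
#' rejection sampling continues until the target number of survivors is
#' reached. Missing calls are then inserted at `missing_rate`. The planted
#' effects are attached as attribute `truth` (and via [cross_truth()]).
#'
#' @param cfg a [cross_config()].
#' @return A [genotype_matrix()] with attributes `truth` (list with
#'   `single`, `pairs`, `segregating`) and `meta` (locus metadata
#'   data.frame).
#' @export
simulate_f2_cross <- function(cfg) {
  assert_that(inherits(cfg, "cross_config"), "expected a cross_config")
  loci_df <- cfg$loci
  seg <- loci_df$locus_id[loci_df$segregating]
  assert_that(length(seg) >= 1, "at least one segregating locus required")

  # joint survival must be attainable
  max_surv <- 1
  for (l in names(cfg$single_locus_survival)) {
    max_surv <- max_surv * max(cfg$single_locus_survival[[l]])
  }
  for (p in cfg$pair_survival) max_surv <- max_surv * max(p$survival)
  assert_that(max_surv > 0, "all-zero joint survival")

  n_target <- cfg$n_individuals
  survivors <- NULL
  with_seed(cfg$seed, {
    while (is.null(survivors) || nrow(survivors) < n_target) {
      batch <- max(2L * n_target, 200L)
      geno <- matrix(sample.int(3L, batch * length(seg), replace = TRUE,
                                prob = c(0.25, 0.5, 0.25)),
                     nrow = batch,
                     dimnames = list(NULL, seg))
      p_surv <- rep(1, batch)
      for (l in names(cfg$single_locus_survival)) {
        if (l %in% seg) {
          p_surv <- p_surv * cfg$single_locus_survival[[l]][geno[, l]]
        }
      }
      for (pe in cfg$pair_survival) {
        if (all(c(pe$locusA, pe$locusB) %in% seg)) {
          s <- as_cell_matrix(pe$survival)
          p_surv <- p_surv * s[cbind(geno[, pe$locusA], geno[, pe$locusB])]
        }
      }
      alive <- stats::runif(batch) < p_surv
      survivors <- rbind(survivors, geno[alive, , drop = FALSE])
    }
    survivors <- survivors[seq_len(n_target), , drop = FALSE]

    g <- matrix(NA_character_, n_target, nrow(loci_df),
                dimnames = list(sprintf("%s_ind%03d", cfg$cross_id,
                                        seq_len(n_target)),
                                loci_df$locus_id))
    g[, seg] <- GENOTYPE_CODES[survivors]
    g[, setdiff(loci_df$locus_id, seg)] <- "RR"
    if (cfg$missing_rate > 0) {
      drop <- matrix(stats::runif(length(g)) < cfg$missing_rate, nrow(g))
      g[drop] <- NA_character_
    }
    m <- genotype_matrix(g, cross_id = cfg$cross_id)
    attr(m, "truth") <- list(
      single = cfg$single_locus_survival,
      pairs = cfg$pair_survival,
      segregating = seg
    )
    attr(m, "meta") <- data.frame(locus_id = loci_df$locus_id,
                                  chromosome = loci_df$chromosome,
                                  stringsAsFactors = FALSE)
    survivors <- m  # reuse binding to return from with_seed block
  })
  survivors
}

#' Planted ground truth of a simulated cross
#' @param m matrix from [simulate_f2_cross()].
#' @return List with `single`, `pairs`, `segregating`.
#' @export
cross_truth <- function(m) attr(m, "truth")

#' Write a simulated cross to disk (genotypes, metadata, truth)
#'
#' Emits the genotype TSV and the locus-metadata TSV consumed by
#' [read_genotype_matrix()] / [read_locus_meta()], plus a JSON file with
#' the planted effects for test harnesses.
#'
#' @param m matrix from [simulate_f2_cross()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_simulated_cross <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, sprintf("%s_genotypes.tsv", m$cross_id)),
    meta = file.path(dir, sprintf("%s_loci.tsv", m$cross_id)),
    truth = file.path(dir, sprintf("%s_truth.json", m$cross_id))
  )
  write_genotype_matrix(m, paths["genotypes"])
  utils::write.table(attr(m, "meta"), paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cross_truth(m), paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

# Study-design constants of the emulated experiment: nine crosses with the
# observed F2 family sizes, 64 inversion loci spread over 14 chromosomes.
STUDY_CROSSES <- c(`62` = 92, `155` = 188, `444` = 148, `502` = 163,
                   `541` = 164, `664` = 157, `909` = 148, `1034` = 151,
                   `1192` = 162)

#' Default locus panel: 64 inversions on 14 chromosomes
#' @noRd
study_locus_panel <- function(n_loci = 64, n_chrom = 14) {
  data.frame(
    locus_id = sprintf("Inv_%02d", seq_len(n_loci)),
    chromosome = sprintf("chr%02d", rep_len(seq_len(n_chrom), n_loci)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the full nine-cross study bundle
#'
#' Emulates the structure of the replicated F2 experiment the analyses
#' assume: nine crosses with family sizes 92-188, a shared panel of 64
#' inversion loci on 14 chromosomes, a cross-specific subset of loci
#' segregating (each locus segregates in a cross with probability
#' `p_segregating`; a small core of loci segregates everywhere), and
#' zygotic viability selection planted per cross: one single-locus effect
#' (survival `single_s_II` for the inverted homozygote) and one
#' cross-chromosome pair effect (survival `pair_s9` for the double inverted
#' homozygote, cell 9). Set the effect parameters to 1 for a fully
#' Mendelian (null) bundle.
#'
#' @param seed integer seed.
#' @param p_segregating per-cross probability that a locus segregates
#'   (default 0.55, reproducing roughly half the pairwise combinatorial
#'   space being valid).
#' @param single_s_II survival of the inverted homozygote at the planted
#'   single-locus effect (default 0.2; use 0 for a recessive lethal).
#' @param pair_s9 survival of the (II, II) cell at the planted pair effect
#'   (default 0.2).
#' @param missing_rate per-call missing probability (default 0.02).
#' @param n_core number of loci forced to segregate in all crosses
#'   (default 3).
#' @return List with `matrices` (named list of [genotype_matrix()]),
#'   `meta` (locus metadata), and `truth` (planted effects per cross).
#' @export
simulate_study_bundle <- function(seed = 1, p_segregating = 0.55,
                                  single_s_II = 0.2, pair_s9 = 0.2,
                                  missing_rate = 0.02, n_core = 3) {
  panel <- study_locus_panel()
  with_seed(seed, {
    core <- sample(panel$locus_id, n_core)
    configs <- lapply(seq_along(STUDY_CROSSES), function(i) {
      cross <- names(STUDY_CROSSES)[i]
      seg <- stats::runif(nrow(panel)) < p_segregating |
        panel$locus_id %in% core
      loci_df <- data.frame(panel, segregating = seg)
      seg_ids <- loci_df$locus_id[seg]
      single <- list()
      if (single_s_II < 1) {
        l1 <- sample(seg_ids, 1)
        single[[l1]] <- c(1, 1, single_s_II)
      }
      pairs <- list()
      if (pair_s9 < 1) {
        chrom <- stats::setNames(loci_df$chromosome, loci_df$locus_id)
        cand <- setdiff(seg_ids, names(single))
        repeat {
          pr <- sample(cand, 2)
          if (chrom[[pr[1]]] != chrom[[pr[2]]]) break
        }
        s <- matrix(1, 3, 3); s[3, 3] <- pair_s9
        pairs <- list(list(locusA = pr[1], locusB = pr[2], survival = s))
      }
      cross_config(cross_id = cross,
                   n_individuals = STUDY_CROSSES[[i]],
                   loci = loci_df,
                   single_locus_survival = single,
                   pair_survival = pairs,
                   missing_rate = missing_rate,
                   seed = sample.int(2^30, 1))
    })
    matrices <- lapply(configs, simulate_f2_cross)
    names(matrices) <- names(STUDY_CROSSES)
    list(
      matrices = matrices,
      meta = panel,
      truth = lapply(matrices, cross_truth)
    )
  })
}
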