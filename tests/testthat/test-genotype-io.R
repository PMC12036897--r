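# Genotype data model, readers/writers, segregation and pair enumeration.

test_that("reading normalizes codes case-insensitively and flags unknown tokens", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual\tInv_01\tInv_02",
               "i1\trr\tRI",
               "i2\tRI\tii",
               "i3\tii\tNA",
               "i4\tXX\tRR"), f)
  expect_warning(m <- read_genotype_matrix(f), "1 unrecognized")
  expect_equal(m$genotypes["i1", "Inv_01"], "RR")
  expect_equal(m$genotypes["i2", "Inv_02"], "II")
  expect_equal(sum(is.na(m$genotypes)), 2L)  # the NA token and the XX token
})

test_that("write/read round trip reproduces the matrix exactly", {
  m <- toy_matrix(list(c("RR", "RI", "II", NA), c("RI", "RI", "RR", "II")),
                  cross = "444")
  for (dialect in c("tsv", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_genotype_matrix(m, f, dialect = dialect)
    m2 <- read_genotype_matrix(f, dialect = dialect)
    expect_identical(m2$genotypes, m$genotypes)
    expect_identical(m2$cross_id, "444")
  }
})

test_that("malformed inputs are hard errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual\tInv_01\tInv_01", "i1\tRR\tRI"), f)
  expect_error(read_genotype_matrix(f), "duplicated locus")
  writeLines(c("individual\tInv_01", "i1\tRR", "i1\tRI"), f)
  expect_error(read_genotype_matrix(f), "duplicated individual")
  writeLines(character(0), f)
  expect_error(read_genotype_matrix(f))
  g <- matrix("ZZ", 1, 1, dimnames = list("i", "l"))
  expect_error(genotype_matrix(g), "invalid genotype codes")
})

test_that("segregation requires two observed genotype classes", {
  m <- toy_matrix(list(
    rep("RR", 6),                      # monomorphic: out
    c("RR", "RR", "RI", "RI", "RR", "RR"),  # RR/RI: in
    c("RR", "II", "RR", "II", NA, NA), # RR/II without hets: in
    c(NA, NA, NA, NA, NA, NA)          # all missing: out
  ))
  expect_identical(segregating_loci(m), c("Inv_02", "Inv_03"))
})

test_that("binarization partitions non-missing individuals over the three codes", {
  m <- toy_matrix(list(c("RR", "RI", "II", "RI")))
  expect_equal(unname(binarize_state(m, "Inv_01", "HET")), c(0L, 1L, 0L, 1L))
  expect_equal(unname(binarize_state(m, "Inv_01", "HOM_INV")), c(0L, 0L, 1L, 0L))
  # HET + HOM_INV + RR indicator = 1 elementwise on non-missing entries
  m2 <- toy_matrix(list(c("RR", "RI", "II", NA, "RR", "II")))
  het <- binarize_state(m2, "Inv_01", "HET")
  hom <- binarize_state(m2, "Inv_01", "HOM_INV")
  rr <- as.integer(m2$genotypes[, 1] == "RR")
  ok <- !is.na(m2$genotypes[, 1])
  expect_true(all((het + hom + rr)[ok] == 1L))
  # an all-RR locus binarizes to all zero under any state
  m3 <- toy_matrix(list(rep("RR", 4)))
  expect_true(all(binarize_state(m3, "Inv_01", "HET") == 0L))
})

test_that("pair enumeration respects chromosome and segregation filters", {
  m <- toy_matrix(list(c("RR", "RI", "II"), c("RI", "RR", "RI"),
                       c("RR", "RR", "RR")))
  meta <- data.frame(locus_id = c("Inv_01", "Inv_02", "Inv_03"),
                     chromosome = c("chr1", "chr1", "chr2"))
  # both segregating loci share chr1 -> no valid pair
  expect_equal(nrow(enumerate_valid_pairs(m, meta, level = "locus")), 0L)
  meta$chromosome <- c("chr1", "chr2", "chr3")
  pairs <- enumerate_valid_pairs(m, meta, level = "locus")
  expect_equal(nrow(pairs), 1L)  # Inv_03 is monomorphic
  expect_setequal(unlist(pairs[1, ]), c("Inv_01", "Inv_02"))
  # idempotent and order-stable
  expect_identical(pairs, enumerate_valid_pairs(m, meta, level = "locus"))
  # missing chromosome for a segregating locus is an error
  expect_error(enumerate_valid_pairs(m, meta[-1, ], level = "locus"),
               "no chromosome")
})

test_that("pair enumeration agrees with a brute-force double loop on synthetic crosses", {
  bundle <- simulate_study_bundle(seed = 7, missing_rate = 0.02)
  meta <- bundle$meta
  chrom <- setNames(meta$chromosome, meta$locus_id)
  for (cross in c("62", "909")) {
    m <- bundle$matrices[[cross]]
    seg <- segregating_loci(m)
    # generator bookkeeping: segregating set is a subset of the planted one
    # (sampling can fail to draw a rare class, never invent one)
    expect_true(all(seg %in% cross_truth(m)$segregating))
    got <- enumerate_valid_pairs(m, meta, level = "locus")
    want <- 0L
    for (i in seq_along(seg)) for (j in seq_along(seg)) {
      if (i < j && chrom[[seg[i]]] != chrom[[seg[j]]]) want <- want + 1L
    }
    expect_equal(nrow(got), want)
    # state-level count matches its own brute-force double loop
    states <- list()
    for (l in seg) for (s in c("HET", "HOM_INV")) {
      v <- binarize_state(m, l, s)
      v <- v[!is.na(v)]
      if (any(v == 1L) && any(v == 0L)) states[[length(states) + 1]] <- c(l, s)
    }
    want_s <- 0L
    for (i in seq_along(states)) for (j in seq_along(states)) {
      if (i < j && chrom[[states[[i]][1]]] != chrom[[states[[j]][1]]]) {
        want_s <- want_s + 1L
      }
    }
    expect_equal(nrow(enumerate_valid_pairs(m, meta, level = "state")), want_s)
  }
})
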