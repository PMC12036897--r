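# Genotype data model and I/O for F2 inversion matrices.
#
# An F2 individual carries one of three codes at each inversion locus:
# RR (homozygous for the reference orientation), RI (heterozygous), or
# II (homozygous for the inverted orientation). Missing calls are NA.

GENOTYPE_CODES <- c("RR", "RI", "II")

#' Construct a genotype matrix object
#'
#' The central data container: a character matrix of genotype codes with
#' individuals in rows and inversion loci in columns, plus a cross label.
#' Codes are kept as strings (never collapsed to allele dosages) so that
#' the inverted homozygote `II` is never silently conflated with a count.
#'
#' @param genotypes character matrix, entries in `RR`, `RI`, `II` or `NA`;
#'   rownames are individual ids, colnames are locus ids.
#' @param cross_id single label identifying the cross (genetic family).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, cross_id = "cross") {
  assert_that(is.matrix(genotypes) && is.character(genotypes),
              "`genotypes` must be a character matrix")
  assert_that(!is.null(rownames(genotypes)) && !is.null(colnames(genotypes)),
              "`genotypes` must carry individual (row) and locus (column) names")
  assert_that(!anyDuplicated(rownames(genotypes)),
              "duplicated individual ids")
  assert_that(!anyDuplicated(colnames(genotypes)),
              "duplicated locus ids")
  bad <- !is.na(genotypes) & !(genotypes %in% GENOTYPE_CODES)
  assert_that(!any(bad), sprintf(
    "invalid genotype codes: %s",
    paste(unique(genotypes[bad]), collapse = ", ")))
  structure(
    list(cross_id = as.character(cross_id)[1], genotypes = genotypes),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> cross %s: %d individuals x %d loci (%d missing calls)\n",
              x$cross_id, nrow(x$genotypes), ncol(x$genotypes),
              sum(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Individual and locus ids of a genotype matrix
#' @param m a `genotype_matrix`.
#' @return Character vector of ids.
#' @export
individuals <- function(m) rownames(m$genotypes)

#' @rdname individuals
#' @export
loci <- function(m) colnames(m$genotypes)

#' Normalize raw genotype tokens
#'
#' Case-insensitive mapping onto `RR`/`RI`/`II`; the reversed heterozygote
#' spelling `IR` is accepted. Common missing-data tokens and anything
#' unrecognized become `NA` (the latter with a warning carrying the count).
#' @noRd
normalize_codes <- function(x) {
  up <- toupper(trimws(x))
  up[up == "IR"] <- "RI"
  missing_tokens <- c("", "NA", "N", "-", ".", "NN", "./.")
  out <- ifelse(up %in% GENOTYPE_CODES, up, NA_character_)
  unknown <- sum(!is.na(x) & !(up %in% c(GENOTYPE_CODES, missing_tokens)))
  if (unknown > 0) {
    warning(sprintf("%d unrecognized genotype tokens set to missing", unknown),
            call. = FALSE)
  }
  out
}

#' Read a genotype matrix from TSV/CSV
#'
#' Expects a header row of locus ids and one row per individual, the first
#' column holding the individual id. An optional `cross`/`cross_id` column
#' supplies the cross label. Codes are normalized case-insensitively and
#' unknown tokens are converted to missing with a warning.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param cross_id cross label; overrides any cross column if given.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("tsv", "csv"),
                                 cross_id = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  assert_that(nrow(df) > 0 && ncol(df) >= 2, "empty or column-less genotype file")
  # check the raw header: data.frame subsetting silently uniquifies names
  assert_that(!anyDuplicated(names(df)), "duplicated locus ids in header")
  ids <- df[[1]]
  assert_that(!anyDuplicated(ids), "duplicated individual ids in file")
  df <- df[, -1, drop = FALSE]
  cross_col <- which(tolower(names(df)) %in% c("cross", "cross_id"))
  if (length(cross_col)) {
    if (is.null(cross_id)) cross_id <- df[[cross_col[1]]][1]
    df <- df[, -cross_col, drop = FALSE]
  }
  g <- as.matrix(df)
  g[] <- normalize_codes(g)
  rownames(g) <- ids
  genotype_matrix(g, cross_id = cross_id %||% "cross")
}

#' Write a genotype matrix to TSV/CSV
#'
#' Emits the same dialect [read_genotype_matrix()] consumes, so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param m a `genotype_matrix`.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_genotype_matrix <- function(m, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(individual = individuals(m),
                   cross = m$cross_id,
                   m$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read locus metadata (locus id, chromosome)
#'
#' @param path two-column TSV with header columns `locus_id` and `chromosome`.
#' @return data.frame with character columns `locus_id` and `chromosome`.
#' @export
read_locus_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  assert_that(all(c("locus_id", "chromosome") %in% names(df)),
              "locus metadata needs `locus_id` and `chromosome` columns")
  assert_that(!anyDuplicated(df$locus_id), "duplicated locus ids in metadata")
  df[, c("locus_id", "chromosome")]
}

#' Loci segregating within a cross
#'
#' A locus segregates when at least two distinct non-missing genotype
#' classes are observed; a locus with only `RR` and `II` (no heterozygotes)
#' still counts.
#'
#' @param m a `genotype_matrix`.
#' @return Character vector of segregating locus ids.
#' @export
segregating_loci <- function(m) {
  g <- m$genotypes
  keep <- vapply(seq_len(ncol(g)), function(j) {
    length(unique(g[!is.na(g[, j]), j])) >= 2L
  }, logical(1))
  colnames(g)[keep]
}

#' Dosage-state label
#'
#' A locus decomposes into two presence/absence states: `HET` (carrying
#' exactly one inverted orientation, genotype `RI`) and `HOM_INV`
#' (homozygous inverted, `II`). The reference homozygote `RR` is the
#' implicit complement and is never a state of its own. The conventional
#' printed suffixes are `_1` = HET and `_2` = HOM_INV.
#'
#' @param locus locus id.
#' @param state `"HET"` or `"HOM_INV"`.
#' @return Label of the form `<locus>_1` / `<locus>_2`.
#' @export
state_label <- function(locus, state = c("HET", "HOM_INV")) {
  state <- match.arg(state, several.ok = FALSE)
  paste0(locus, if (state == "HET") "_1" else "_2")
}

#' @noRd
state_code <- function(state) c(HET = "RI", HOM_INV = "II")[[state]]

#' Binarize a locus into a dosage-state presence vector
#'
#' @param m a `genotype_matrix`.
#' @param locus locus id present in `m`.
#' @param state `"HET"` or `"HOM_INV"`.
#' @return Integer vector over individuals: 1 where the genotype equals the
#'   state's code, 0 otherwise, `NA` for missing calls (dropped pairwise at
#'   contrast time).
#' @export
binarize_state <- function(m, locus, state = c("HET", "HOM_INV")) {
  state <- match.arg(state)
  assert_that(locus %in% loci(m), sprintf("locus %s not in matrix", locus))
  g <- m$genotypes[, locus]
  out <- as.integer(g == state_code(state))
  names(out) <- individuals(m)
  out
}

#' Enumerate valid locus or state pairs for co-occurrence testing
#'
#' At `locus` level, a valid pair is an unordered pair of segregating loci
#' on different chromosomes. At `state` level, each segregating locus is
#' decomposed into its HET and HOM_INV states; a state is usable when it is
#' present in at least one individual and absent in at least one, and valid
#' pairs combine usable states of loci on different chromosomes. Setting
#' the filter flags to `FALSE` enumerates the full combinatorial space
#' (e.g. 64 loci give 2016 locus pairs and 8128 state pairs).
#'
#' @param m a `genotype_matrix`.
#' @param meta locus metadata data.frame (`locus_id`, `chromosome`);
#'   must cover every locus considered unless `different_chromosomes = FALSE`.
#' @param level `"locus"` or `"state"`.
#' @param segregating_only restrict to segregating loci (default `TRUE`).
#' @param different_chromosomes require the two loci to sit on different
#'   chromosomes (default `TRUE`).
#' @param drop_constant_states at state level, require each state to vary
#'   across individuals (default `TRUE`).
#' @return data.frame of pairs; locus level has columns `locusA`, `locusB`;
#'   state level adds `stateA`, `stateB` and the printed labels.
#' @export
enumerate_valid_pairs <- function(m, meta = NULL,
                                  level = c("locus", "state"),
                                  segregating_only = TRUE,
                                  different_chromosomes = TRUE,
                                  drop_constant_states = TRUE) {
  level <- match.arg(level)
  locus_ids <- if (segregating_only) segregating_loci(m) else loci(m)
  chrom <- NULL
  if (different_chromosomes) {
    assert_that(!is.null(meta), "locus metadata required to filter by chromosome")
    chrom <- stats::setNames(meta$chromosome, meta$locus_id)
    missing_meta <- setdiff(locus_ids, names(chrom))
    assert_that(length(missing_meta) == 0, sprintf(
      "no chromosome recorded for loci: %s", paste(missing_meta, collapse = ", ")))
  }

  if (level == "locus") {
    if (length(locus_ids) < 2) {
      return(data.frame(locusA = character(0), locusB = character(0)))
    }
    idx <- utils::combn(locus_ids, 2)
    out <- data.frame(locusA = idx[1, ], locusB = idx[2, ],
                      stringsAsFactors = FALSE)
    if (different_chromosomes) {
      out <- out[chrom[out$locusA] != chrom[out$locusB], , drop = FALSE]
    }
    rownames(out) <- NULL
    return(out)
  }

  states <- expand.grid(locus = locus_ids, state = c("HET", "HOM_INV"),
                        stringsAsFactors = FALSE)
  states <- states[order(match(states$locus, locus_ids)), , drop = FALSE]
  if (drop_constant_states) {
    usable <- vapply(seq_len(nrow(states)), function(i) {
      v <- binarize_state(m, states$locus[i], states$state[i])
      v <- v[!is.na(v)]
      length(v) > 0 && any(v == 1L) && any(v == 0L)
    }, logical(1))
    states <- states[usable, , drop = FALSE]
  }
  if (nrow(states) < 2) {
    return(data.frame(locusA = character(0), stateA = character(0),
                      locusB = character(0), stateB = character(0)))
  }
  idx <- utils::combn(nrow(states), 2)
  out <- data.frame(
    locusA = states$locus[idx[1, ]], stateA = states$state[idx[1, ]],
    locusB = states$locus[idx[2, ]], stateB = states$state[idx[2, ]],
    stringsAsFactors = FALSE
  )
  if (different_chromosomes) {
    out <- out[chrom[out$locusA] != chrom[out$locusB], , drop = FALSE]
  }
  out$labelA <- mapply(state_label, out$locusA, out$stateA, USE.NAMES = FALSE)
  out$labelB <- mapply(state_label, out$locusB, out$stateB, USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}
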