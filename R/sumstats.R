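#' @title GWAS/QTL summary-statistic tables
#'
#' @description
#' Throughout the package a set of per-variant marginal association statistics
#' ("summary statistics") is an ordinary `data.frame` with one row per variant
#' and the columns
#'
#' \describe{
#'   \item{snp_id}{variant identifier (character, unique within a table)}
#'   \item{chrom}{chromosome label, no `"chr"` prefix (character)}
#'   \item{pos}{1-based physical position (integer)}
#'   \item{effect_allele, other_allele}{single bases A/C/G/T; the beta is per
#'     copy of `effect_allele`}
#'   \item{eaf}{effect-allele frequency in `[0,1]`, `NA` when unknown}
#'   \item{beta}{marginal effect estimate (log odds ratio for binary traits)}
#'   \item{se}{standard error, strictly positive}
#'   \item{pvalue}{two-sided p-value in `(0, 1]`}
#'   \item{zscore}{`beta / se`}
#'   \item{n}{effective sample size}
#'   \item{ncase, ncontrol}{case/control counts for binary traits (`NA` for
#'     quantitative traits)}
#' }
#'
#' `validate_sumstats()` enforces the internal-consistency contract between
#' those columns: z must equal beta/se (relative tolerance 1e-8), p must match
#' the two-sided normal p implied by z (absolute tolerance 1e-6), alleles must
#' differ, and se must be positive.  A missing `zscore` or `pvalue` is
#' back-filled from the other quantities; a conflict beyond tolerance drops the
#' row.  The number of dropped rows is attached as the `"n_dropped"` attribute
#' and reported via `message()`, mirroring how dirty real-world summary files
#' are usually handled (log and continue, never silently keep).
#'
#' @name sumstats
NULL

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "zscore", "n",
                   "ncase", "ncontrol")

MANDATORY_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se")

BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a validated summary-statistics table
#'
#' @param df data.frame containing at least the mandatory columns
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`);
#'   optional columns are filled with `NA`.
#' @param quiet suppress the dropped-row message.
#' @return data.frame in canonical column order with invalid rows removed;
#'   attribute `"n_dropped"` holds the number of removed rows.
#' @export
validate_sumstats <- function(df, quiet = FALSE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLS, names(df))) df[[col]] <- NA
  df <- df[SUMSTATS_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "zscore", "n"))
    df[[col]] <- as.numeric(df[[col]])

  n_in <- nrow(df)
  bad <- logical(n_in)
  bad <- bad | is.na(df$snp_id) | is.na(df$beta) | is.na(df$se)
  bad <- bad | !(df$se > 0)
  bad <- bad | !(df$effect_allele %in% BASES) | !(df$other_allele %in% BASES)
  bad <- bad | (df$effect_allele == df$other_allele)
  bad <- bad | (!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))

  ok <- !bad
  # back-fill zscore from beta/se, check stored values against the implied ones
  z_implied <- ifelse(ok, df$beta / df$se, NA_real_)
  z_conflict <- ok & !is.na(df$zscore) &
    abs(df$zscore - z_implied) > 1e-8 * pmax(abs(z_implied), 1)
  bad <- bad | z_conflict
  df$zscore <- ifelse(is.na(df$zscore), z_implied, df$zscore)

  p_implied <- 2 * stats::pnorm(-abs(df$zscore))
  p_conflict <- !bad & !is.na(df$pvalue) & abs(df$pvalue - p_implied) > 1e-6
  bad <- bad | p_conflict
  df$pvalue <- ifelse(is.na(df$pvalue), p_implied, df$pvalue)
  bad <- bad | is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1

  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  n_dropped <- sum(bad)
  if (n_dropped > 0L && !quiet) {
    message("validate_sumstats: dropped ", n_dropped, " of ", n_in,
            " rows failing consistency checks")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a summary-statistics table from a tab-separated file
#'
#' @param path path to a TSV file with a header row.
#' @param dialect named character vector or list mapping canonical column
#'   names (see [sumstats]) to the column names used in the file, e.g.
#'   `c(snp_id = "SNP", pvalue = "P")`.  Unmapped canonical names are assumed
#'   to appear verbatim.
#' @param quiet suppress the dropped-row message.
#' @return validated summary-statistics data.frame (see [validate_sumstats]).
#' @export
read_sumstats <- function(path, dialect = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(raw)) {
        stop("dialect maps '", canon, "' to missing column '", file_col, "'")
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- validate_sumstats(raw, quiet = quiet)
  if (nrow(out) == 0L) stop("no valid rows in ", path)
  out
}

#' Write a result table as TSV with full numeric precision
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' read-back reproduces every value to better than 1e-12 relative error.
#'
#' @param records data.frame of results (any of the package's record types).
#' @param path output path.
#' @export
write_report <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("refusing to write an empty report")
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a report written by [write_report]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read an LD correlation matrix as TSV
#'
#' The file is the square correlation matrix with a header row of SNP ids and
#' the ids repeated in the first column.
#'
#' @param ld square correlation matrix with SNP ids as dimnames.
#' @param path file path.
#' @export
write_ld <- function(ld, path) {
  stopifnot(is.matrix(ld), nrow(ld) == ncol(ld), !is.null(rownames(ld)))
  df <- data.frame(snp_id = rownames(ld),
                   apply(ld, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("snp_id", colnames(ld))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, ids)
  validate_ld(m)
  m
}

#' Validate an LD correlation matrix
#'
#' Checks symmetry (1e-10), unit diagonal, entries in `[-1, 1]` and positive
#' semi-definiteness up to eigenvalue -1e-8.
#'
#' @param ld square numeric matrix.
#' @return the matrix, invisibly.
#' @export
validate_ld <- function(ld) {
  stopifnot(is.matrix(ld), nrow(ld) == ncol(ld))
  if (max(abs(ld - t(ld))) > 1e-10) stop("LD matrix is not symmetric")
  if (max(abs(diag(ld) - 1)) > 1e-10) stop("LD matrix diagonal is not 1")
  if (min(ld) < -1 - 1e-10 || max(ld) > 1 + 1e-10)
    stop("LD entries outside [-1, 1]")
  ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("LD matrix is not positive semi-definite")
  invisible(ld)
}

complement_alleles <- function(a) unname(BASE_COMPLEMENT[a])

is_palindromic <- function(a1, a2) a1 == complement_alleles(a2)

#' Harmonize one variant's statistics between two studies
#'
#' Given the same variant observed in study `a` (the reference, e.g. the
#' exposure) and study `b`, re-expresses `b` on `a`'s effect allele:
#' swapped alleles flip `beta`'s sign and reflect `eaf`; strand flips are
#' resolved by complementing; palindromic variants (A/T or C/G) whose
#' frequency cannot resolve the strand (eaf in `[0.42, 0.58]` or missing) are
#' flagged non-harmonizable, as are irreconcilable allele sets.
#'
#' @param a,b single-row summary-statistics data.frames with equal `snp_id`.
#' @return list with elements `a`, `b` (possibly modified) and `ok` (logical:
#'   `FALSE` when the pair is non-harmonizable).
#' @export
align_alleles <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L, a$snp_id == b$snp_id)
  res <- harmonise_sumstats(a, b)
  b_out <- b
  if (res$ok) {
    for (col in c("effect_allele", "other_allele", "beta", "zscore", "eaf"))
      b_out[[col]] <- res$merged[[paste0(col, "_b")]]
  }
  list(a = a, b = b_out, ok = res$ok)
}

#' Harmonize two summary-statistics tables on shared variants
#'
#' Vectorized harmonization used by the colocalization and MR stages: the
#' tables are merged on `snp_id` and study `b`'s effects are re-expressed on
#' study `a`'s effect alleles under the rules of [align_alleles].
#'
#' @param a,b summary-statistics data.frames.
#' @return list with `merged` (data.frame of shared variants, `_a`/`_b`
#'   suffixed columns, harmonized) restricted to harmonizable variants,
#'   `ok` (logical vector over shared variants before filtering) and
#'   `n_dropped` (non-harmonizable count).
#' @export
harmonise_sumstats <- function(a, b) {
  m <- merge(a, b, by = "snp_id", suffixes = c("_a", "_b"), sort = FALSE)
  if (nrow(m) == 0L) {
    return(list(merged = m, ok = logical(0), n_dropped = 0L))
  }
  ea_a <- m$effect_allele_a; oa_a <- m$other_allele_a
  ea_b <- m$effect_allele_b; oa_b <- m$other_allele_b

  pal_a <- is_palindromic(ea_a, oa_a)

  same <- ea_b == ea_a & oa_b == oa_a
  swapped <- ea_b == oa_a & oa_b == ea_a
  flip_same <- complement_alleles(ea_b) == ea_a & complement_alleles(oa_b) == oa_a
  flip_swap <- complement_alleles(ea_b) == oa_a & complement_alleles(oa_b) == ea_a

  # palindromic variants: strand flip is indistinguishable from an allele
  # swap, so only a clearly informative frequency can orient them
  eaf_ref <- ifelse(is.na(m$eaf_a), m$eaf_b, m$eaf_a)
  ambiguous_freq <- is.na(eaf_ref) | (eaf_ref >= 0.42 & eaf_ref <= 0.58)
  nonharm_pal <- pal_a & ambiguous_freq

  resolvable <- (same | swapped | flip_same | flip_swap) & !nonharm_pal
  # for palindromic-but-informative variants orient by frequency agreement
  pal_use <- pal_a & !ambiguous_freq & (same | swapped | flip_same | flip_swap)
  pal_flip <- pal_use & !is.na(m$eaf_a) & !is.na(m$eaf_b) &
    ((m$eaf_a < 0.5) != (m$eaf_b < 0.5))
  need_sign_flip <- ifelse(pal_use, pal_flip, swapped | flip_swap)

  ok <- resolvable
  m$effect_allele_b <- ea_a
  m$other_allele_b <- oa_a
  m$beta_b <- ifelse(need_sign_flip, -m$beta_b, m$beta_b)
  if ("zscore_b" %in% names(m))
    m$zscore_b <- ifelse(need_sign_flip, -m$zscore_b, m$zscore_b)
  if ("eaf_b" %in% names(m))
    m$eaf_b <- ifelse(need_sign_flip & !is.na(m$eaf_b), 1 - m$eaf_b, m$eaf_b)

  list(merged = m[ok, , drop = FALSE], ok = ok, n_dropped = sum(!ok))
}
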