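#' @title FUSION-style association statistics
#'
#' @description
#' The discovery stage tests an imputed feature level (a weighted combination
#' of cis-SNP effects) against an outcome using only GWAS summary statistics
#' and an LD reference: for weights w over variants with GWAS z-scores z and
#' LD correlation R,
#' \deqn{Z = w' z / \sqrt{w' R w}.}
#' Under the null of no feature-outcome association Z is standard normal.
#'
#' @name xwas
NULL

#' Weight model constructor
#'
#' @param feature_id feature (protein or gene) identifier.
#' @param layer evidence layer tag, e.g. `"plasma_pwas"`, `"blood_twas"`,
#'   `"breast_twas"`.
#' @param snp_ids variant ids (unique).
#' @param weights numeric weights aligned to `snp_ids`, not all zero.
#' @param ld LD correlation matrix covering `snp_ids` (dimnames required).
#' @return list of class `weight_model`.
#' @export
weight_model <- function(feature_id, layer, snp_ids, weights, ld = NULL) {
  stopifnot(length(snp_ids) == length(weights),
            !anyDuplicated(snp_ids), any(weights != 0))
  structure(list(feature_id = feature_id, layer = layer,
                 snp_ids = as.character(snp_ids), weights = as.numeric(weights),
                 ld = ld),
            class = "weight_model")
}

#' Compute the association Z-statistic for one weight model
#'
#' Variants in the model that are absent from the GWAS table are dropped
#' jointly from the weights and the LD matrix (weights are not renormalized,
#' matching FUSION's handling); the count of surviving variants is recorded.
#' GWAS effects are used on the weight model's allele orientation when allele
#' columns are available in both (via [harmonise_sumstats] conventions the
#' GWAS table is assumed pre-aligned to the LD panel, as FUSION requires).
#'
#' @param w `weight_model` (or bare list with the same fields).
#' @param gwas GWAS summary-statistics data.frame.
#' @param ld LD matrix; defaults to `w$ld`.
#' @param outcome outcome label carried into the result.
#' @return one-row data.frame: feature_id, layer, outcome, zscore, pvalue,
#'   n_snps_used (p_fdr is added later by [run_layer]).
#' @export
xwas_z <- function(w, gwas, ld = w$ld, outcome = "outcome") {
  stopifnot(!is.null(ld))
  idx <- match(w$snp_ids, gwas$snp_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no weighted variant found in the GWAS table")
  snps <- w$snp_ids[keep]
  wt <- w$weights[keep]
  z <- gwas$zscore[idx[keep]]
  R <- ld[snps, snps, drop = FALSE]
  wRw <- drop(crossprod(wt, R %*% wt))
  if (wRw <= 1e-12) stop("degenerate predictor variance (w' R w ~ 0)")
  Z <- drop(crossprod(wt, z)) / sqrt(wRw)
  data.frame(feature_id = w$feature_id, layer = w$layer, outcome = outcome,
             zscore = Z, pvalue = 2 * stats::pnorm(-abs(Z)),
             n_snps_used = sum(keep), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` fixing the contract
#' used across the package: input p in `(0, 1]`, step-up adjusted values
#' capped at 1 and never below the input.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the association screen for one evidence layer
#'
#' Computes [xwas_z] for every weight model, collapses duplicate feature ids
#' (e.g. multiple aptamers measuring one protein) to the record with the
#' smallest unadjusted p-value, and applies Benjamini-Hochberg correction
#' across the collapsed set.
#'
#' @param weights list of `weight_model`s (all one layer).
#' @param gwas GWAS summary statistics for the outcome. May be a single
#'   data.frame or a named list keyed by feature_id (per-window tables).
#' @param outcome outcome label.
#' @param alpha FDR threshold for the significance flag.
#' @return data.frame, one row per feature: feature_id, layer, outcome,
#'   zscore, pvalue, p_fdr, n_snps_used, significant. Features whose z could
#'   not be formed (no usable variant) are reported with NA statistics.
#' @export
run_layer <- function(weights, gwas, outcome = "outcome", alpha = 0.05) {
  stopifnot(length(weights) >= 1)
  rows <- lapply(weights, function(w) {
    g <- if (is.data.frame(gwas)) gwas else gwas[[w$feature_id]]
    res <- tryCatch(xwas_z(w, g, outcome = outcome), error = function(e) NULL)
    if (is.null(res)) {
      res <- data.frame(feature_id = w$feature_id, layer = w$layer,
                        outcome = outcome, zscore = NA_real_,
                        pvalue = NA_real_, n_snps_used = NA_integer_,
                        stringsAsFactors = FALSE)
    }
    res
  })
  out <- do.call(rbind, rows)
  # collapse duplicate features (aptamers) to the smallest unadjusted p
  out <- out[order(out$feature_id, out$pvalue, na.last = TRUE), , drop = FALSE]
  out <- out[!duplicated(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out$p_fdr <- NA_real_
  usable <- !is.na(out$pvalue)
  out$p_fdr[usable] <- bh_adjust(out$pvalue[usable])
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}
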