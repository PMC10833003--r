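#' @title Two-sample Mendelian randomization
#'
#' @description
#' The causal stage treats cis-QTL variants as instruments for a feature's
#' level and estimates the feature's effect on the outcome from two sets of
#' summary statistics.  Instruments must be genome-wide significant for the
#' exposure (p < 5e-8, relaxing to 5e-6 when nothing passes) and
#' approximately independent after LD clumping.  With one instrument the
#' Wald ratio `beta_out / beta_exp` is used; with several, the
#' inverse-variance weighted (IVW) estimator, equivalent to weighted least
#' squares of outcome on exposure effects through the origin with weights
#' `1/se_out^2`, plus MR-Egger regression (intercept = directional
#' pleiotropy test), Cochran's Q heterogeneity and Steiger directionality.
#'
#' @name mr
NULL

#' Build an instrument table from harmonized exposure/outcome statistics
#'
#' @param exposure,outcome summary-statistics data.frames restricted to the
#'   selected instruments; harmonized on `snp_id` via [harmonise_sumstats].
#' @return data.frame with columns snp_id, beta_exp, se_exp, p_exp, n_exp,
#'   beta_out, se_out, p_out, n_out.
#' @export
make_instruments <- function(exposure, outcome) {
  h <- harmonise_sumstats(exposure, outcome)
  m <- h$merged
  if (nrow(m) == 0L) return(NULL)
  data.frame(snp_id = m$snp_id,
             beta_exp = m$beta_a, se_exp = m$se_a, p_exp = m$pvalue_a,
             n_exp = m$n_a,
             beta_out = m$beta_b, se_out = m$se_b, p_out = m$pvalue_b,
             n_out = m$n_b, stringsAsFactors = FALSE)
}

#' Select instrument variants from exposure summary statistics
#'
#' @param exposure summary-statistics data.frame.
#' @param p_primary genome-wide threshold (default 5e-8).
#' @param p_fallback relaxed threshold used only when no variant passes the
#'   primary one (default 5e-6).
#' @return subset of `exposure`; zero rows (with attribute
#'   `status = "no-instrument"`) when neither threshold selects anything.
#' @export
select_instruments <- function(exposure, p_primary = 5e-8, p_fallback = 5e-6) {
  stopifnot(nrow(exposure) >= 1)
  sel <- exposure[exposure$pvalue < p_primary, , drop = FALSE]
  if (nrow(sel) == 0L)
    sel <- exposure[exposure$pvalue < p_fallback, , drop = FALSE]
  if (nrow(sel) == 0L) {
    message("select_instruments: no variant below ", p_fallback,
            " (status no-instrument)")
    attr(sel, "status") <- "no-instrument"
  }
  sel
}

#' Greedy LD clumping of selected variants
#'
#' Orders variants by ascending p-value; repeatedly keeps the most
#' significant remaining variant and discards all others within
#' `window_kb` kilobases (same chromosome) whose squared correlation with it
#' exceeds `r2`.
#'
#' @param snps summary-statistics data.frame (must be covered by `ld`).
#' @param ld LD correlation matrix with SNP ids as dimnames.
#' @param r2 squared-correlation threshold (default 0.001).
#' @param window_kb window in kb (default 10000, i.e. 10 Mb).
#' @return the retained subset, in ascending p order.
#' @export
clump <- function(snps, ld, r2 = 0.001, window_kb = 10000) {
  if (nrow(snps) <= 1L) return(snps)
  stopifnot(all(snps$snp_id %in% rownames(ld)))
  ord <- snps[order(snps$pvalue), , drop = FALSE]
  keep <- character(0)
  remaining <- ord
  while (nrow(remaining) > 0L) {
    top <- remaining[1L, ]
    keep <- c(keep, top$snp_id)
    r <- ld[top$snp_id, remaining$snp_id]
    in_window <- remaining$chrom == top$chrom &
      abs(remaining$pos - top$pos) <= window_kb * 1000
    drop <- in_window & (r^2 > r2)
    drop[1L] <- TRUE
    remaining <- remaining[!drop, , drop = FALSE]
  }
  out <- ord[match(keep, ord$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mr_result <- function(method, n_snps, beta, se, feature_id = NA_character_,
                      outcome = NA_character_, q_stat = NA_real_,
                      q_df = NA_integer_, q_p = NA_real_,
                      egger_intercept = NA_real_,
                      egger_intercept_p = NA_real_,
                      steiger_correct_direction = NA, steiger_p = NA_real_) {
  z <- beta / se
  structure(list(feature_id = feature_id, outcome = outcome, method = method,
                 n_snps = as.integer(n_snps), beta = beta, se = se,
                 or_ = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 pvalue = 2 * stats::pnorm(-abs(z)),
                 q_stat = q_stat, q_df = q_df, q_p = q_p,
                 egger_intercept = egger_intercept,
                 egger_intercept_p = egger_intercept_p,
                 steiger_correct_direction = steiger_correct_direction,
                 steiger_p = steiger_p),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s, %d instrument%s): OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              x$or_, x$ci_low, x$ci_high, x$pvalue))
  if (!is.na(x$q_stat))
    cat(sprintf("  Cochran Q = %.3f (df %d, p = %.3g)\n",
                x$q_stat, x$q_df, x$q_p))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_p))
  if (!is.na(x$steiger_correct_direction))
    cat(sprintf("  Steiger direction %s (p = %.3g)\n",
                if (x$steiger_correct_direction) "exposure -> outcome"
                else "suspect (reverse)", x$steiger_p))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(feature_id = x$feature_id, outcome = x$outcome,
             method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             or_ = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue, q_stat = x$q_stat, q_df = x$q_df,
             q_p = x$q_p, egger_intercept = x$egger_intercept,
             egger_intercept_p = x$egger_intercept_p,
             steiger_correct_direction = x$steiger_correct_direction,
             steiger_p = x$steiger_p, stringsAsFactors = FALSE)
}

#' Wald ratio estimator (single instrument)
#'
#' `beta = beta_out / beta_exp`, `se = se_out / |beta_exp|` (first-order
#' delta method, exposure uncertainty ignored).
#'
#' @param inst one-row instrument data.frame.
#' @param ... labels passed to the result.
#' @return `mr_result`.
#' @export
wald_ratio <- function(inst, ...) {
  stopifnot(nrow(inst) == 1L)
  if (abs(inst$beta_exp) < 1e-12) stop("exposure effect is (numerically) zero")
  beta <- inst$beta_out / inst$beta_exp
  se <- inst$se_out / abs(inst$beta_exp)
  st <- steiger(inst)
  mr_result("wald_ratio", 1L, beta, se,
            steiger_correct_direction = st$direction, steiger_p = st$p, ...)
}

#' Inverse-variance weighted estimator
#'
#' Fixed-effect meta-analysis of the per-instrument Wald ratios with weights
#' `beta_exp^2 / se_out^2` (equivalently WLS of `beta_out` on `beta_exp`
#' through the origin, weights `1/se_out^2`).  When Cochran's
#' `Q/(k-1) > 1` the standard error is inflated by `sqrt(Q/(k-1))`
#' (multiplicative random-effects model).
#'
#' @param insts instrument data.frame (>= 2 rows; a single row is accepted
#'   and reduces exactly to the Wald ratio).
#' @param ... labels passed to the result.
#' @return `mr_result` with Q statistics filled in.
#' @export
ivw <- function(insts, ...) {
  k <- nrow(insts)
  stopifnot(k >= 1)
  ratios <- insts$beta_out / insts$beta_exp
  w <- insts$beta_exp^2 / insts$se_out^2
  beta <- sum(w * ratios) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratios - beta)^2)
  q_df <- k - 1L
  infl <- if (q_df >= 1L && Q / q_df > 1) sqrt(Q / q_df) else 1
  se <- se_fixed * infl
  q_p <- if (q_df >= 1L) stats::pchisq(Q, q_df, lower.tail = FALSE) else NA_real_
  st <- steiger(insts)
  mr_result("ivw", k, beta, se, q_stat = Q, q_df = q_df, q_p = q_p,
            steiger_correct_direction = st$direction, steiger_p = st$p, ...)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with an
#' intercept, weights `1/se_out^2`, after orienting every exposure effect
#' positive (flipping each instrument pair jointly).  The slope is the
#' causal estimate; a nonzero intercept indicates directional pleiotropy.
#' The residual scale is floored at 1 (standard errors are never deflated
#' below their fixed-effect value); p-values use the t distribution with
#' k - 2 degrees of freedom.
#'
#' @param insts instrument data.frame (>= 3 rows).
#' @param ... labels passed to the result.
#' @return `mr_result` with `egger_intercept` fields filled.
#' @export
mr_egger <- function(insts, ...) {
  k <- nrow(insts)
  stopifnot(k >= 3)
  flip <- sign(insts$beta_exp)
  flip[flip == 0] <- 1
  bx <- insts$beta_exp * flip
  by <- insts$beta_out * flip
  wts <- 1 / insts$se_out^2

  X <- cbind(1, bx)
  XtWX <- crossprod(X, wts * X)
  XtWy <- crossprod(X, wts * by)
  coefs <- unname(drop(solve(XtWX, XtWy)))
  resid <- by - drop(X %*% coefs)
  sigma2 <- sum(wts * resid^2) / (k - 2)
  vc <- solve(XtWX) * max(sigma2, 1)
  se_int <- sqrt(vc[1, 1]); se_slope <- sqrt(vc[2, 2])
  p_int <- 2 * stats::pt(-abs(coefs[1] / se_int), df = k - 2)
  st <- steiger(insts)
  res <- mr_result("egger", k, coefs[2], se_slope,
                   egger_intercept = coefs[1], egger_intercept_p = p_int,
                   steiger_correct_direction = st$direction, steiger_p = st$p,
                   ...)
  res$pvalue <- 2 * stats::pt(-abs(coefs[2] / se_slope), df = k - 2)
  res
}

#' Steiger directionality test
#'
#' Per instrument the variance explained on each side is
#' `r^2 = z^2 / (z^2 + n - 2)`; the per-side totals (summed over the
#' approximately independent post-clumping instruments) are compared.  The
#' causal direction is "exposure to outcome" when the instruments explain
#' more variance in the exposure than in the outcome.  The p-value is a
#' two-sided Z-test on the difference of the Fisher-transformed aggregate
#' correlations with standard error `sqrt(1/(n_exp-3) + 1/(n_out-3))`.
#'
#' @param insts instrument data.frame with `n_exp`, `n_out` columns.
#' @return list with `direction` (logical), `p`, `r2_exp`, `r2_out`.
#' @export
steiger <- function(insts) {
  stopifnot(nrow(insts) >= 1)
  z_exp <- insts$beta_exp / insts$se_exp
  z_out <- insts$beta_out / insts$se_out
  r2_exp <- sum(z_exp^2 / (z_exp^2 + insts$n_exp - 2))
  r2_out <- sum(z_out^2 / (z_out^2 + insts$n_out - 2))
  r_exp <- sqrt(min(r2_exp, 1 - 1e-12))
  r_out <- sqrt(min(r2_out, 1 - 1e-12))
  n_exp <- mean(insts$n_exp)
  n_out <- mean(insts$n_out)
  se <- sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  z <- (atanh(r_exp) - atanh(r_out)) / se
  list(direction = r2_exp > r2_out, p = 2 * stats::pnorm(-abs(z)),
       r2_exp = r2_exp, r2_out = r2_out)
}

#' Tier-gated MR for one feature
#'
#' Refuses features outside the Strong/Moderate tiers or with an
#' inconsistent cross-layer direction.  Otherwise: instrument selection
#' (5e-8 with 5e-6 fallback) -> LD clumping -> harmonization against the
#' outcome -> Steiger filtering (instruments explaining more outcome than
#' exposure variance are dropped) -> Wald ratio (1 instrument) or IVW
#' (several; MR-Egger added when k >= 3).
#'
#' @param feature tier record (row of [score_feature] output).
#' @param exposure QTL summary statistics for the feature (exposure study).
#' @param outcome GWAS summary statistics (outcome study).
#' @param ld LD matrix covering the exposure variants.
#' @param p_primary,p_fallback,clump_r2,clump_window_kb thresholds.
#' @param steiger_mode `"filter"` (drop wrong-direction instruments,
#'   default) or `"report"` (keep all, report the aggregate test only).
#' @return `mr_result`, or a list with `status = "not-estimable"` /
#'   `status = "gated"` when no estimate is produced.
#' @export
run_mr <- function(feature, exposure, outcome, ld,
                   p_primary = 5e-8, p_fallback = 5e-6,
                   clump_r2 = 0.001, clump_window_kb = 10000,
                   steiger_mode = c("filter", "report")) {
  steiger_mode <- match.arg(steiger_mode)
  if (!feature$tier %in% c("Strong", "Moderate") ||
      isFALSE(feature$direction_consistent)) {
    return(list(status = "gated", feature_id = feature$feature_id,
                reason = sprintf("tier %s%s not eligible for causal follow-up",
                                 feature$tier,
                                 if (isFALSE(feature$direction_consistent))
                                   " (direction-inconsistent)" else "")))
  }
  sel <- select_instruments(exposure, p_primary, p_fallback)
  if (nrow(sel) == 0L)
    return(list(status = "not-estimable", feature_id = feature$feature_id,
                reason = "no instrument passes the selection thresholds"))
  sel <- clump(sel, ld, r2 = clump_r2, window_kb = clump_window_kb)
  insts <- make_instruments(sel, outcome)
  if (is.null(insts))
    return(list(status = "not-estimable", feature_id = feature$feature_id,
                reason = "no instrument harmonizable against the outcome"))
  if (steiger_mode == "filter") {
    keep <- vapply(seq_len(nrow(insts)),
                   function(j) steiger(insts[j, ])$direction, logical(1))
    keep[is.na(keep)] <- TRUE   # unknown sample sizes: cannot filter
    insts <- insts[keep, , drop = FALSE]
    if (nrow(insts) == 0L)
      return(list(status = "not-estimable", feature_id = feature$feature_id,
                  reason = "all instruments removed by Steiger filtering"))
  }
  labels <- list(feature_id = feature$feature_id, outcome = feature$outcome)
  res <- if (nrow(insts) == 1L) {
    do.call(wald_ratio, c(list(insts), labels))
  } else {
    do.call(ivw, c(list(insts), labels))
  }
  if (nrow(insts) >= 3L) {
    egger <- do.call(mr_egger, c(list(insts), labels))
    res$egger_intercept <- egger$egger_intercept
    res$egger_intercept_p <- egger$egger_intercept_p
  }
  res
}

#' Replication call against external-cohort MR results
#'
#' @param discovery `mr_result` from the discovery cohort.
#' @param validations list of `mr_result`s from validation cohorts.
#' @return `"replicated"` (>= 1 validation with the same effect sign and
#'   p < 0.05), `"trend"` (same sign only), else `"not-replicated"`.
#' @export
mr_replicate <- function(discovery, validations) {
  stopifnot(length(validations) >= 1)
  signs <- vapply(validations, function(v) sign(v$beta), numeric(1))
  ps <- vapply(validations, function(v) v$pvalue, numeric(1))
  same <- signs == sign(discovery$beta)
  if (any(same & ps < 0.05)) "replicated"
  else if (any(same)) "trend"
  else "not-replicated"
}
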