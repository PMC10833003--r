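#' @title Bayesian colocalization via Wakefield approximate Bayes factors
#'
#' @description
#' For each variant the evidence of association with a trait is summarised by
#' Wakefield's approximate Bayes factor against the null: with `V = se^2`,
#' prior effect variance `W = prior_sd^2` and `z = beta/se`,
#' \deqn{\log ABF = \tfrac12\left[\log\frac{V}{V+W} + z^2\,\frac{W}{V+W}\right].}
#' Assuming at most one causal variant per trait in the window, the five
#' hypotheses (H0 neither trait associated; H1/H2 only trait 1/2; H3 both,
#' distinct variants; H4 both, one shared variant) have unnormalised supports
#' built from the per-variant ABFs and the per-variant prior probabilities
#' p1, p2, p12; posteriors follow by normalisation.  All sums are carried in
#' log space (log-sum-exp), so windows with very strong signals do not
#' overflow.
#'
#' @name coloc
NULL

logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows or is negative (the caller clamps H3 support at zero)
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Log approximate Bayes factor for one variant
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param prior_sd prior SD of the true effect (> 0); 0.15 is the
#'   conventional choice for quantitative traits, 0.2 (log-OR scale) for
#'   binary traits.
#' @return log ABF (vectorised over the inputs).
#' @export
log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd > 0))
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(V / (V + W)) + z2 * W / (V + W))
}

#' Colocalize two traits over a shared cis window
#'
#' Intersects the two summary-statistics tables on `snp_id` (harmonizing
#' trait 2 onto trait 1's effect alleles) and enumerates the five-hypothesis
#' posterior under the single-causal-variant assumption.
#'
#' @param stats1,stats2 summary-statistics data.frames (trait 1 is
#'   conventionally the QTL, trait 2 the outcome GWAS).
#' @param p1,p2 per-variant prior probability of association with trait 1 /
#'   trait 2 only.
#' @param p12 per-variant prior probability of association with both.
#' @param sd1,sd2 prior effect SDs for the two traits.
#' @param feature_id,layer,outcome labels carried into the result.
#' @return object of class `coloc_result`: list with `pph0 ... pph4`,
#'   `n_snps`, the per-variant log-ABF vectors `labf1`, `labf2`, and labels.
#' @export
colocalize <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       sd1 = 0.15, sd2 = 0.2, feature_id = NA_character_,
                       layer = NA_character_, outcome = NA_character_) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1)
  h <- harmonise_sumstats(stats1, stats2)
  m <- h$merged
  if (nrow(m) == 0L) stop("no shared harmonizable variant between the traits")

  labf1 <- log_abf(m$beta_a, m$se_a, sd1)
  labf2 <- log_abf(m$beta_b, m$se_b, sd2)

  l1 <- logsumexp(labf1)                 # log sum_j ABF1_j
  l2 <- logsumexp(labf2)                 # log sum_j ABF2_j
  l12 <- logsumexp(labf1 + labf2)        # log sum_j ABF1_j ABF2_j

  lS0 <- 0
  lS1 <- log(p1) + l1
  lS2 <- log(p2) + l2
  # sum over ordered distinct pairs = (sum_j)(sum_k) - sum_{j=k}; clamped >= 0
  lS3 <- log(p1) + log(p2) + logdiffexp(l1 + l2, l12)
  lS4 <- log(p12) + l12

  ls <- c(lS0, lS1, lS2, lS3, lS4)
  post <- exp(ls - logsumexp(ls))
  post <- post / sum(post)

  structure(list(feature_id = feature_id, layer = layer, outcome = outcome,
                 pph0 = post[1], pph1 = post[2], pph2 = post[3],
                 pph3 = post[4], pph4 = post[5],
                 n_snps = nrow(m), labf1 = labf1, labf2 = labf2,
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_snps, "shared variants\n")
  if (!is.na(x$feature_id))
    cat("  feature:", x$feature_id,
        if (!is.na(x$layer)) paste0("(", x$layer, ")") else "", "\n")
  p <- c(H0 = x$pph0, H1 = x$pph1, H2 = x$pph2, H3 = x$pph3, H4 = x$pph4)
  print(round(p, 4))
  invisible(x)
}

#' Shared-causal-variant evidence flag
#'
#' @param res `coloc_result` (or anything with a `pph4` element).
#' @param threshold posterior cut; the tier-scoring rule uses 0.75, strict.
#' @return `TRUE` iff `pph4 > threshold`.
#' @export
coloc_evidence_flag <- function(res, threshold = 0.75) {
  stopifnot(is.numeric(res$pph4), res$pph4 >= 0, res$pph4 <= 1)
  res$pph4 > threshold
}
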