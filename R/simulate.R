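#' @title Synthetic summary-statistics generators
#'
#' @description
#' Generators for LD panels, cis-QTL weight models, GWAS/QTL summary
#' statistics, colocalization scenarios and MR instrument sets with known
#' ground truth.  All generators are pure functions of their parameters and a
#' seed, so every downstream calibration is reproducible.  The marginal
#' Z-score model is the standard multivariate-normal approximation for
#' summary statistics under LD: for a feature with predictor weights w over a
#' cis window with correlation matrix R, a causal feature-level effect alpha
#' (per SD, log-OR scale for binary outcomes) induces
#' `z = alpha * sqrt(n) * R w / sqrt(w' R w) + eps`, `eps ~ MVN(0, R)`,
#' with `beta = z / sqrt(n)` and `se = 1 / sqrt(n)` (effects in phenotypic SD
#' units).  Under `alpha = 0` the implied association Z-statistic of
#' [xwas_z] is standard normal.
#'
#' @name synthdata
NULL

# non-palindromic allele pairs used for simulated variants
ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulate an AR(1) LD correlation matrix
#'
#' `r[i, j] = rho^|i - j|`, the first-order autoregressive structure commonly
#' used as an analytically tractable stand-in for local LD decay.
#'
#' @param m number of variants (>= 1).
#' @param rho adjacent-variant correlation in `[0, 1)`.
#' @param snp_ids optional ids; default `snp_001 ...`.
#' @return m x m correlation matrix with SNP ids as dimnames.
#' @export
simulate_ld <- function(m, rho = 0.6, snp_ids = NULL) {
  stopifnot(m >= 1, rho >= 0, rho < 1)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%03d", seq_len(m))
  r <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

# one draw from MVN(0, R) via the (upper) Cholesky factor
rmvn_chol <- function(chol_R) {
  drop(crossprod(chol_R, stats::rnorm(nrow(chol_R))))
}

# variant annotation scaffold for a simulated cis window
sim_variant_frame <- function(m, chrom = "1", start_pos = 1e6, spacing = 2000L,
                              snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%03d", seq_len(m))
  pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), m, replace = TRUE), ,
                       drop = FALSE]
  data.frame(snp_id = snp_ids,
             chrom = chrom,
             pos = as.integer(start_pos + (seq_len(m) - 1L) * spacing),
             effect_allele = pair[, 1],
             other_allele = pair[, 2],
             eaf = round(stats::runif(m, 0.1, 0.9), 4),
             stringsAsFactors = FALSE)
}

# turn a z-vector into a full summary-statistics table at sample size n
zs_to_sumstats <- function(variants, z, n, ncase = NA, ncontrol = NA) {
  se <- rep(1 / sqrt(n), length(z))
  df <- variants
  df$beta <- z * se
  df$se <- se
  df$pvalue <- 2 * stats::pnorm(-abs(z))
  df$zscore <- z
  df$n <- n
  df$ncase <- ncase
  df$ncontrol <- ncontrol
  df[SUMSTATS_COLS]
}

#' Simulate marginal GWAS summary statistics induced by a feature-level effect
#'
#' @param ld LD correlation matrix of the cis window.
#' @param w predictor weight vector aligned to `ld`.
#' @param alpha true causal effect of the (standardised) feature on the
#'   outcome; 0 gives the null.
#' @param n GWAS sample size (>= 50).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param noise set `FALSE` to suppress the MVN noise term (for exactness
#'   checks against the closed form).
#' @param variants optional variant annotation frame (from
#'   `sim_variant_frame`); generated when missing.
#' @param ncase,ncontrol optional binary-outcome counts carried through.
#' @return summary-statistics data.frame (see [sumstats]).
#' @export
simulate_feature_gwas <- function(ld, w, alpha, n, seed = NULL, noise = TRUE,
                                  variants = NULL, ncase = NA, ncontrol = NA) {
  stopifnot(length(w) == nrow(ld), n >= 50)
  if (!is.null(seed)) set.seed(seed)
  wRw <- drop(crossprod(w, ld %*% w))
  if (wRw <= 0) stop("w' R w must be positive")
  mu <- alpha * sqrt(n) * drop(ld %*% w) / sqrt(wRw)
  z <- if (noise) mu + rmvn_chol(chol(ld)) else mu
  if (is.null(variants)) variants <- sim_variant_frame(nrow(ld),
                                                       snp_ids = rownames(ld))
  zs_to_sumstats(variants, z, n, ncase, ncontrol)
}

#' Simulate a colocalization scenario pair
#'
#' Generates summary statistics for two traits over a shared cis window under
#' one of the five colocalization hypotheses: `H0` both null, `H1`/`H2` one
#' trait has a causal variant, `H3` the two traits have distinct causal
#' variants in low LD (r^2 < 0.2), `H4` a shared causal variant.  Per-trait
#' non-centrality at the causal variant is `effect * sqrt(n)`, so the default
#' `effect` puts the causal variant's expected |z| well above 6.
#'
#' @param scenario one of `"H0" ... "H4"`.
#' @param m window size (>= 3).
#' @param n1,n2 per-trait sample sizes.
#' @param rho AR(1) LD parameter.
#' @param effect per-allele effect in SD units at the causal variant.
#' @param seed RNG seed.
#' @return list with `trait1`, `trait2` (summary-statistics data.frames) and
#'   `truth` (list: scenario, causal index per trait).
#' @export
simulate_coloc_pair <- function(scenario = c("H0", "H1", "H2", "H3", "H4"),
                                m = 50, n1 = 10000, n2 = 10000, rho = 0.6,
                                effect = 0.08, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(m >= 3)
  set.seed(seed)
  ld <- simulate_ld(m, rho)
  variants <- sim_variant_frame(m, snp_ids = rownames(ld))

  c1 <- c2 <- NA_integer_
  mid <- as.integer(ceiling(m / 2))
  if (scenario %in% c("H1", "H4")) c1 <- mid
  if (scenario %in% c("H2", "H4")) c2 <- mid
  if (scenario == "H3") {
    # need two causal variants with r^2 < 0.2
    lo <- as.integer(ceiling(m / 4)); hi <- as.integer(ceiling(3 * m / 4))
    if (ld[lo, hi]^2 >= 0.2) {
      lo <- 1L; hi <- m
      if (ld[lo, hi]^2 >= 0.2)
        stop("no variant pair with r^2 < 0.2; increase m or decrease rho")
    }
    c1 <- lo; c2 <- hi
  }

  mu_for <- function(causal, eff, n) {
    if (is.na(causal)) return(rep(0, m))
    eff * sqrt(n) * ld[, causal]
  }
  chR <- chol(ld)
  z1 <- mu_for(c1, effect, n1) + rmvn_chol(chR)
  z2 <- mu_for(c2, effect, n2) + rmvn_chol(chR)

  list(trait1 = zs_to_sumstats(variants, z1, n1),
       trait2 = zs_to_sumstats(variants, z2, n2),
       truth = list(scenario = scenario, causal1 = c1, causal2 = c2))
}

#' Simulate a harmonized two-sample MR instrument set with known causal effect
#'
#' Independent instruments are drawn with true exposure effects
#' `N(0, 0.15^2)`; observed exposure estimates carry sampling noise at
#' `se = 1/sqrt(n_exp)` and are rejection-sampled to be genome-wide
#' significant (p < 5e-8), emulating instrument selection.  Outcome effects
#' follow `alpha * betaX + pleiotropy + noise` with
#' `pleiotropy ~ N(0, pleiotropy_sd^2)` and noise at `se = 1/sqrt(n_out)`.
#'
#' @param k number of instruments (>= 1).
#' @param alpha true causal effect of exposure on outcome.
#' @param pleiotropy_sd SD of per-instrument directional-free pleiotropy.
#' @param n_exp,n_out sample sizes of the exposure and outcome studies.
#' @param seed RNG seed.
#' @return list with `instruments` (data.frame: snp_id, beta_exp, se_exp,
#'   p_exp, n_exp, beta_out, se_out, p_out, n_out) and `truth`.
#' @export
simulate_mr_set <- function(k, alpha, pleiotropy_sd = 0, n_exp = 10000,
                            n_out = 50000, seed = 1) {
  stopifnot(k >= 1)
  set.seed(seed)
  se_exp <- 1 / sqrt(n_exp)
  se_out <- 1 / sqrt(n_out)
  z_thresh <- stats::qnorm(1 - 5e-8 / 2)

  beta_true <- numeric(k)
  beta_exp <- numeric(k)
  for (j in seq_len(k)) {
    repeat {
      b <- stats::rnorm(1, 0, 0.15)
      bhat <- b + stats::rnorm(1, 0, se_exp)
      if (abs(bhat) / se_exp > z_thresh) { beta_true[j] <- b; beta_exp[j] <- bhat; break }
    }
  }
  pleio <- if (pleiotropy_sd > 0) stats::rnorm(k, 0, pleiotropy_sd) else numeric(k)
  beta_out <- alpha * beta_true + pleio + stats::rnorm(k, 0, se_out)

  instruments <- data.frame(
    snp_id = sprintf("iv_%03d", seq_len(k)),
    beta_exp = beta_exp, se_exp = se_exp,
    p_exp = 2 * stats::pnorm(-abs(beta_exp) / se_exp), n_exp = n_exp,
    beta_out = beta_out, se_out = se_out,
    p_out = 2 * stats::pnorm(-abs(beta_out) / se_out), n_out = n_out,
    stringsAsFactors = FALSE)
  list(instruments = instruments,
       truth = list(alpha = alpha, pleiotropy_sd = pleiotropy_sd,
                    beta_true = beta_true, seed = seed))
}

#' Simulate a full multi-layer study with known ground truth
#'
#' Builds the input bundle the pipeline consumes: per feature a cis LD block,
#' per evidence layer a sparse weight model (single strong causal cis variant)
#' and QTL summary statistics, and per outcome GWAS summary statistics over
#' each feature's window.  Causal features transmit their QTL variant's
#' signal to the outcome (`alpha != 0`), producing a shared-variant
#' (colocalizing) GWAS peak; null features have a QTL signal but a null GWAS
#' window.
#'
#' @param n_features number of features.
#' @param n_causal number of features with a true causal effect on the
#'   outcome (the first `n_causal` features).
#' @param layers character vector of layer names.
#' @param outcomes character vector of outcome names.
#' @param m variants per cis window.
#' @param rho AR(1) LD parameter.
#' @param n_gwas outcome GWAS sample size.
#' @param n_qtl QTL study sample size.
#' @param alpha causal feature-level effect for causal features.
#' @param lambda_qtl expected |z| of the causal cis-QTL variant.
#' @param seed RNG seed.
#' @return object of class `ptmr_study`: list with `features` (per-feature
#'   ld, per-layer weights and qtl stats), `gwas` (per outcome, per feature),
#'   `truth` data.frame, and the generating parameters.
#' @export
simulate_study <- function(n_features = 20, n_causal = 2,
                           layers = c("plasma_pwas", "blood_twas", "breast_twas"),
                           outcomes = "overall", m = 25, rho = 0.6,
                           n_gwas = 50000, n_qtl = 7000, alpha = 0.05,
                           lambda_qtl = 12, seed = 1) {
  stopifnot(n_causal <= n_features)
  set.seed(seed)
  feature_ids <- sprintf("FEAT%02d", seq_len(n_features))
  causal <- seq_len(n_features) <= n_causal

  features <- vector("list", n_features)
  names(features) <- feature_ids
  gwas <- lapply(outcomes, function(o) stats::setNames(vector("list", n_features),
                                                       feature_ids))
  names(gwas) <- outcomes

  for (f in seq_len(n_features)) {
    chrom <- as.character(1 + (f - 1) %% 22)
    ids <- sprintf("%s_snp_%03d", feature_ids[f], seq_len(m))
    ld <- simulate_ld(m, rho, snp_ids = ids)
    variants <- sim_variant_frame(m, chrom = chrom,
                                  start_pos = 1e6 + f * 5e6, snp_ids = ids)
    chR <- chol(ld)
    causal_idx <- as.integer(ceiling(m / 2))
    w <- numeric(m); w[causal_idx] <- 1

    layer_list <- lapply(layers, function(l) {
      zq <- lambda_qtl * ld[, causal_idx] + rmvn_chol(chR)
      list(weights = list(feature_id = feature_ids[f], layer = l,
                          snp_ids = ids, weights = w),
           qtl = zs_to_sumstats(variants, zq, n_qtl))
    })
    names(layer_list) <- layers
    features[[f]] <- list(feature_id = feature_ids[f], ld = ld,
                          variants = variants, causal_idx = causal_idx,
                          layers = layer_list)

    for (o in outcomes) {
      a <- if (causal[f]) alpha else 0
      mu <- a * sqrt(n_gwas) * ld[, causal_idx]
      z <- mu + rmvn_chol(chR)
      gwas[[o]][[f]] <- zs_to_sumstats(variants, z, n_gwas,
                                       ncase = round(n_gwas / 2),
                                       ncontrol = round(n_gwas / 2))
    }
  }

  structure(list(features = features, gwas = gwas,
                 truth = data.frame(feature_id = feature_ids, causal = causal,
                                    alpha = ifelse(causal, alpha, 0),
                                    stringsAsFactors = FALSE),
                 params = list(n_features = n_features, n_causal = n_causal,
                               layers = layers, outcomes = outcomes, m = m,
                               rho = rho, n_gwas = n_gwas, n_qtl = n_qtl,
                               alpha = alpha, lambda_qtl = lambda_qtl,
                               seed = seed)),
            class = "ptmr_study")
}

#' @export
print.ptmr_study <- function(x, ...) {
  p <- x$params
  cat("Synthetic summary-statistics study\n")
  cat(sprintf("  %d features (%d causal), %d-SNP cis windows, AR(1) rho = %g\n",
              p$n_features, p$n_causal, p$m, p$rho))
  cat(sprintf("  layers: %s | outcomes: %s | seed %d\n",
              paste(p$layers, collapse = ", "),
              paste(p$outcomes, collapse = ", "), p$seed))
  invisible(x)
}
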