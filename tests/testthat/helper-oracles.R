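# Independent oracles and small fixture builders used across the suite.

# Build a summary-statistics frame from a z vector (shared allele
# orientation so harmonization is the identity).
zframe <- function(z, n = 10000, snp_ids = sprintf("s%02d", seq_along(z)),
                   chrom = "1", pos0 = 1e6) {
  se <- 1 / sqrt(n)
  data.frame(snp_id = snp_ids, chrom = chrom,
             pos = as.integer(pos0 + seq_along(z) * 1000),
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = z * se, se = se, pvalue = 2 * pnorm(-abs(z)),
             zscore = z, n = n, ncase = NA, ncontrol = NA,
             stringsAsFactors = FALSE)
}

# Wakefield ABF via the marginal-likelihood density ratio — an independent
# route to the same quantity as ptmr::log_abf's closed form.
oracle_abf <- function(beta, se, prior_sd) {
  dnorm(beta, 0, sqrt(se^2 + prior_sd^2)) / dnorm(beta, 0, se)
}

# Exhaustive configuration enumeration of the five-hypothesis posterior
# (1 + m + m + m(m-1) + m configurations), linear space; valid for the
# moderate |z| used in tests.
oracle_coloc <- function(beta1, se1, beta2, se2,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd1 = 0.15, sd2 = 0.2) {
  m <- length(beta1)
  abf1 <- oracle_abf(beta1, se1, sd1)
  abf2 <- oracle_abf(beta2, se2, sd2)
  s0 <- 1
  s1 <- sum(p1 * abf1)
  s2 <- sum(p2 * abf2)
  s3 <- 0
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (j != k) s3 <- s3 + p1 * p2 * abf1[j] * abf2[k]
  }
  s4 <- sum(p12 * abf1 * abf2)
  s <- c(s0, s1, s2, s3, s4)
  s / sum(s)
}

# Weighted least squares of beta_out on beta_exp through the origin with
# weights 1/se_out^2, via lm(); multiplicative random-effects se floors the
# residual scale at 1.
oracle_ivw <- function(insts) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = insts,
            weights = 1 / insts$se_out^2)
  sm <- summary(fit)
  sigma <- sm$sigma
  se_fixed <- sm$coefficients[1, 2] / sigma
  k <- nrow(insts)
  list(beta = unname(coef(fit)[1]),
       se = se_fixed * max(1, sigma),
       q = sigma^2 * (k - 1))
}

# Generic weighted regression with intercept via lm(), exposure effects
# oriented positive; same residual-scale floor; t reference with k-2 df.
oracle_egger <- function(insts) {
  flip <- ifelse(insts$beta_exp < 0, -1, 1)
  d <- data.frame(bx = insts$beta_exp * flip, by = insts$beta_out * flip)
  fit <- lm(by ~ bx, data = d, weights = 1 / insts$se_out^2)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- max(1, sigma) / sigma
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = sm$coefficients[1, 2] * infl,
       se_slope = sm$coefficients[2, 2] * infl)
}

# Random instrument frame for estimator-equivalence checks.
random_instruments <- function(k, seed) {
  set.seed(seed)
  data.frame(snp_id = sprintf("iv%02d", seq_len(k)),
             beta_exp = rnorm(k, 0, 0.2) + sample(c(-0.1, 0.1), k, TRUE),
             se_exp = runif(k, 0.005, 0.02),
             p_exp = NA, n_exp = 10000,
             beta_out = rnorm(k, 0, 0.05),
             se_out = runif(k, 0.003, 0.01),
             p_out = NA, n_out = 50000,
             stringsAsFactors = FALSE)
}

# One-variant summary-stats row for harmonization tests.
snp_row <- function(snp_id = "rs1", ea, oa, beta = 0.1, se = 0.05,
                    eaf = NA, chrom = "1", pos = 100) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = 2 * pnorm(-abs(beta / se)),
             zscore = beta / se, n = 1000, ncase = NA, ncontrol = NA,
             stringsAsFactors = FALSE)
}
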