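test_that("instrument selection applies the primary and fallback thresholds", {
  ex <- zframe(c(6.5, 5.4), n = 10000)  # p ~ 8e-11, 6.7e-8
  sel <- select_instruments(ex)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$zscore, 6.5)
  ex2 <- zframe(c(5.4, 4.9), n = 10000)  # both between 5e-8 and 5e-6
  expect_equal(nrow(select_instruments(ex2)), 2)
  ex3 <- zframe(2.5, n = 10000)
  expect_message(sel3 <- select_instruments(ex3), "no-instrument")
  expect_equal(nrow(sel3), 0)
  expect_equal(attr(sel3, "status"), "no-instrument")
})

test_that("clumping keeps the best variant and greedily prunes by r2", {
  ld <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2,
               dimnames = list(c("s1", "s2"), c("s1", "s2")))
  snps <- zframe(c(6.5, 5.8), snp_ids = c("s1", "s2"))
  snps$pvalue <- c(1e-10, 1e-8)
  expect_equal(clump(snps, ld)$snp_id, "s1")

  ld2 <- ld; ld2[1, 2] <- ld2[2, 1] <- sqrt(0.0005)
  expect_equal(nrow(clump(snps, ld2)), 2)

  # chain A-B r2=0.5, B-C r2=0.5, A-C r2=0: greedy keeps A and C
  r <- sqrt(0.5)
  ld3 <- diag(3); ld3[1, 2] <- ld3[2, 1] <- r; ld3[2, 3] <- ld3[3, 2] <- r
  dimnames(ld3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  snps3 <- zframe(c(7, 6.5, 6), snp_ids = c("A", "B", "C"))
  snps3$pvalue <- c(1e-12, 1e-10, 1e-9)
  expect_equal(sort(clump(snps3, ld3)$snp_id), c("A", "C"))

  # variants outside the window survive regardless of r2
  snps_far <- snps
  snps_far$pos <- c(1e6, 1e6 + 2e7)  # 20 Mb apart
  expect_equal(nrow(clump(snps_far, ld, window_kb = 10000)), 2)
})

test_that("wald_ratio matches hand calculations", {
  i1 <- data.frame(snp_id = "s", beta_exp = 1, se_exp = 0.1, p_exp = NA,
                   n_exp = 1000, beta_out = 0.2, se_out = 0.05, p_out = NA,
                   n_out = 1000)
  r <- wald_ratio(i1)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.05)
  expect_equal(r$or_, exp(0.2), tolerance = 1e-10)
  expect_equal(r$ci_low, exp(0.2 - 1.96 * 0.05), tolerance = 1e-10)
  i2 <- i1; i2$beta_exp <- -0.5; i2$beta_out <- 0.1
  r2 <- wald_ratio(i2)
  expect_equal(r2$beta, -0.2)
  expect_equal(r2$se, 0.1)
  i3 <- i1; i3$beta_exp <- 0
  expect_error(wald_ratio(i3), "zero")
})

test_that("ivw equals the WLS-through-origin oracle and the Wald ratio at k=1", {
  for (seed in 1:40) {
    insts <- random_instruments(sample(2:8, 1), seed)
    r <- ivw(insts)
    o <- oracle_ivw(insts)
    expect_equal(r$beta, o$beta, tolerance = 1e-10)
    expect_equal(r$se, o$se, tolerance = 1e-10)
    expect_equal(r$q_stat, o$q, tolerance = 1e-10)
    expect_equal(r$q_df, nrow(insts) - 1L)
  }
  # two identical instruments: beta is the common ratio, Q = 0
  insts <- random_instruments(1, 99)
  two <- rbind(insts, insts)
  r2 <- ivw(two)
  expect_equal(r2$beta, insts$beta_out / insts$beta_exp, tolerance = 1e-12)
  expect_equal(r2$q_stat, 0, tolerance = 1e-20)
  # single instrument reduces exactly to the Wald ratio
  r1 <- ivw(insts)
  w1 <- wald_ratio(insts)
  expect_equal(r1$beta, w1$beta, tolerance = 1e-12)
  expect_equal(r1$se, w1$se, tolerance = 1e-12)
})

test_that("mr_egger equals the generic weighted-regression oracle", {
  for (seed in 41:70) {
    insts <- random_instruments(sample(3:10, 1), seed)
    r <- mr_egger(insts)
    o <- oracle_egger(insts)
    expect_equal(r$beta, o$slope, tolerance = 1e-10)
    expect_equal(r$se, o$se_slope, tolerance = 1e-10)
    expect_equal(r$egger_intercept, o$intercept, tolerance = 1e-10)
  }
  # exact line through the origin: slope recovered, intercept 0
  insts <- random_instruments(5, 71)
  insts$beta_out <- 0.3 * insts$beta_exp
  r <- mr_egger(insts)
  expect_equal(r$beta, 0.3, tolerance = 1e-10)
  expect_equal(r$egger_intercept, 0, tolerance = 1e-10)
  # pure intercept (after positive orientation of exposure effects)
  insts2 <- random_instruments(5, 72)
  insts2$beta_out <- 0.1 * sign(insts2$beta_exp)
  r2 <- mr_egger(insts2)
  expect_equal(r2$beta, 0, tolerance = 1e-10)
  expect_equal(r2$egger_intercept, 0.1, tolerance = 1e-10)
  expect_error(mr_egger(random_instruments(2, 73)))
})

test_that("steiger compares variance explained and is symmetric under ties", {
  i <- data.frame(snp_id = "s", beta_exp = 30, se_exp = 1, p_exp = NA,
                  n_exp = 1000, beta_out = 3, se_out = 1, p_out = NA,
                  n_out = 1000)
  s <- steiger(i)
  expect_true(s$direction)
  # hand values: z_exp=10, z_out=2, n=1000 each
  i2 <- data.frame(snp_id = "s", beta_exp = 10, se_exp = 1, p_exp = NA,
                   n_exp = 1000, beta_out = 2, se_out = 1, p_out = NA,
                   n_out = 1000)
  s2 <- steiger(i2)
  expect_equal(s2$r2_exp, 100 / (100 + 998), tolerance = 1e-10)
  expect_equal(s2$r2_out, 4 / (4 + 998), tolerance = 1e-10)
  expect_equal(round(s2$r2_exp, 4), 0.0911)
  expect_equal(round(s2$r2_out, 4), 0.0040)
  expect_true(s2$direction)
  # symmetric z and n: no direction, p = 1
  i3 <- i2; i3$beta_out <- 10
  s3 <- steiger(i3)
  expect_false(s3$direction)
  expect_equal(s3$p, 1, tolerance = 1e-12)
})

test_that("MR estimates are sign-equivariant in the outcome", {
  insts <- random_instruments(6, 80)
  r <- ivw(insts)
  neg <- insts; neg$beta_out <- -neg$beta_out
  rn <- ivw(neg)
  expect_equal(rn$beta, -r$beta, tolerance = 1e-12)
  expect_equal(rn$or_, 1 / r$or_, tolerance = 1e-10)
  expect_equal(rn$se, r$se, tolerance = 1e-12)
})

test_that("run_mr routes by instrument count and enforces the tier gate", {
  set.seed(123)
  ld <- simulate_ld(20, 0.3)
  # one strong causal variant -> one clumped instrument -> Wald ratio
  zq <- 12 * ld[, 10] + rnorm(20, 0, 0.1)
  expo <- zframe(zq, n = 7000, snp_ids = rownames(ld))
  outc <- zframe(0.5 * zq, n = 50000, snp_ids = rownames(ld))
  strong <- data.frame(feature_id = "F1", outcome = "o", score = 5L,
                       tier = "Strong", direction_consistent = TRUE)
  res <- run_mr(strong, expo, outc, ld)
  expect_s3_class(res, "mr_result")
  expect_equal(res$method, "wald_ratio")

  # five independent significant variants -> IVW with q_df = 4
  ld5 <- diag(5); dimnames(ld5) <- list(sprintf("v%d", 1:5), sprintf("v%d", 1:5))
  expo5 <- zframe(c(8, 9, 10, 8.5, 7.5), n = 7000, snp_ids = rownames(ld5))
  expo5$pos <- as.integer(seq(1e6, 9e7, length.out = 5))
  outc5 <- zframe(c(4, 4.5, 5, 4.2, 3.8), n = 50000, snp_ids = rownames(ld5))
  res5 <- run_mr(strong, expo5, outc5, ld5)
  expect_equal(res5$method, "ivw")
  expect_equal(res5$q_df, 4L)
  expect_false(is.na(res5$egger_intercept))

  # Weak tier and inconsistent features are refused
  weak <- strong; weak$tier <- "Weak"
  g <- run_mr(weak, expo, outc, ld)
  expect_equal(g$status, "gated")
  incons <- strong; incons$direction_consistent <- FALSE
  expect_equal(run_mr(incons, expo, outc, ld)$status, "gated")

  # no instrument at all -> not-estimable, not an exception
  nullexpo <- zframe(c(1, -0.5, 0.2), snp_ids = rownames(ld)[1:3])
  ne <- suppressMessages(run_mr(strong, nullexpo, outc, ld))
  expect_equal(ne$status, "not-estimable")
})

test_that("replication calls follow sign and significance", {
  disc <- ivw(random_instruments(5, 90))
  stopifnot(disc$beta != 0)
  same_sig <- disc; same_sig$pvalue <- 0.001
  same_ns <- disc; same_ns$pvalue <- 0.129
  opp <- disc; opp$beta <- -disc$beta; opp$pvalue <- 0.001
  expect_equal(mr_replicate(disc, list(same_sig)), "replicated")
  expect_equal(mr_replicate(disc, list(same_ns)), "trend")
  expect_equal(mr_replicate(disc, list(opp)), "not-replicated")
  expect_equal(mr_replicate(disc, list(opp, same_sig)), "replicated")
})
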