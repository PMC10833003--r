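test_that("read_sumstats validates, back-fills z, and drops bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- rbind(snp_row("rs1", "A", "G", beta = 0.1, se = 0.05),
              snp_row("rs2", "T", "C", beta = -0.2, se = 0.1),
              snp_row("rs3", "A", "C", beta = 0.05, se = 0.02))
  write_report(df, path)
  out <- read_sumstats(path)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_dropped"), 0L)
  expect_equal(out$beta, df$beta, tolerance = 1e-12)

  # se = 0 row is dropped and counted
  df2 <- df; df2$se[2] <- 0
  write_report(df2, path)
  expect_message(out2 <- read_sumstats(path), "dropped 1")
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "n_dropped"), 1L)

  # zscore back-filled from beta/se when absent
  df3 <- df[, setdiff(names(df), c("zscore", "pvalue"))]
  write_report(df3, path)
  out3 <- read_sumstats(path)
  expect_equal(out3$zscore[out3$snp_id == "rs1"], 2.0, tolerance = 1e-12)

  # missing mandatory column is a hard error naming the column
  df4 <- df[, setdiff(names(df), "se")]
  write_report(df4, path)
  expect_error(read_sumstats(path), "se")

  # zero valid rows is a hard error
  df5 <- df; df5$se <- 0
  write_report(df5, path)
  expect_error(suppressMessages(read_sumstats(path)), "no valid rows")
})

test_that("stored z or p conflicting with beta/se drops the row", {
  df <- rbind(snp_row("rs1", "A", "G"), snp_row("rs2", "T", "C"))
  df$zscore[1] <- 5  # beta/se says 2
  out <- validate_sumstats(df, quiet = TRUE)
  expect_equal(out$snp_id, "rs2")
  expect_equal(attr(out, "n_dropped"), 1L)

  df <- rbind(snp_row("rs1", "A", "G"), snp_row("rs2", "T", "C"))
  df$pvalue[2] <- 0.5  # inconsistent with z = -2
  out <- validate_sumstats(df, quiet = TRUE)
  expect_equal(out$snp_id, "rs1")
})

test_that("report write/read round-trips numeric fields to 1e-12", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- data.frame(feature_id = c("A", "B"), outcome = "overall",
                    score = c(5L, 3L), tier = c("Strong", "Moderate"),
                    beta = c(0.123456789012345, -1.98765432109876e-07),
                    consistent = c(TRUE, FALSE), stringsAsFactors = FALSE)
  write_report(rec, path)
  back <- read_report(path)
  expect_equal(back$beta, rec$beta, tolerance = 1e-12)
  expect_equal(back$score, rec$score)
  expect_equal(back$tier, rec$tier)
  expect_error(write_report(rec[0, ], path), "empty")
})

test_that("LD matrix write/read round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ld <- simulate_ld(5, 0.7)
  write_ld(ld, path)
  back <- read_ld(path)
  expect_equal(back, ld, tolerance = 1e-12)
  bad <- ld; bad[1, 2] <- 0.9  # breaks symmetry
  expect_error(validate_ld(bad), "symmetric")
  bad <- ld; diag(bad)[2] <- 0.5
  expect_error(validate_ld(bad), "diagonal")
})

test_that("allele alignment handles swaps, strand flips, palindromes", {
  a <- snp_row("rs1", "A", "G", beta = 0.1)
  # swapped alleles flip beta
  b <- snp_row("rs1", "G", "A", beta = 0.3)
  r <- align_alleles(a, b)
  expect_true(r$ok)
  expect_equal(r$b$effect_allele, "A")
  expect_equal(r$b$beta, -0.3)
  # strand complement resolves without sign change
  b <- snp_row("rs1", "T", "C", beta = 0.2)
  r <- align_alleles(a, b)
  expect_true(r$ok)
  expect_equal(r$b$beta, 0.2)
  # palindromic with ambiguous frequency is non-harmonizable
  a2 <- snp_row("rs9", "A", "T", eaf = 0.50)
  b2 <- snp_row("rs9", "A", "T", eaf = 0.50)
  expect_false(align_alleles(a2, b2)$ok)
  # palindromic with informative, disagreeing frequency flips the sign
  a3 <- snp_row("rs8", "A", "T", eaf = 0.10, beta = 0.1)
  b3 <- snp_row("rs8", "A", "T", eaf = 0.90, beta = 0.2)
  r3 <- align_alleles(a3, b3)
  expect_true(r3$ok)
  expect_equal(r3$b$beta, -0.2)
  # irreconcilable allele sets flagged, not an error
  b4 <- snp_row("rs1", "A", "C")
  expect_false(align_alleles(a, b4)$ok)
})

test_that("allele alignment is idempotent", {
  cases <- list(
    list(a = snp_row("rs1", "A", "G", beta = 0.1, eaf = 0.2),
         b = snp_row("rs1", "G", "A", beta = 0.3, eaf = 0.75)),
    list(a = snp_row("rs2", "T", "C", beta = -0.4, eaf = 0.6),
         b = snp_row("rs2", "A", "G", beta = 0.2, eaf = 0.35)),
    list(a = snp_row("rs3", "A", "T", eaf = 0.10, beta = 0.1),
         b = snp_row("rs3", "T", "A", eaf = 0.88, beta = 0.2)))
  for (cs in cases) {
    once <- align_alleles(cs$a, cs$b)
    twice <- align_alleles(once$a, once$b)
    expect_true(once$ok)
    expect_equal(twice$b, once$b)
  }
})
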