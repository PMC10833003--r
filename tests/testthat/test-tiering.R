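test_that("score_feature reproduces the worked-example proteins", {
  # CSK: every layer significant and colocalizing
  csk <- score_feature(
    assoc = list(plasma = list(p_fdr = 0.0049, zscore = -4.147),
                 blood = list(p_fdr = 0.0002, zscore = -3.979),
                 breast = list(p_fdr = 1.46e-5, zscore = -4.613)),
    colocs = list(plasma = 0.779, blood = 0.843, breast = 0.863),
    feature_id = "CSK")
  expect_equal(csk$score, 6L)
  expect_equal(csk$tier, "Strong")
  expect_true(csk$direction_consistent)

  # PEX14: blood-layer colocalization fails, everything else passes
  pex14 <- score_feature(
    assoc = list(plasma = list(p_fdr = 0.0004, zscore = 4.839),
                 blood = list(p_fdr = 1.09e-10, zscore = 6.843),
                 breast = list(p_fdr = 8.14e-7, zscore = 5.341)),
    colocs = list(plasma = 0.989, blood = 0.195, breast = 0.79))
  expect_equal(pex14$score, 5L)
  expect_equal(pex14$tier, "Strong")

  # FBLN5: plasma significance only, no colocalization, breast absent
  fbln5 <- score_feature(
    assoc = list(plasma = list(p_fdr = 7.60e-5, zscore = 5.226),
                 blood = list(p_fdr = 0.6460, zscore = 0.460)),
    colocs = list(plasma = 0, blood = 0))
  expect_equal(fbln5$score, 1L)
  expect_equal(fbln5$tier, "Weak")

  # no evidence at all
  none <- score_feature(assoc = list(plasma = list(p_fdr = 0.9, zscore = 1)))
  expect_equal(none$score, 0L)
  expect_equal(none$tier, "None")

  expect_error(score_feature(list(plasma = list(p_fdr = 0, zscore = 1))),
               "p_fdr")
  expect_error(score_feature(list(plasma = list(p_fdr = 1.2, zscore = 1))),
               "p_fdr")
})

test_that("score is monotone in p_fdr and pph4", {
  set.seed(5)
  for (i in 1:30) {
    p <- runif(3, 1e-4, 0.9); h <- runif(3)
    base <- score_feature(
      list(plasma = list(p_fdr = p[1], zscore = 1),
           blood = list(p_fdr = p[2], zscore = 1),
           breast = list(p_fdr = p[3], zscore = 1)),
      list(plasma = h[1], blood = h[2], breast = h[3]))
    better <- score_feature(
      list(plasma = list(p_fdr = p[1] / 2, zscore = 1),
           blood = list(p_fdr = p[2], zscore = 1),
           breast = list(p_fdr = p[3], zscore = 1)),
      list(plasma = h[1], blood = min(1, h[2] * 1.5), breast = h[3]))
    expect_gte(better$score, base$score)
  }
})

test_that("tier boundaries are exactly {0},{1,2},{3,4},{5,6}", {
  tiers <- vapply(0:6, function(s) {
    assoc <- list(); colocs <- list()
    layers <- c("plasma", "blood", "breast")
    for (i in 1:3) {
      pts_here <- max(0, min(2, s - 2 * (i - 1)))
      assoc[[layers[i]]] <- list(p_fdr = if (pts_here >= 1) 0.01 else 0.5,
                                 zscore = 1)
      colocs[[layers[i]]] <- if (pts_here == 2) 0.9 else 0.1
    }
    score_feature(assoc, colocs)$tier
  }, character(1))
  expect_equal(tiers, c("None", "Weak", "Weak", "Moderate", "Moderate",
                        "Strong", "Strong"))
})

test_that("direction consistency follows the plasma sign over significant layers", {
  expect_false(direction_consistency(c(plasma = 4.194, blood = -2.547,
                                       breast = -3.266)))
  expect_true(direction_consistency(c(plasma = -4.147, blood = -3.979,
                                      breast = -4.613)))
  expect_true(is.na(direction_consistency(c(plasma = 2.0))))
  # non-significant opposite-signed layer does not break consistency
  expect_true(is.na(direction_consistency(c(plasma = 5.2, blood = -0.4),
                                          significant = c(TRUE, FALSE))))
  expect_false(direction_consistency(c(plasma = 5.2, blood = -2.4),
                                     significant = c(TRUE, TRUE)))
})

test_that("the packaged 25-protein table reproduces printed scores and tiers", {
  df <- read_example_scores()
  expect_equal(nrow(df), 25)
  scored <- score_example_table(df)
  expect_equal(scored$score, df$score)
  expect_equal(scored$tier, df$tier)
  counts <- tier_table(scored)
  expect_equal(unname(counts[c("Strong", "Moderate", "Weak")]), c(5L, 6L, 14L))
  # MST1 keeps its score but is flagged direction-inconsistent
  mst1 <- scored[scored$feature_id == "MST1", ]
  expect_equal(mst1$score, 4L)
  expect_false(mst1$direction_consistent)
})

test_that("tier_table counts tiers and handles edge cases", {
  df <- data.frame(tier = c("Strong", "Weak", "Weak"))
  expect_equal(unname(tier_table(df)), c(0L, 2L, 0L, 1L))
  expect_equal(unname(tier_table(data.frame(tier = character(0)))),
               rep(0L, 4))
  one <- score_feature(list(plasma = list(p_fdr = 0.001, zscore = 2),
                            blood = list(p_fdr = 0.001, zscore = 2),
                            breast = list(p_fdr = 0.001, zscore = 2)),
                       list(plasma = 0.9, blood = 0.9, breast = 0.9))
  expect_equal(unname(tier_table(one)), c(0L, 0L, 0L, 1L))
})
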