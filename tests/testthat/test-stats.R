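test_that("condition means average valid critical trials only", {
  tab <- data.frame(
    subject_id = rep("S01", 7),
    trial_id = sprintf("T%03d", 1:7),
    pronoun = c(rep(c("I", "YOU", "HE"), 2), "I"),
    verb_type = c(rep(c("AV", "IV"), each = 3), "AV"),
    is_catch = c(rep(FALSE, 6), TRUE),
    linguistic_error = FALSE,
    onset_ms = 100,
    segmentation_failure = FALSE,
    pct_t_vpeak = c(50, 52, 48, 51, 47, 49, 99),
    stringsAsFactors = FALSE
  )
  # single trial per cell: means equal the trial values; catch excluded
  cm <- condition_means(apply_qc(tab), parameters = "pct_t_vpeak")
  expect_equal(nrow(cm), 6)
  expect_false(99 %in% cm$mean)
  one <- cm$mean[cm$pronoun == "I" & cm$verb_type == "AV"]
  expect_equal(one, 50)
  # permuting trial order leaves the means unchanged
  cm2 <- condition_means(apply_qc(tab[sample(7), ]), parameters = "pct_t_vpeak")
  expect_equal(cm2[order(cm2$pronoun, cm2$verb_type), "mean"],
               cm[order(cm$pronoun, cm$verb_type), "mean"])
})

test_that("subjects with an empty cell are dropped with a report entry", {
  mat <- random_means_matrix(4, 1)
  m <- synthetic_means(mat)
  tab <- data.frame(
    subject_id = m$subject_id, trial_id = seq_len(nrow(m)),
    pronoun = m$pronoun, verb_type = m$verb_type,
    is_catch = FALSE, linguistic_error = FALSE, onset_ms = 100,
    segmentation_failure = FALSE, pct_t_vpeak = m$mean,
    stringsAsFactors = FALSE
  )
  tab <- tab[!(tab$subject_id == "S03" & tab$pronoun == "YOU" &
                 tab$verb_type == "IV"), ]
  cm <- condition_means(apply_qc(tab), parameters = "pct_t_vpeak")
  expect_false("S03" %in% cm$subject_id)
  expect_equal(attr(cm, "dropped")$pct_t_vpeak, "S03")
})

test_that("repeated-measures ANOVA reproduces the brute-force sums-of-squares oracle", {
  for (case in 1:6) {
    n <- sample(3:6, 1)
    mat <- random_means_matrix(n, 100 + case)
    res <- rm_anova(synthetic_means(mat))
    o <- oracle_rm_anova(mat)
    for (pair in list(c("Verb", "verb"), c("Pronoun", "pronoun"),
                      c("Verb x Pronoun", "interaction"))) {
      r <- res[res$effect == pair[1], ]
      e <- o[[pair[2]]]
      expect_equal(r$F, e$F, tolerance = 1e-10)
      expect_equal(r$df1, e$df1)
      expect_equal(r$df2, e$df2)
      expect_equal(r$MSE, e$MSE, tolerance = 1e-10)
      expect_equal(r$p, e$p, tolerance = 1e-10)
      expect_equal(r$eta_p2, e$eta_p2, tolerance = 1e-10)
    }
  }
})

test_that("within-subject degrees of freedom follow the design size", {
  res12 <- rm_anova(synthetic_means(random_means_matrix(12, 7)))
  int12 <- res12[res12$effect == "Verb x Pronoun", ]
  expect_equal(c(int12$df1, int12$df2), c(2, 22))
  res13 <- rm_anova(synthetic_means(random_means_matrix(13, 8)))
  int13 <- res13[res13$effect == "Verb x Pronoun", ]
  expect_equal(c(int13$df1, int13$df2), c(2, 24))
  expect_error(rm_anova(synthetic_means(random_means_matrix(1, 9))),
               "at least 2 subjects")
})

test_that("partial eta squared identity matches reported values", {
  expect_equal(round(eta_p2(0.341, 2, 24), 3), 0.028)
  expect_equal(eta_p2(6.48, 2, 22), 6.48 * 2 / (6.48 * 2 + 22))
  # recompute from our own ANOVA output
  mat <- random_means_matrix(9, 3)
  res <- rm_anova(synthetic_means(mat))
  expect_equal(res$eta_p2, eta_p2(res$F, res$df1, res$df2), tolerance = 1e-12)
})

test_that("planned paired comparisons are antisymmetric and handle null data", {
  mat <- random_means_matrix(12, 11)
  m <- synthetic_means(mat)
  fwd <- planned_ttests(m, comparisons = list(c("YOU", "AV", "YOU", "IV")),
                        sided = "two")
  rev <- planned_ttests(m, comparisons = list(c("YOU", "IV", "YOU", "AV")),
                        sided = "two")
  expect_equal(fwd$t, -rev$t, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)

  mat0 <- mat
  mat0[, "I.IV"] <- mat0[, "I.AV"] # identical cells -> zero differences
  null <- planned_ttests(synthetic_means(mat0),
                         comparisons = list(c("I", "AV", "I", "IV")))
  expect_equal(null$t, 0)
  expect_equal(null$p, 0.5)
  expect_true(null$degenerate)
})

test_that("one-sided p values use the t survival function", {
  # t = 0.56 on 11 df -> one-sided p ~ 0.29
  expect_equal(pt(0.56, 11, lower.tail = FALSE), 0.29, tolerance = 0.02)
  set.seed(42)
  base <- rnorm(12, 50, 2)
  mat <- random_means_matrix(12, 42)
  m <- synthetic_means(mat)
  res <- planned_ttests(m, comparisons = list(c("HE", "AV", "HE", "IV")))
  d <- mat[, "HE.AV"] - mat[, "HE.IV"]
  tref <- mean(d) / (sd(d) / sqrt(12))
  expect_equal(res$t, tref, tolerance = 1e-12)
  expect_equal(res$p, pt(abs(tref), 11, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$df, 11)
})

test_that("alpha correction modes set the corrected level", {
  mat <- random_means_matrix(6, 13)
  m <- synthetic_means(mat)
  bon <- planned_ttests(m)
  expect_equal(unique(bon$alpha_corrected), 0.05 / 3)
  fixed <- planned_ttests(m, correction = "fixed", alpha_fixed = 0.01)
  expect_equal(unique(fixed$alpha_corrected), 0.01)
})

test_that("paired t agrees with stats::t.test as an independent cross-check", {
  mat <- random_means_matrix(10, 77)
  m <- synthetic_means(mat)
  res <- planned_ttests(m, comparisons = list(c("I", "AV", "I", "IV")),
                        sided = "two")
  ref <- t.test(mat[, "I.AV"], mat[, "I.IV"], paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("summary table uses the published layout and half-up rounding", {
  expect_equal(round_half_up(47.38), 47.4)
  expect_equal(round_half_up(47.35), 47.4)
  expect_equal(round_half_up(-1.25), -1.3)
  mat <- random_means_matrix(5, 19)
  tab <- summary_table(synthetic_means(mat))
  expect_identical(names(tab),
                   c("parameter", "I_Action", "You_Action", "He_Action",
                     "I_Interaction", "You_Interaction", "He_Interaction"))
  expect_equal(tab$You_Action, round_half_up(mean(mat[, "YOU.AV"])))
  empty <- summary_table(synthetic_means(mat)[0, ])
  expect_equal(nrow(empty), 0)
})
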