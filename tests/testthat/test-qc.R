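kin_row <- function(onset_ms = 120, seg_fail = FALSE, catch = FALSE,
                    ling = FALSE) {
  data.frame(subject_id = "S01", trial_id = "T001", pronoun = "I",
             verb_type = "AV", is_catch = catch, linguistic_error = ling,
             onset_ms = onset_ms, segmentation_failure = seg_fail,
             stringsAsFactors = FALSE)
}

test_that("trial validation flags anticipations, catch trials and failures", {
  f <- validate_trial(kin_row(onset_ms = -50))
  expect_true(f$anticipated_movement)
  expect_false(f$valid)

  f2 <- validate_trial(kin_row(catch = TRUE))
  expect_true(f2$catch_trial)
  expect_false(f2$valid)

  f3 <- validate_trial(kin_row())
  expect_true(f3$valid)
  expect_false(any(unlist(f3[c("linguistic_error", "anticipated_movement",
                               "segmentation_failure", "catch_trial")])))

  f4 <- validate_trial(kin_row(seg_fail = TRUE))
  expect_true(f4$segmentation_failure)
  expect_false(f4$valid)

  f5 <- validate_trial(kin_row(ling = TRUE))
  expect_false(f5$valid)
})

make_qc_table <- function(valid_per_subject, n_critical = 30, n_catch = 10) {
  rows <- list()
  for (s in seq_along(valid_per_subject)) {
    nv <- valid_per_subject[s]
    for (i in seq_len(n_critical)) {
      rows[[length(rows) + 1L]] <- kin_row(onset_ms = if (i <= nv) 120 else -10)
      rows[[length(rows)]]$subject_id <- sprintf("P%02d", s)
      rows[[length(rows)]]$trial_id <- sprintf("T%03d", i)
    }
    for (i in seq_len(n_catch)) {
      rows[[length(rows) + 1L]] <- kin_row(catch = TRUE)
      rows[[length(rows)]]$subject_id <- sprintf("P%02d", s)
      rows[[length(rows)]]$trial_id <- sprintf("C%03d", i)
    }
  }
  apply_qc(do.call(rbind, rows))
}

test_that("participant exclusion is strict at the 50% boundary", {
  tab <- make_qc_table(c(14, 15, 30))
  out <- filter_participants(tab, 0.5)
  expect_identical(out$report$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(out$report$fraction, c(14, 15, 30) / 30)
  expect_false("P01" %in% out$params$subject_id)
  expect_true("P02" %in% out$params$subject_id) # exactly 50% is retained
})

test_that("exclusion is monotone in the threshold and accounts for all trials", {
  tab <- make_qc_table(c(10, 16, 22, 30))
  excl <- function(f) sum(filter_participants(tab, f)$report$excluded)
  fractions <- c(0.2, 0.35, 0.5, 0.6, 0.7)
  counts <- vapply(fractions, excl, 0)
  expect_true(all(diff(counts) >= 0))
  rep <- filter_participants(tab, 0.5)$report
  n_catch <- sum(tab$is_catch)
  expect_equal(sum(rep$n_critical) + n_catch, nrow(tab))
  expect_equal(sum(rep$n_valid), sum(tab$valid))
})

test_that("excluding every participant is an error", {
  tab <- make_qc_table(c(2, 3))
  expect_error(filter_participants(tab, 0.5), "all participants")
})

test_that("a planted error rate produces the expected count of valid trials per cell", {
  cfg <- generator_preset("exp2_german", n_subjects = 3,
                          linguistic_error_rate = 0.08)
  ds <- simulate_experiment(cfg, seed = 31, calibrate = FALSE)
  tab <- data.frame(
    subject_id = vapply(ds$trials, function(tr) tr$subject_id, ""),
    trial_id = vapply(ds$trials, function(tr) tr$trial_id, ""),
    pronoun = vapply(ds$trials, function(tr) tr$condition$pronoun, ""),
    verb_type = vapply(ds$trials, function(tr) tr$condition$verb_type, ""),
    is_catch = vapply(ds$trials, function(tr) tr$condition$is_catch, TRUE),
    linguistic_error = vapply(ds$trials, function(tr) tr$linguistic_error, TRUE),
    onset_ms = 150, segmentation_failure = FALSE,
    stringsAsFactors = FALSE
  )
  tab <- apply_qc(tab)
  valid_rate <- sum(tab$valid) / sum(!tab$is_catch)
  expect_gt(valid_rate, 0.85)
  expect_lt(valid_rate, 0.97)
  # ~92% of 14 trials/cell -> about 13 valid trials per condition cell
  per_cell <- sum(tab$valid) / (3 * 6)
  expect_gt(per_cell, 12)
  expect_lt(per_cell, 14)
})
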