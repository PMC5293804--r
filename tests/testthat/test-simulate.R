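test_that("simulated trials are byte-identical for a fixed seed", {
  cfg <- generator_preset("exp1_italian")
  t1 <- simulate_trial(condition("I", "AV"), NULL, cfg, seed = 99)
  t2 <- simulate_trial(condition("I", "AV"), NULL, cfg, seed = 99)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  t3 <- simulate_trial(condition("I", "AV"), NULL, cfg, seed = 100)
  expect_false(identical(t3$markers$wrist$x_mm, t1$markers$wrist$x_mm))
})

test_that("simulated experiments are reproducible byte-for-byte", {
  cfg <- generator_preset("exp1_italian", n_subjects = 2)
  d1 <- simulate_experiment(cfg, seed = 5)
  d2 <- simulate_experiment(cfg, seed = 5)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})

test_that("experiment layout matches the two study designs", {
  ds1 <- simulate_experiment(generator_preset("exp1_italian", n_subjects = 2),
                             seed = 1)
  catch1 <- vapply(ds1$trials, function(tr) tr$condition$is_catch, TRUE)
  subj1 <- vapply(ds1$trials, function(tr) tr$subject_id, "")
  expect_equal(length(ds1), 2 * 40)
  expect_equal(sum(!catch1[subj1 == "S01"]), 30)
  expect_equal(sum(catch1[subj1 == "S01"]), 10)

  ds2 <- simulate_experiment(generator_preset("exp2_german", n_subjects = 1),
                             seed = 1)
  catch2 <- vapply(ds2$trials, function(tr) tr$condition$is_catch, TRUE)
  expect_equal(length(ds2), 100)
  expect_equal(sum(!catch2), 84)
  expect_equal(sum(catch2), 16)
  # every critical cell is filled equally
  cells <- table(vapply(ds2$trials[!catch2], function(tr)
    paste(tr$condition$pronoun, tr$condition$verb_type), ""))
  expect_true(all(cells == 14))
})

test_that("position noise is zero-mean around the noiseless path", {
  cfg <- generator_preset("exp1_italian")
  cfg$trial_noise_sd_mm <- 0.5
  cfg0 <- cfg
  cfg0$trial_noise_sd_mm <- 0
  nrep <- 300
  devs <- vapply(seq_len(nrep), function(i) {
    tr <- simulate_trial(condition("I", "AV"), NULL, cfg, seed = 3000 + i)
    tr0 <- simulate_trial(condition("I", "AV"), NULL, cfg0, seed = 3000 + i)
    mean(tr$markers$wrist$x_mm - tr0$markers$wrist$x_mm)
  }, 0)
  sem <- sd(devs) / sqrt(nrep)
  expect_lt(abs(mean(devs)), 3 * sem + 1e-12)
})

test_that("zero-variance configuration reproduces the preset cell means per subject", {
  cfg <- noiseless(generator_preset("exp1_italian", n_subjects = 2))
  ds <- simulate_experiment(cfg, seed = 8)
  cm <- condition_means(apply_qc(process_dataset(ds)),
                        parameters = c("reach_time_ms", "pct_t_vpeak"))
  truth <- cfg$condition_means
  frame <- 1000 / 60
  for (i in seq_len(nrow(truth))) {
    sel <- cm$pronoun == truth$pronoun[i] & cm$verb_type == truth$verb_type[i]
    rt <- cm$mean[sel & cm$parameter == "reach_time_ms"]
    pc <- cm$mean[sel & cm$parameter == "pct_t_vpeak"]
    expect_lt(max(abs(rt - truth$reach_time_ms[i])), frame)
    expect_lt(max(abs(pc - truth$pct_t_vpeak[i])), 0.5)
    # both subjects agree (no between-subject variance)
    expect_lt(diff(range(rt)), 1e-9)
  }
})

test_that("simulation rejects conditions missing from the configuration", {
  cfg <- generator_preset("exp1_italian")
  cfg$condition_means <- cfg$condition_means[-2, ]
  expect_error(validate_generator_config(cfg), "six pronoun x verb cells")
  cfg2 <- generator_preset("exp1_italian")
  cm <- cfg2$condition_means[cfg2$condition_means$pronoun != "HE" |
                               cfg2$condition_means$verb_type != "IV", ]
  cfg2$condition_means <- cm
  expect_error(simulate_trial(condition("HE", "IV"), NULL, cfg2, seed = 1),
               "missing")
})

test_that("generator configuration enforces its invariants", {
  expect_error(generator_config(catch_fraction = 1), "catch_fraction")
  expect_error(generator_config(trial_noise_sd_mm = -1), "non-negative")
  cm <- reachgrasp:::exp1_condition_means()
  cm$pct_t_vpeak[3] <- 104
  expect_error(generator_config(condition_means = cm), "strictly in")
})

test_that("cumulative path length of the noiseless wrist equals the reach amplitude", {
  cfg <- noiseless(generator_preset("exp1_italian"))
  tr <- simulate_trial(condition("I", "AV"), NULL, cfg, seed = 4)
  w <- tr$markers$wrist
  seg <- sqrt(diff(w$x_mm)^2 + diff(w$y_mm)^2 + diff(w$z_mm)^2)
  expect_lt(abs(sum(seg) - 330) / 330, 0.001)
})
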