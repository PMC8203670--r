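test_that("default generator yields 24 children x 4 experiments x 4 trials", {
  trials <- generate_exploration_trials(generator_config(seed = 7))
  expect_equal(nrow(trials), 384)
  expect_equal(length(unique(paste(trials$experiment, trials$child_id))), 96)
  counts <- table(trials$experiment, trials$trial_order)
  expect_true(all(counts == 24))
  expect_true(all(trials$playtime_s > 0))
  # response is always one of the two alternatives; correct iff it is the hidden one
  expect_true(all(trials$response_count == trials$n_a |
                    trials$response_count == trials$n_b))
  expect_equal(trials$correct, trials$response_count == trials$hidden)
})

test_that("generation is fully deterministic under (seed, config)", {
  cfg <- generator_config(seed = 42)
  t1 <- generate_exploration_trials(cfg)
  t2 <- generate_exploration_trials(cfg)
  expect_identical(t1, t2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(t1, p1)
  write_trials(t2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  t3 <- generate_exploration_trials(generator_config(seed = 43))
  expect_false(identical(t1$playtime_s, t3$playtime_s))
})

test_that("trial order and hidden alternative are exactly counterbalanced", {
  trials <- generate_exploration_trials(generator_config(seed = 3))
  for (e in unique(trials$experiment)) {
    sub <- trials[trials$experiment == e, ]
    # each contrast occupies each trial position equally often
    pos <- table(sub$label, sub$trial_order)
    expect_true(all(pos == 6))
    if (e == "exp6") next
    # each alternative of a contrast hidden equally often
    hid <- table(sub$label, sub$hidden)
    expect_true(all(hid[hid > 0] == 12))
  }
})

test_that("a fixed-content set keeps its specified hidden counts for every child", {
  trials <- generate_exploration_trials(generator_config(seed = 5))
  exp6 <- trials[trials$experiment == "exp6", ]
  expect_true(all(exp6$hidden %in% c(8, 3)))
  expect_equal(length(unique(paste(exp6$label, exp6$hidden))), 4)
})

test_that("noiseless generation is exactly linear in -d' after normalization", {
  cfg <- generator_config(playtime_slope_theta = 0.3, trial_order_slope = 0,
                          child_sd = 0, noise_sd = 0, seed = 11)
  norm <- normalize_playtimes(generate_exploration_trials(cfg))
  fit <- suppressWarnings(fit_playtime_regression(norm, "neg_dprime"))
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
})

test_that("correctness rate increases with d' at large n", {
  cfg <- generator_config(n_children_per_experiment = 400, seed = 21)
  trials <- generate_exploration_trials(cfg)
  d <- dprime(trials[c("label", "n_a", "n_b", "hidden")])
  acc <- tapply(trials$correct, round(d, 6), mean)
  expect_gt(cor(as.numeric(names(acc)), as.numeric(acc), method = "spearman"), 0.9)
})

test_that("choice generator respects degenerate and stochastic probabilities", {
  all_yes <- generate_choice_trials(24, 1, seed = 1)
  expect_equal(sum(all_yes$chose_discriminable), 24)
  none <- generate_choice_trials(24, 0, seed = 1)
  expect_equal(sum(none$chose_discriminable), 0)
  big <- generate_choice_trials(10000, 0.75, seed = 99)
  expect_equal(mean(big$chose_discriminable), 0.75, tolerance = 0.02 / 0.75)
  expect_identical(generate_choice_trials(50, 0.5, seed = 8),
                   generate_choice_trials(50, 0.5, seed = 8))
  expect_error(generate_choice_trials(10, 1.5), "probability")
})

test_that("config validation catches malformed contrast sets", {
  expect_error(generator_config(contrast_sets = list(exp4 = contrasts_tbl(8, 2))),
               "exactly 4")
  expect_error(generate_exploration_trials(list()), "generator_config")
})

test_that("log playtime scale also yields positive playtimes and recovers theta", {
  cfg <- generator_config(playtime_scale = "log", seed = 13)
  trials <- generate_exploration_trials(cfg)
  expect_true(all(trials$playtime_s > 0))
  fit <- fit_playtime_regression(normalize_playtimes(trials), "neg_dprime")
  expect_equal(fit$beta, 0.24, tolerance = 0.35)
})

test_that("trial CSV round-trips through the canonical schema", {
  trials <- generate_exploration_trials(generator_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back$playtime_s, trials$playtime_s, tolerance = 1e-12)
  expect_equal(back$correct, trials$correct)
  # reader names missing columns
  broken <- trials[setdiff(names(trials), "playtime_s")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, p2)
  expect_error(read_trials(p2), "playtime_s")
})
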