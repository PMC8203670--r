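# A small handmade trial table: 3 children, 4 trials each, distinct d' per trial.
toy_trials <- function(playtimes = NULL) {
  cs <- contrasts_tbl(c(9, 3, 8, 7), c(8, 2, 3, 1))
  n_kids <- 3
  if (is.null(playtimes)) {
    set.seed(99)
    playtimes <- runif(4 * n_kids, 5, 20)
  }
  tibble::tibble(
    child_id = rep(sprintf("c%d", 1:n_kids), each = 4),
    experiment = "exp4",
    trial_order = rep(1:4, n_kids),
    label = rep(cs$label, n_kids),
    n_a = rep(cs$n_a, n_kids),
    n_b = rep(cs$n_b, n_kids),
    hidden = rep(cs$hidden, n_kids),
    age_years = rep(c(4.2, 5.0, 5.7), each = 4),
    playtime_s = playtimes,
    response_count = rep(cs$hidden, n_kids),
    correct = TRUE
  )
}

test_that("normalization gives per-child mean 1 and the worked proportions", {
  t1 <- toy_trials(c(10, 10, 10, 10, 10, 20, 30, 40, 1, 2, 3, 2))
  norm <- normalize_playtimes(t1)
  expect_equal(norm$normalized_playtime[1:4], c(1, 1, 1, 1))
  expect_equal(norm$normalized_playtime[5:8], c(0.4, 0.8, 1.2, 1.6))
  means <- tapply(norm$normalized_playtime, norm$child_id, mean)
  expect_equal(as.numeric(means), rep(1, 3))
  sums <- tapply(norm$normalized_playtime, norm$child_id, sum)
  expect_equal(as.numeric(sums), rep(4, 3))
})

test_that("normalization is invariant to rescaling one child's raw playtimes", {
  base <- toy_trials()
  norm1 <- normalize_playtimes(base)
  scaled <- base
  scaled$playtime_s[scaled$child_id == "c2"] <-
    scaled$playtime_s[scaled$child_id == "c2"] * 37.5
  norm2 <- normalize_playtimes(scaled)
  expect_equal(norm1$normalized_playtime, norm2$normalized_playtime)
})

test_that("zero-total-playtime children are excluded with a warning", {
  t1 <- toy_trials()
  t1$playtime_s[t1$child_id == "c3"] <- 0
  expect_warning(norm <- normalize_playtimes(t1), "zero total playtime")
  expect_false("c3" %in% norm$child_id)
  expect_equal(nrow(norm), 8)
  t1$playtime_s[1] <- -2
  expect_error(normalize_playtimes(t1), "negative")
})

test_that("clustered-OLS slope equals brute-force normal equations on a toy table", {
  norm <- normalize_playtimes(toy_trials())
  fit <- fit_playtime_regression(norm, "neg_dprime")
  X <- cbind(1, -dprime(norm[c("label", "n_a", "n_b", "hidden")]))
  beta_hat <- solve(t(X) %*% X, t(X) %*% norm$normalized_playtime)
  expect_equal(fit$beta, beta_hat[2, 1], tolerance = 1e-12)
  expect_lte(fit$ci_low, fit$beta)
  expect_gte(fit$ci_high, fit$beta)
  expect_equal(fit$n_children, 3)
})

test_that("regression battery flags degenerate designs and missing data", {
  norm <- normalize_playtimes(toy_trials())
  same_d <- norm
  same_d$n_a <- 8; same_d$n_b <- 2; same_d$hidden <- 8; same_d$label <- "8v2"
  expect_error(fit_playtime_regression(same_d, "neg_dprime"), "constant")
  expect_error(fit_accuracy_regression(same_d), "constant")
  norm_na <- norm
  norm_na$normalized_playtime[2] <- NA
  expect_error(fit_playtime_regression(norm_na, "neg_dprime"), "missing")
  one_kid <- normalize_playtimes(toy_trials()[1:4, ])
  expect_error(fit_playtime_regression(one_kid, "neg_dprime"), "2 children")
})

test_that("mixed-model estimator agrees with clustered OLS on balanced synthetic data", {
  norm <- normalize_playtimes(generate_exploration_trials(generator_config(seed = 17)))
  ols <- fit_playtime_regression(norm, "neg_dprime")
  mix <- fit_playtime_regression(norm, "neg_dprime", estimator = "mixed")
  expect_equal(mix$beta, ols$beta, tolerance = 0.05)
  expect_equal(mix$estimator, "mixed")
})

test_that("hidden-count and age effects are null by construction", {
  norm <- normalize_playtimes(generate_exploration_trials(generator_config(seed = 23)))
  hid <- fit_playtime_regression(norm, "hidden_count")
  expect_lte(hid$ci_low, 0)
  expect_gte(hid$ci_high, 0)
  age <- fit_playtime_regression(norm, "age")
  expect_lte(age$ci_low, 0)
  expect_gte(age$ci_high, 0)
})

test_that("accuracy regression recovers the generating log-odds slope", {
  cfg <- generator_config(n_children_per_experiment = 500, seed = 31)
  trials <- generate_exploration_trials(cfg)
  fit <- fit_accuracy_regression(trials)
  expect_equal(fit$beta, 1.12, tolerance = 0.10)
  expect_true(fit$converged)
})

test_that("an all-correct outcome is reported as a separation flag, not an error", {
  t1 <- toy_trials()           # all responses correct by construction
  fit <- fit_accuracy_regression(t1)
  expect_false(fit$converged)
  expect_equal(fit$note, "separation")
})

test_that("condition-mean correlation is 1 on noiseless linear data and errors on degeneracy", {
  cfg <- generator_config(playtime_slope_theta = 0.24, trial_order_slope = 0,
                          child_sd = 0, noise_sd = 0, seed = 1)
  norm <- normalize_playtimes(generate_exploration_trials(cfg))
  fit <- condition_mean_correlation(norm)
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  flat <- normalize_playtimes(toy_trials(rep(7, 12)))
  expect_error(condition_mean_correlation(flat), "zero variance")
})

test_that("individual slopes count positive children with a binomial CI", {
  # deterministic playtimes: c1 and c2 follow difficulty, c3 anti-follows
  cs_d <- -dprime(contrasts_tbl(c(9, 3, 8, 7), c(8, 2, 3, 1)))
  t1 <- toy_trials(c(10 + cs_d, 10 + 2 * cs_d, 10 - cs_d))
  s <- individual_slopes(normalize_playtimes(t1))
  expect_equal(s$k_positive, 2)
  expect_equal(s$n, 3)
  expect_equal(s$proportion, 2 / 3)
  expect_lte(s$ci_low, s$proportion)
  expect_gte(s$ci_high, s$proportion)

  # noiseless generator: every child follows the model exactly
  cfg <- generator_config(trial_order_slope = 0, child_sd = 0, noise_sd = 0, seed = 4)
  s2 <- individual_slopes(normalize_playtimes(generate_exploration_trials(cfg)))
  expect_equal(s2$proportion, 1)

  # children with constant d' are excluded with a warning
  t2 <- toy_trials()
  t2[t2$child_id == "c1", c("n_a", "n_b", "hidden", "label")] <-
    list(8, 2, 8, "8v2")
  expect_warning(s3 <- individual_slopes(normalize_playtimes(t2)), "constant d'")
  expect_equal(s3$n, 2)
})
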