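#' Default contrast sets for the four free-exploration experiments
#'
#' Four sets of four numerosity contrasts over counts 1-9, spanning the d'
#' range from near the hardest adjacent pair (8 vs 7, d' ~ 0.13) to the
#' easiest (9 vs 1, d' ~ 2.2). The sets are balanced in two ways. First,
#' the product of the count ratios is exactly 48 in every set, so every
#' experiment has the same mean d' (log(48)/4 ~ 0.968): pooled trial-level
#' regressions on -d' are then not attenuated by between-experiment
#' differences in set means, and noiseless generation is exactly linear in
#' -d' across the whole design. Second, the expected hidden count under
#' counterbalancing is decorrelated from d' across the 16 contrasts, so a
#' marginal regression of playtime on the actual content is null by design,
#' not merely in expectation over assignments. The third set mimics a
#' fixed-content design: the hidden count is pinned to 8 or 3 for every
#' contrast (each content level paired with one hard and one easy
#' contrast), providing a within-experiment dissociation of content from
#' contrast. Fully replaceable via [generator_config()].
#'
#' @return A named list of four contrast tibbles (`exp4` ... `exp7`); the
#'   `exp6` element carries attribute `fixed_content = TRUE`.
#' @export
default_contrast_sets <- function() {
  exp6 <- contrasts_tbl(
    n_a = c(3, 3, 8, 8), n_b = c(1, 2, 1, 6),
    hidden = c(3, 3, 8, 8)
  )
  attr(exp6, "fixed_content") <- TRUE
  list(
    exp4 = contrasts_tbl(n_a = c(2, 4, 4, 9), n_b = c(1, 2, 3, 1)),
    exp5 = contrasts_tbl(n_a = c(4, 7, 8, 9), n_b = c(1, 2, 7, 3)),
    exp6 = exp6,
    exp7 = contrasts_tbl(n_a = c(5, 6, 6, 8), n_b = c(2, 1, 5, 3))
  )
}

#' Configuration for the synthetic exploration-trial generator
#'
#' Bundles every tunable of the generative model for the free-exploration
#' experiments. Defaults are calibrated to the fitted effects the analysis
#' pipeline is designed to recover: expected normalized playtime rises with
#' the difficulty of the contrast (slope `playtime_slope_theta` per unit
#' -d'), declines weakly over the four trials, and is unaffected by the
#' actual hidden count; accuracy follows a logistic function of d'.
#'
#' @param n_children_per_experiment Children per experiment (default 24).
#' @param contrast_sets Named list of four contrast tables, one per
#'   experiment, four contrasts each. Default [default_contrast_sets()].
#' @param playtime_slope_theta Effect of -d' on expected normalized playtime
#'   (default 0.24).
#' @param trial_order_slope Change in expected normalized playtime per trial
#'   position (default -0.051).
#' @param content_slope Effect of the hidden count (default 0: content has no
#'   effect, only the contrast does).
#' @param accuracy_intercept Log-odds of a correct report at d' = 0
#'   (default 0, i.e. chance).
#' @param accuracy_slope Log-odds increase in correctness per unit d'
#'   (default 1.12).
#' @param child_sd SD of the per-child log baseline-playtime effect
#'   (default 0.5).
#' @param noise_sd Trial-level Gaussian noise SD on the normalized-playtime
#'   scale (default 0.15).
#' @param base_playtime_s Median raw playtime in seconds (default 10).
#' @param age_range_years Range of simulated ages, uniform (default 4 to 6);
#'   age has no generative effect on playtime.
#' @param playtime_scale `"normalized"` (additive Gaussian noise on the
#'   normalized scale, the default) or `"log"` (log-normal noise).
#' @param seed Integer seed; together with the config it fully determines
#'   the generated table.
#' @return A list of class `"shakebox_config"`.
#' @export
generator_config <- function(n_children_per_experiment = 24,
                             contrast_sets = default_contrast_sets(),
                             playtime_slope_theta = 0.24,
                             trial_order_slope = -0.051,
                             content_slope = 0,
                             accuracy_intercept = 0,
                             accuracy_slope = 1.12,
                             child_sd = 0.5,
                             noise_sd = 0.15,
                             base_playtime_s = 10,
                             age_range_years = c(4, 6),
                             playtime_scale = c("normalized", "log"),
                             seed = 1L) {
  playtime_scale <- match.arg(playtime_scale)
  if (!is.list(contrast_sets) || length(contrast_sets) == 0L) {
    stop("configuration error: `contrast_sets` must be a non-empty list", call. = FALSE)
  }
  if (is.null(names(contrast_sets)) || any(names(contrast_sets) == "")) {
    names(contrast_sets) <- paste0("exp", seq_along(contrast_sets) + 3L)
  }
  for (nm in names(contrast_sets)) {
    cs <- validate_contrasts(contrast_sets[[nm]])
    if (nrow(cs) != 4L) {
      stop("configuration error: contrast set `", nm, "` must have exactly 4 contrasts",
           call. = FALSE)
    }
  }
  stopifnot(
    n_children_per_experiment >= 1,
    child_sd >= 0, noise_sd >= 0, base_playtime_s > 0,
    length(age_range_years) == 2L, age_range_years[1] <= age_range_years[2]
  )
  structure(list(
    n_children_per_experiment = as.integer(n_children_per_experiment),
    contrast_sets = contrast_sets,
    playtime_slope_theta = playtime_slope_theta,
    trial_order_slope = trial_order_slope,
    content_slope = content_slope,
    accuracy_intercept = accuracy_intercept,
    accuracy_slope = accuracy_slope,
    child_sd = child_sd,
    noise_sd = noise_sd,
    base_playtime_s = base_playtime_s,
    age_range_years = as.numeric(age_range_years),
    playtime_scale = playtime_scale,
    seed = as.integer(seed)
  ), class = "shakebox_config")
}

# 4x4 Latin square: row r gives the contrast index presented at each of the
# four trial positions for children assigned to row r. Every contrast occupies
# every position exactly once per cycle of four children.
latin_square_4 <- function() {
  matrix(c(
    1, 2, 3, 4,
    2, 4, 1, 3,
    3, 1, 4, 2,
    4, 3, 2, 1
  ), nrow = 4, byrow = TRUE)
}

#' Generate synthetic free-exploration trials
#'
#' Simulates one row per child x trial for the free-exploration experiments.
#' For child i with baseline effect b_i ~ N(0, `child_sd`) and contrast c in
#' trial position j, the expected playtime on the normalized scale is
#'
#'   mu = 1 + theta * (x_c - mean of x over the child's four contrasts)
#'         + trial_order_slope * (j - 2.5)
#'         + content_slope * (hidden_c - mean hidden over the four trials)
#'
#' with x = -d'. Raw seconds are `base_playtime_s * exp(b_i) * max(0.05,
#' mu + e)` with trial noise e ~ N(0, `noise_sd`) (on the log scale instead
#' when `playtime_scale = "log"`); the 0.05 floor keeps playtimes strictly
#' positive. Correct report of the hidden count is Bernoulli with
#' logit(p) = `accuracy_intercept` + `accuracy_slope` * d'.
#'
#' Trial order follows a balanced Latin square and the hidden alternative of
#' each contrast is flipped for alternating blocks of children, so that with
#' a multiple of 4 children per experiment every contrast occupies every
#' position equally often and each alternative is hidden equally often --
#' except in a fixed-content set (attribute `fixed_content`), where the
#' specified hidden counts are kept for every child.
#'
#' @param config A [generator_config()].
#' @return A tibble of trial records: `child_id`, `experiment`,
#'   `trial_order`, `label`, `n_a`, `n_b`, `hidden`, `age_years`,
#'   `playtime_s`, `response_count`, `correct`, with the config's seed in
#'   attribute `seed`.
#' @export
generate_exploration_trials <- function(config = generator_config()) {
  if (!inherits(config, "shakebox_config")) {
    stop("configuration error: `config` must come from generator_config()", call. = FALSE)
  }
  set.seed(config$seed)
  sq <- latin_square_4()
  out <- vector("list", length(config$contrast_sets))
  for (e in seq_along(config$contrast_sets)) {
    exp_name <- names(config$contrast_sets)[e]
    cs <- validate_contrasts(config$contrast_sets[[e]])
    fixed <- isTRUE(attr(config$contrast_sets[[e]], "fixed_content"))
    n_kids <- config$n_children_per_experiment
    d <- dprime(cs)

    child_eff <- stats::rnorm(n_kids, 0, config$child_sd)
    ages <- stats::runif(n_kids, config$age_range_years[1], config$age_range_years[2])

    rows <- vector("list", n_kids)
    for (i in seq_len(n_kids)) {
      order_row <- sq[((i - 1L) %% 4L) + 1L, ]          # contrast index per position
      flip <- ((i - 1L) %/% 4L) %% 2L == 1L             # hidden-side flip block
      c_idx <- order_row
      hid <- cs$hidden[c_idx]
      if (!fixed && flip) {
        other <- ifelse(cs$hidden == cs$n_a, cs$n_b, cs$n_a)
        hid <- other[c_idx]
      }
      x <- -d[c_idx]
      mu <- 1 +
        config$playtime_slope_theta * (x - mean(x)) +
        config$trial_order_slope * (1:4 - 2.5) +
        config$content_slope * (hid - mean(hid))
      if (config$playtime_scale == "log") {
        noisy <- pmax(0.05, mu) * exp(stats::rnorm(4, 0, config$noise_sd))
      } else {
        noisy <- pmax(0.05, mu + stats::rnorm(4, 0, config$noise_sd))
      }
      playtime <- config$base_playtime_s * exp(child_eff[i]) * noisy
      p_corr <- stats::plogis(config$accuracy_intercept + config$accuracy_slope * d[c_idx])
      correct <- stats::rbinom(4, 1, p_corr) == 1L
      other_count <- ifelse(hid == cs$n_a[c_idx], cs$n_b[c_idx], cs$n_a[c_idx])
      rows[[i]] <- tibble::tibble(
        child_id = sprintf("%s_c%02d", exp_name, i),
        experiment = exp_name,
        trial_order = 1:4,
        label = cs$label[c_idx],
        n_a = cs$n_a[c_idx],
        n_b = cs$n_b[c_idx],
        hidden = hid,
        age_years = ages[i],
        playtime_s = playtime,
        response_count = ifelse(correct, hid, other_count),
        correct = correct
      )
    }
    out[[e]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "seed") <- config$seed
  res
}

#' Generate synthetic forced-choice records
#'
#' One row per child; `chose_discriminable` is an i.i.d. Bernoulli draw with
#' success probability `p_correct`, reproducible under `seed`.
#'
#' @param n_children Number of children (rows).
#' @param p_correct Probability of choosing the more discriminable box.
#' @param seed Integer seed.
#' @param experiment Experiment identifier stored in the output.
#' @return A tibble with columns `child_id`, `experiment`,
#'   `chose_discriminable`.
#' @export
generate_choice_trials <- function(n_children, p_correct, seed = 1L,
                                   experiment = "exp1") {
  if (!is.numeric(p_correct) || length(p_correct) != 1L ||
      is.na(p_correct) || p_correct < 0 || p_correct > 1) {
    stop("invalid parameter: `p_correct` must be a probability in [0, 1]", call. = FALSE)
  }
  if (n_children < 1) stop("invalid parameter: `n_children` must be >= 1", call. = FALSE)
  set.seed(seed)
  tibble::tibble(
    child_id = sprintf("%s_c%02d", experiment, seq_len(n_children)),
    experiment = experiment,
    chose_discriminable = stats::rbinom(n_children, 1, p_correct) == 1L
  )
}

trial_csv_columns <- c("child_id", "experiment", "trial_order", "label",
                       "n_a", "n_b", "hidden", "age_years", "playtime_s",
                       "response_count", "correct")

#' Read or write the canonical trial CSV
#'
#' Columns: `child_id`, `experiment`, `trial_order`, `label`, `n_a`, `n_b`,
#' `hidden`, `age_years`, `playtime_s`, `response_count`, `correct`.
#' `read_trials()` validates the schema and errors naming any missing column.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  require_columns(trials, trial_csv_columns, what = "trial table")
  readr::write_csv(trials[trial_csv_columns], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_trials(x)
}

#' @rdname write_trials
#' @param x A data frame to validate against the trial schema.
#' @export
validate_trials <- function(x) {
  require_columns(x, setdiff(trial_csv_columns, "age_years"), what = "trial table")
  if (nrow(x) == 0L) stop("data error: trial table is empty", call. = FALSE)
  if (any(x$playtime_s < 0)) stop("data error: negative playtime_s", call. = FALSE)
  x$correct <- as.logical(x$correct)
  tibble::as_tibble(x)
}

#' Read or write the choice CSV
#'
#' Columns: `child_id`, `experiment`, `chose_discriminable`.
#'
#' @param choices A choice tibble.
#' @param path File path.
#' @export
write_choices <- function(choices, path) {
  require_columns(choices, c("child_id", "experiment", "chose_discriminable"),
                  what = "choice table")
  readr::write_csv(choices, path)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(x, c("child_id", "experiment", "chose_discriminable"),
                  what = "choice table")
  x$chose_discriminable <- as.logical(x$chose_discriminable)
  tibble::as_tibble(x)
}
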