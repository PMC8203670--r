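#' Sample proportion with a binomial confidence interval
#'
#' Computes the proportion of successes with a 95% confidence interval,
#' either the Bernoulli normal approximation
#' `p_hat +/- 1.96 * sqrt(p_hat (1 - p_hat) / n)` clipped to `[0, 1]`
#' (z fixed at 1.96 for reproducibility of reported intervals), or the exact
#' Clopper-Pearson interval from [stats::binom.test()]. A degenerate normal
#' interval at `p_hat` of 0 or 1 has zero width and is flagged in `note`.
#'
#' Supply either a choice table (successes counted from
#' `chose_discriminable`) or `k` and `n` directly.
#'
#' @param choices Optional choice table (see [read_choices()]).
#' @param k,n Integer count of successes and trials.
#' @param method `"normal_approx"` or `"exact_binomial"`.
#' @return A one-row tibble: `k`, `n`, `p_hat`, `ci_low`, `ci_high`,
#'   `method`, `note`.
#' @examples
#' proportion_with_ci(k = 18, n = 24)  # 75%, CI ~ [0.58, 0.92]
#' @export
proportion_with_ci <- function(choices = NULL, k = NULL, n = NULL,
                               method = c("normal_approx", "exact_binomial")) {
  method <- match.arg(method)
  if (!is.null(choices)) {
    require_columns(choices, "chose_discriminable", what = "choice table")
    if (nrow(choices) == 0L) stop("data error: empty choice table", call. = FALSE)
    k <- sum(choices$chose_discriminable)
    n <- nrow(choices)
  }
  if (is.null(k) || is.null(n) || n < 1 || k < 0 || k > n) {
    stop("data error: need 0 <= k <= n with n >= 1", call. = FALSE)
  }
  p_hat <- k / n
  note <- NA_character_
  if (method == "normal_approx") {
    half <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
    lo <- max(0, p_hat - half)
    hi <- min(1, p_hat + half)
    if (p_hat %in% c(0, 1)) note <- "degenerate zero-width normal interval"
    else if (hi == 1 || lo == 0) note <- "interval clipped to [0, 1]"
  } else {
    ci <- stats::binom.test(k, n)$conf.int
    lo <- ci[1]
    hi <- ci[2]
  }
  tibble::tibble(k = as.integer(k), n = as.integer(n), p_hat = p_hat,
                 ci_low = lo, ci_high = hi, method = method, note = note)
}

#' Exact binomial test against a chance level
#'
#' Two-sided exact binomial p-value for observing `k` successes in `n`
#' trials when the chance probability is `chance`. Uses the "minlike"
#' two-sided convention (sum of all outcome probabilities no larger than
#' that of the observed count), as implemented by [stats::binom.test()].
#'
#' @param k,n Successes and trials.
#' @param chance Null success probability, strictly between 0 and 1
#'   (default 0.5).
#' @return The two-sided p-value.
#' @examples
#' binomial_test_vs_chance(24, 24)  # 2 * 0.5^24
#' @export
binomial_test_vs_chance <- function(k, n, chance = 0.5) {
  if (n < 1 || k < 0 || k > n) stop("data error: need 0 <= k <= n", call. = FALSE)
  if (chance <= 0 || chance >= 1) {
    stop("invalid parameter: `chance` must lie strictly between 0 and 1", call. = FALSE)
  }
  stats::binom.test(k, n, p = chance, alternative = "two.sided")$p.value
}

#' Per-experiment choice proportions
#'
#' Summarises a forced-choice table: for each experiment, the proportion of
#' children choosing the more discriminable box, its binomial CI, and the
#' two-sided exact binomial p-value against 0.5 chance.
#'
#' @param choices A choice table (see [read_choices()]).
#' @param method CI method, as in [proportion_with_ci()].
#' @return A tibble with one row per experiment: `experiment`, `k`, `n`,
#'   `p_hat`, `ci_low`, `ci_high`, `method`, `p_value`, `note`.
#' @export
summarize_choices <- function(choices, method = c("normal_approx", "exact_binomial")) {
  method <- match.arg(method)
  require_columns(choices, c("experiment", "chose_discriminable"),
                  what = "choice table")
  if (nrow(choices) == 0L) stop("data error: empty choice table", call. = FALSE)
  choices |>
    dplyr::group_by(.data$experiment) |>
    dplyr::group_modify(function(df, key) {
      pr <- proportion_with_ci(k = sum(df$chose_discriminable), n = nrow(df),
                               method = method)
      pr$p_value <- binomial_test_vs_chance(pr$k, pr$n, 0.5)
      pr
    }) |>
    dplyr::ungroup()
}

#' Round half away from zero
#'
#' Display rounding for reported proportions: 0.925 rounds to 0.93 at two
#' decimals (unlike base [round()], which rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # small offset absorbs representation error in x * scale (e.g. 0.575 * 100)
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}
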