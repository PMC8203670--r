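#' Compare difficulty models as predictors of exploration
#'
#' Pits the signal-detection d' model against the heuristic alternatives
#' (absolute difference, negative ratio) as predictors of normalized
#' playtime. Each model's easiness score is negated so that larger predictor
#' values mean harder discriminations and all fitted slopes are
#' positive-signed and comparable. For every model the function reports:
#'
#' \describe{
#'   \item{`r_condition_means`}{Pearson correlation between per-contrast
#'     mean normalized playtime and the model's difficulty predictor.}
#'   \item{`r2_trial_level`}{R-squared of the trial-level OLS fit.}
#'   \item{`aic_trial_level`}{AIC of the same fit (Gaussian likelihood on
#'     the normalized scale), computed on an identical observation set for
#'     every model.}
#'   \item{`rank_agreement_with_dprime`}{Spearman correlation between the
#'     contrast ordering induced by the model and by d'. Always 1 for
#'     `neg_ratio` (both are monotone in max/min); `abs_diff` can misorder
#'     contrasts such as 9-vs-5 and 2-vs-1.}
#' }
#'
#' @inheritParams fit_playtime_regression
#' @param models Character vector of registered difficulty models (default
#'   all three).
#' @return A tibble with one row per model.
#' @export
compare_models <- function(norm_trials,
                           models = c("dprime", "abs_diff", "neg_ratio"),
                           sigma = 1) {
  known <- c("dprime", "abs_diff", "neg_ratio")
  if (length(models) < 2L) {
    stop("configuration error: need at least 2 models to compare", call. = FALSE)
  }
  if (!all(models %in% known)) {
    stop("configuration error: unknown model(s): ",
         paste(setdiff(models, known), collapse = ", "), call. = FALSE)
  }
  require_columns(norm_trials, c("normalized_playtime", "n_a", "n_b", "hidden"),
                  what = "normalized trial table")
  ctab <- norm_trials[c("label", "n_a", "n_b", "hidden")]
  key <- paste(pmax(norm_trials$n_a, norm_trials$n_b),
               pmin(norm_trials$n_a, norm_trials$n_b), sep = "v")
  if (length(unique(key)) < 3L) {
    stop("data error: need at least 3 distinct contrasts", call. = FALSE)
  }
  y <- norm_trials$normalized_playtime
  uniq <- !duplicated(key)
  dprime_scores_uniq <- dprime(ctab[uniq, ])

  rows <- lapply(models, function(m) {
    score <- difficulty_score(ctab, m, sigma = sigma)
    x <- -score                       # larger = harder
    fit <- stats::lm(y ~ x)
    cm <- tapply(y, key, mean)
    xm <- tapply(x, key, function(v) v[1])
    tibble::tibble(
      model_name = m,
      r_condition_means = stats::cor(as.numeric(cm), as.numeric(xm)),
      r2_trial_level = summary(fit)$r.squared,
      aic_trial_level = stats::AIC(fit),
      rank_agreement_with_dprime = stats::cor(
        score[uniq], dprime_scores_uniq, method = "spearman")
    )
  })
  dplyr::bind_rows(rows)
}
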