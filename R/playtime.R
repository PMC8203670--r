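#' Normalize playtimes within child
#'
#' Converts each child's raw playtime on each trial into a proportion of
#' that child's total playtime across their trials, multiplied by the number
#' of trials, so the per-child mean is exactly 1: values above 1 mean more
#' than an even share of that child's play. This removes individual
#' differences in overall exploratory tempo before any regression.
#'
#' Children whose total playtime is zero cannot be normalized and are
#' dropped with a warning.
#'
#' @param trials A trial table (see [read_trials()]).
#' @return The table with a `normalized_playtime` column appended.
#' @examples
#' \dontrun{
#' norm <- normalize_playtimes(generate_exploration_trials())
#' }
#' @export
normalize_playtimes <- function(trials) {
  trials <- validate_trials(trials)
  out <- trials |>
    dplyr::group_by(.data$experiment, .data$child_id) |>
    dplyr::mutate(
      .total = sum(.data$playtime_s),
      normalized_playtime = dplyr::n() * .data$playtime_s / .data$.total
    ) |>
    dplyr::ungroup()
  zero <- out$.total == 0
  if (any(zero)) {
    dropped <- unique(out$child_id[zero])
    warning("excluding ", length(dropped),
            " child(ren) with zero total playtime: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    out <- out[!zero, , drop = FALSE]
  }
  out$.total <- NULL
  out
}

child_uid <- function(x) paste(x$experiment, x$child_id, sep = "/")

new_fit_result <- function(predictor, beta, ci_low, ci_high, estimator,
                           clustering, n_obs, n_children, converged = TRUE,
                           note = NA_character_) {
  tibble::tibble(
    predictor = predictor, beta = beta, ci_low = ci_low, ci_high = ci_high,
    estimator = estimator, clustering = clustering,
    n_obs = n_obs, n_children = n_children,
    converged = converged, note = note
  )
}

# Cluster-robust 95% Wald CI for the slope of a fitted lm/glm.
# Uses the CR1 small-sample correction from sandwich::vcovCL and a
# t quantile on G - 1 degrees of freedom (G = number of clusters).
cluster_ci <- function(fit, cluster, term) {
  g <- length(unique(cluster))
  if (g < 2L) {
    stop("degenerate clustering: need at least 2 children for clustered standard errors",
         call. = FALSE)
  }
  V <- sandwich::vcovCL(fit, cluster = cluster)
  se <- sqrt(V[term, term])
  beta <- stats::coef(fit)[[term]]
  crit <- stats::qt(0.975, df = g - 1L)
  c(beta = beta, lo = beta - crit * se, hi = beta + crit * se)
}

#' Regression of normalized playtime on a design predictor
#'
#' The workhorse of the exploration-time analysis: an ordinary least squares
#' fit of normalized playtime on a single predictor, with child-clustered
#' standard errors (children contribute four correlated trials each).
#' A per-child random-intercept mixed model is available as an alternative
#' estimator; normalization already removes child intercepts, so clustered
#' OLS is the default.
#'
#' Predictors:
#' \describe{
#'   \item{`neg_dprime`}{-d' of the trial's contrast, natural-log units
#'     (unstandardized). A positive slope means longer exploration of less
#'     discriminable contrasts.}
#'   \item{`hidden_count`}{the count actually in the box; a null effect is
#'     the signature that exploration tracks the contrast, not the content.}
#'   \item{`trial_order`}{trial position 1-4.}
#'   \item{`age`}{age in years (requires an `age_years` column).}
#' }
#'
#' @param norm_trials Output of [normalize_playtimes()].
#' @param predictor One of `"neg_dprime"`, `"hidden_count"`,
#'   `"trial_order"`, `"age"`.
#' @param sigma Internal-noise SD used to compute d' (default 1).
#' @param estimator `"ols_cluster"` (default) or `"mixed"` (random intercept
#'   per child via [lme4::lmer()], Wald CI).
#' @return A one-row tibble: `predictor`, `beta`, `ci_low`, `ci_high`
#'   (95% CI), `estimator`, `clustering`, `n_obs`, `n_children`,
#'   `converged`, `note`.
#' @export
fit_playtime_regression <- function(norm_trials,
                                    predictor = c("neg_dprime", "hidden_count",
                                                  "trial_order", "age"),
                                    sigma = 1,
                                    estimator = c("ols_cluster", "mixed")) {
  predictor <- match.arg(predictor)
  estimator <- match.arg(estimator)
  require_columns(norm_trials, "normalized_playtime", what = "normalized trial table")
  if (any(is.na(norm_trials$normalized_playtime))) {
    stop("data error: missing normalized playtimes", call. = FALSE)
  }
  x <- switch(predictor,
    neg_dprime = -dprime(norm_trials[c("label", "n_a", "n_b", "hidden")], sigma = sigma),
    hidden_count = norm_trials$hidden,
    trial_order = norm_trials$trial_order,
    age = {
      require_columns(norm_trials, "age_years", what = "trial table (predictor `age`)")
      norm_trials$age_years
    }
  )
  if (length(unique(x)) < 2L) {
    stop("degenerate design: predictor `", predictor, "` is constant", call. = FALSE)
  }
  y <- norm_trials$normalized_playtime
  cl <- child_uid(norm_trials)
  n_children <- length(unique(cl))
  if (estimator == "mixed") {
    dat <- data.frame(y = y, x = x, child = cl)
    fit <- lme4::lmer(y ~ x + (1 | child), data = dat, REML = TRUE)
    beta <- lme4::fixef(fit)[["x"]]
    se <- sqrt(as.matrix(stats::vcov(fit))["x", "x"])
    ci <- c(beta - 1.96 * se, beta + 1.96 * se)
    return(new_fit_result(predictor, beta, ci[1], ci[2], "mixed",
                          "random_intercept", length(y), n_children))
  }
  fit <- stats::lm(y ~ x)
  ci <- cluster_ci(fit, cl, "x")
  new_fit_result(predictor, ci[["beta"]], ci[["lo"]], ci[["hi"]],
                 "ols_cluster", "child", length(y), n_children)
}

#' Logistic regression of trial correctness on discriminability
#'
#' Fits `correct ~ d'` by maximum-likelihood logistic regression with
#' child-clustered standard errors. The slope is in log-odds of a correct
#' report per unit d'. Perfect separation (or an all-correct/all-wrong
#' outcome column) is reported as a flagged, non-converged fit rather than
#' an error.
#'
#' @param trials A trial table with a `correct` column.
#' @param sigma Internal-noise SD for d' (default 1).
#' @return A one-row fit tibble (see [fit_playtime_regression()]).
#' @export
fit_accuracy_regression <- function(trials, sigma = 1) {
  trials <- validate_trials(trials)
  d <- dprime(trials[c("label", "n_a", "n_b", "hidden")], sigma = sigma)
  if (length(unique(d)) < 2L) {
    stop("degenerate design: d' is constant across trials", call. = FALSE)
  }
  y <- as.integer(trials$correct)
  cl <- child_uid(trials)
  n_children <- length(unique(cl))
  separated <- length(unique(y)) < 2L
  fit <- suppressWarnings(stats::glm(y ~ d, family = stats::binomial()))
  probs <- stats::fitted(fit)
  separated <- separated || !fit$converged ||
    any(probs > 1 - 1e-8) || any(probs < 1e-8) || abs(stats::coef(fit)[["d"]]) > 15
  if (separated) {
    return(new_fit_result("dprime", stats::coef(fit)[["d"]], NA_real_, NA_real_,
                          "logistic_cluster", "child", length(y), n_children,
                          converged = FALSE, note = "separation"))
  }
  ci <- cluster_ci(fit, cl, "d")
  new_fit_result("dprime", ci[["beta"]], ci[["lo"]], ci[["hi"]],
                 "logistic_cluster", "child", length(y), n_children)
}

#' Correlation between condition-mean playtimes and the model
#'
#' Averages normalized playtime within each contrast (pooled over
#' experiments) and reports the Pearson correlation of those condition means
#' with -d', with its 95% CI from [stats::cor.test()]. This is the
#' condition-level summary of how tightly exploration tracks predicted
#' difficulty.
#'
#' @inheritParams fit_playtime_regression
#' @return A one-row tibble: `predictor = "neg_dprime_condition_means"`,
#'   `beta` holding r, `ci_low`, `ci_high`, `n_obs` = number of contrasts.
#' @export
condition_mean_correlation <- function(norm_trials, sigma = 1) {
  require_columns(norm_trials, c("normalized_playtime", "n_a", "n_b"),
                  what = "normalized trial table")
  key <- paste(pmax(norm_trials$n_a, norm_trials$n_b),
               pmin(norm_trials$n_a, norm_trials$n_b), sep = "v")
  means <- norm_trials |>
    dplyr::mutate(.key = key,
                  .x = -dprime(norm_trials[c("label", "n_a", "n_b", "hidden")],
                               sigma = sigma)) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(mean_play = mean(.data$normalized_playtime),
                     x = .data$.x[1], .groups = "drop")
  if (nrow(means) < 3L) {
    stop("data error: need at least 3 distinct contrasts", call. = FALSE)
  }
  if (stats::sd(means$mean_play) == 0 || stats::sd(means$x) == 0) {
    stop("undefined correlation: zero variance in condition means", call. = FALSE)
  }
  ct <- stats::cor.test(means$mean_play, means$x)
  r <- unname(ct$estimate)
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  new_fit_result("neg_dprime_condition_means", r, ci[1], ci[2],
                 "pearson", "none", nrow(means),
                 length(unique(child_uid(norm_trials))))
}

#' Per-child slopes of playtime on discrimination difficulty
#'
#' For each child, fits an ordinary least squares line of normalized
#' playtime on -d' across that child's trials. A positive slope means the
#' child explored longer on harder (less discriminable) contrasts,
#' qualitatively following the discriminability model. Returns the count
#' and proportion of positive slopes with a binomial confidence interval.
#' Children whose trials all share one d' value have no defined slope and
#' are excluded with a warning.
#'
#' @inheritParams fit_playtime_regression
#' @param ci_method `"normal_approx"` or `"exact_binomial"` (Clopper-Pearson)
#'   for the CI on the proportion of positive slopes.
#' @return A list of class `"shakebox_slopes"`: `per_child_slopes` (tibble
#'   of `child_id`, `experiment`, `slope`), `k_positive`, `n`, `proportion`,
#'   `ci_low`, `ci_high`, `ci_method`.
#' @export
individual_slopes <- function(norm_trials, sigma = 1,
                              ci_method = c("normal_approx", "exact_binomial")) {
  ci_method <- match.arg(ci_method)
  require_columns(norm_trials, "normalized_playtime", what = "normalized trial table")
  norm_trials$.x <- -dprime(norm_trials[c("label", "n_a", "n_b", "hidden")],
                            sigma = sigma)
  slopes <- norm_trials |>
    dplyr::group_by(.data$experiment, .data$child_id) |>
    dplyr::summarise(
      slope = if (length(unique(.data$.x)) < 2L) NA_real_ else
        stats::cov(.data$normalized_playtime, .data$.x) / stats::var(.data$.x),
      .groups = "drop"
    )
  if (any(is.na(slopes$slope))) {
    bad <- slopes$child_id[is.na(slopes$slope)]
    warning("excluding ", length(bad), " child(ren) with constant d' across trials: ",
            paste(bad, collapse = ", "), call. = FALSE)
    slopes <- slopes[!is.na(slopes$slope), , drop = FALSE]
  }
  k <- sum(slopes$slope > 0)
  n <- nrow(slopes)
  prop <- proportion_with_ci(k = k, n = n, method = ci_method)
  structure(list(
    per_child_slopes = slopes,
    k_positive = k, n = n,
    proportion = prop$p_hat,
    ci_low = prop$ci_low, ci_high = prop$ci_high,
    ci_method = ci_method
  ), class = "shakebox_slopes")
}

#' @export
print.shakebox_slopes <- function(x, ...) {
  cat(sprintf(
    "Individual slopes: %d/%d children positive (%.1f%%; 95%% CI [%.2f, %.2f], %s)\n",
    x$k_positive, x$n, 100 * x$proportion, x$ci_low, x$ci_high, x$ci_method))
  invisible(x)
}
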