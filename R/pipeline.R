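#' Read a generator configuration from a YAML or JSON file
#'
#' The file may set any argument of [generator_config()]; `contrast_sets`
#' is given as a named list of records with `n_a`, `n_b` and optionally
#' `hidden`, `label` and `fixed_content`. Unknown keys raise a
#' configuration error naming the offender.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `shakebox_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("configuration error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$contrast_sets)) {
    raw$contrast_sets <- lapply(raw$contrast_sets, function(cs) {
      cs <- as.data.frame(cs)
      fixed <- isTRUE(cs$fixed_content[1])
      cs$fixed_content <- NULL
      out <- contrasts_tbl(cs$n_a, cs$n_b,
                           hidden = if (is.null(cs$hidden)) cs$n_a else cs$hidden,
                           label = cs$label)
      if (fixed) attr(out, "fixed_content") <- TRUE
      out
    })
  }
  do.call(generator_config, raw)
}

default_choice_designs <- function() {
  tibble::tibble(
    experiment = c("exp1", "exp2", "exp3"),
    n_children = c(16L, 24L, 24L),
    p_correct = c(0.812, 0.79, 0.75)
  )
}

write_manifest <- function(out_dir, stage, config, seed, files) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("shakebox")),
    seed = seed,
    config = config_to_list(config),
    files = as.list(files),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_to_list <- function(config) {
  if (is.null(config)) return(NULL)
  out <- unclass(config)
  out$contrast_sets <- lapply(out$contrast_sets, function(cs) {
    l <- as.list(cs)
    if (isTRUE(attr(cs, "fixed_content"))) l$fixed_content <- TRUE
    l
  })
  out
}

stage_log <- function(...) message("[shakebox] ", sprintf(...))

#' Simulate stage: write synthetic trial and choice CSVs
#'
#' Generates the free-exploration trial table and the forced-choice tables
#' under the given configuration and writes `trials.csv`, `choices.csv`
#' and a JSON run manifest into `out_dir`.
#'
#' @param config A [generator_config()], or a path to a YAML/JSON config
#'   file.
#' @param out_dir Output directory (created if needed).
#' @param choice_designs Tibble with columns `experiment`, `n_children`,
#'   `p_correct` for the forced-choice simulations; defaults to three
#'   experiments (n = 16, 24, 24 at success probabilities .812, .79, .75).
#' @return Invisibly, a named list of written file paths.
#' @export
run_simulate <- function(config = generator_config(), out_dir = ".",
                         choice_designs = default_choice_designs()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- generate_exploration_trials(config)
  choices <- dplyr::bind_rows(lapply(seq_len(nrow(choice_designs)), function(i) {
    generate_choice_trials(choice_designs$n_children[i],
                           choice_designs$p_correct[i],
                           seed = config$seed + i,
                           experiment = choice_designs$experiment[i])
  }))
  files <- list(trials = file.path(out_dir, "trials.csv"),
                choices = file.path(out_dir, "choices.csv"))
  write_trials(trials, files$trials)
  write_choices(choices, files$choices)
  write_manifest(out_dir, "simulate", config, config$seed, files)
  stage_log("simulate: %d trial rows, %d choice rows (seed %d) -> %s",
            nrow(trials), nrow(choices), config$seed, out_dir)
  invisible(files)
}

#' Analyze stage: regression battery, slopes, proportions, figures
#'
#' Runs the full exploration-time and forced-choice analysis on a trial CSV
#' (and optionally a choice CSV): playtime normalization, the regression
#' battery (discriminability, hidden count, trial order, age when present,
#' and the accuracy logistic), the condition-mean correlation, per-child
#' slopes, and choice proportions. Writes `fits.csv`, `slopes.csv`,
#' `proportions.csv` (when choices are given) and three diagnostic figures.
#'
#' @param trials_csv Path to a canonical trial CSV.
#' @param choices_csv Optional path to a choice CSV.
#' @param out_dir Output directory.
#' @param sigma Internal-noise SD for d' (default 1).
#' @param ci_method Binomial CI method for proportions and slope counts.
#' @param estimator Playtime regression estimator (see
#'   [fit_playtime_regression()]).
#' @param figures Write PDF figures (default TRUE).
#' @return Invisibly, a list with the fits, slopes and proportions tables
#'   and written file paths.
#' @export
run_analyze <- function(trials_csv, choices_csv = NULL, out_dir = ".",
                        sigma = 1,
                        ci_method = c("normal_approx", "exact_binomial"),
                        estimator = c("ols_cluster", "mixed"),
                        figures = TRUE) {
  ci_method <- match.arg(ci_method)
  estimator <- match.arg(estimator)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_trials(trials_csv)
  norm <- normalize_playtimes(trials)

  predictors <- c("neg_dprime", "hidden_count", "trial_order")
  if ("age_years" %in% names(norm)) predictors <- c(predictors, "age")
  fits <- dplyr::bind_rows(
    lapply(predictors, function(p) {
      fit_playtime_regression(norm, p, sigma = sigma, estimator = estimator)
    }),
    fit_accuracy_regression(trials, sigma = sigma),
    condition_mean_correlation(norm, sigma = sigma)
  )
  slopes <- individual_slopes(norm, sigma = sigma, ci_method = ci_method)
  slope_tbl <- slopes$per_child_slopes

  files <- list(fits = file.path(out_dir, "fits.csv"),
                slopes = file.path(out_dir, "slopes.csv"))
  readr::write_csv(fits, files$fits)
  readr::write_csv(slope_tbl, files$slopes)

  props <- NULL
  if (!is.null(choices_csv)) {
    props <- summarize_choices(read_choices(choices_csv), method = ci_method)
    files$proportions <- file.path(out_dir, "proportions.csv")
    readr::write_csv(props, files$proportions)
  }
  if (figures) {
    files$fig_condition_means <- file.path(out_dir, "fig_condition_means.pdf")
    files$fig_hidden_count <- file.path(out_dir, "fig_hidden_count.pdf")
    files$fig_child_slopes <- file.path(out_dir, "fig_child_slopes.pdf")
    ggplot2::ggsave(files$fig_condition_means, plot_condition_means(norm, sigma),
                    width = 6, height = 4)
    ggplot2::ggsave(files$fig_hidden_count, plot_hidden_count(norm),
                    width = 6, height = 4)
    ggplot2::ggsave(files$fig_child_slopes, plot_child_slopes(slope_tbl),
                    width = 6, height = 4)
  }
  write_manifest(out_dir, "analyze", NULL, NA, files)
  stage_log("analyze: %d fits, %d child slopes (%d positive)%s -> %s",
            nrow(fits), slopes$n, slopes$k_positive,
            if (is.null(props)) "" else sprintf(", %d choice experiments", nrow(props)),
            out_dir)
  invisible(list(fits = fits, slopes = slopes, proportions = props, files = files))
}

#' Compare stage: difficulty-model comparison table
#'
#' @param trials_csv Path to a canonical trial CSV.
#' @param out_dir Output directory.
#' @param sigma Internal-noise SD for d'.
#' @return Invisibly, the comparison tibble (also written to
#'   `comparison.csv`).
#' @export
run_compare <- function(trials_csv, out_dir = ".", sigma = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  norm <- normalize_playtimes(read_trials(trials_csv))
  comp <- compare_models(norm, sigma = sigma)
  path <- file.path(out_dir, "comparison.csv")
  readr::write_csv(comp, path)
  write_manifest(out_dir, "compare", NULL, NA, list(comparison = path))
  stage_log("compare: %d models -> %s", nrow(comp), path)
  invisible(comp)
}

#' Report stage: human-readable markdown summary
#'
#' Collates the CSV outputs of the analyze and compare stages into a single
#' markdown report listing every fitted coefficient with its CI, the
#' per-child slope summary, the choice proportions, and the
#' model-comparison table. Errors if an upstream output is missing.
#'
#' @param out_dir Directory holding `fits.csv`, `slopes.csv` and optionally
#'   `proportions.csv`, `comparison.csv`.
#' @return Invisibly, the path of the written `report.md`.
#' @export
run_report <- function(out_dir = ".") {
  need <- file.path(out_dir, c("fits.csv", "slopes.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("pipeline-order error: missing upstream output(s): ",
         paste(basename(missing), collapse = ", "),
         " -- run the analyze stage first", call. = FALSE)
  }
  fits <- readr::read_csv(need[1], show_col_types = FALSE)
  slopes <- readr::read_csv(need[2], show_col_types = FALSE)

  fmt_ci <- function(lo, hi) sprintf("[%.3f, %.3f]", lo, hi)
  lines <- c(
    "# Shaking-box analysis report", "",
    "## Fitted coefficients (95% CI)", "")
  for (i in seq_len(nrow(fits))) {
    f <- fits[i, ]
    stat <- if (f$predictor == "neg_dprime_condition_means") "r" else "beta"
    lines <- c(lines, sprintf(
      "- %s: %s = %.4f %s (%s, n_obs = %d, n_children = %d)%s",
      f$predictor, stat, f$beta,
      if (is.na(f$ci_low)) "[CI unavailable]" else fmt_ci(f$ci_low, f$ci_high),
      f$estimator, f$n_obs, f$n_children,
      if (!f$converged) " [FLAG: non-converged/separation]" else ""))
  }
  k <- sum(slopes$slope > 0)
  lines <- c(lines, "", "## Individual slopes", "",
             sprintf("- %d/%d children (%.0f%%) have a positive slope of playtime on -d'",
                     k, nrow(slopes), 100 * k / nrow(slopes)))

  prop_path <- file.path(out_dir, "proportions.csv")
  if (file.exists(prop_path)) {
    props <- readr::read_csv(prop_path, show_col_types = FALSE)
    lines <- c(lines, "", "## Forced-choice proportions", "")
    for (i in seq_len(nrow(props))) {
      p <- props[i, ]
      lines <- c(lines, sprintf(
        "- %s: %d/%d chose the discriminable box (%.0f%%; 95%% CI [%.2f-%.2f], %s; exact binomial p vs 0.5 = %.3g)%s",
        p$experiment, p$k, p$n, 100 * p$p_hat,
        round_half_up(p$ci_low), round_half_up(p$ci_high), p$method, p$p_value,
        if (!is.na(p$note)) paste0(" [", p$note, "]") else ""))
    }
  }
  comp_path <- file.path(out_dir, "comparison.csv")
  if (file.exists(comp_path)) {
    comp <- readr::read_csv(comp_path, show_col_types = FALSE)
    lines <- c(lines, "", "## Difficulty-model comparison", "",
               "| model | r (condition means) | R2 (trial) | AIC | rank agreement with d' |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(comp))) {
      m <- comp[i, ]
      lines <- c(lines, sprintf("| %s | %.3f | %.3f | %.1f | %.3f |",
                                m$model_name, m$r_condition_means, m$r2_trial_level,
                                m$aic_trial_level, m$rank_agreement_with_dprime))
    }
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  stage_log("report -> %s", path)
  invisible(path)
}

#' Run the full pipeline: simulate, analyze, compare, report
#'
#' @inheritParams run_simulate
#' @inheritParams run_analyze
#' @return Invisibly, the path of the final report.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = ".",
                         sigma = 1,
                         ci_method = c("normal_approx", "exact_binomial"),
                         estimator = c("ols_cluster", "mixed"),
                         figures = TRUE) {
  files <- run_simulate(config, out_dir)
  run_analyze(files$trials, files$choices, out_dir, sigma = sigma,
              ci_method = ci_method, estimator = estimator, figures = figures)
  run_compare(files$trials, out_dir, sigma = sigma)
  run_report(out_dir)
}

plot_condition_means <- function(norm, sigma = 1) {
  norm$neg_d <- -dprime(norm[c("label", "n_a", "n_b", "hidden")], sigma = sigma)
  cm <- norm |>
    dplyr::group_by(.data$label, .data$neg_d) |>
    dplyr::summarise(mean_play = mean(.data$normalized_playtime),
                     sem = stats::sd(.data$normalized_playtime) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$neg_d, y = .data$mean_play)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_play - .data$sem,
                                        ymax = .data$mean_play + .data$sem),
                           width = 0.03, color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "steelblue") +
    ggplot2::labs(x = expression(-d * minute ~ "(difficulty)"),
                  y = "Mean normalized playtime",
                  title = "Exploration tracks discrimination difficulty") +
    ggplot2::theme_minimal()
}

plot_hidden_count <- function(norm) {
  cm <- norm |>
    dplyr::group_by(.data$hidden) |>
    dplyr::summarise(mean_play = mean(.data$normalized_playtime),
                     sem = stats::sd(.data$normalized_playtime) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$hidden, y = .data$mean_play)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_play - .data$sem,
                                        ymax = .data$mean_play + .data$sem),
                           width = 0.15, color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Hidden count (marbles)", y = "Mean normalized playtime",
                  title = "Exploration vs. actual box content") +
    ggplot2::theme_minimal()
}

plot_child_slopes <- function(slope_tbl) {
  ggplot2::ggplot(slope_tbl, ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~experiment) +
    ggplot2::labs(x = "Per-child slope of normalized playtime on -d'",
                  y = "Children",
                  title = "Individual conformity to the discriminability model") +
    ggplot2::theme_minimal()
}
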