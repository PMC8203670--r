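#' Build a table of numerosity contrasts
#'
#' A contrast is a pair of candidate numerosities (counts of marbles) of which
#' one is actually hidden in the box. It is the unit of discriminability for
#' all difficulty models in the package.
#'
#' @param n_a,n_b Positive integer vectors: the two candidate counts.
#' @param hidden Positive integer vector, each element equal to the
#'   corresponding `n_a` or `n_b`: the count actually in the box. Defaults to
#'   `n_a`.
#' @param label Character vector of identifiers; auto-generated as
#'   `"<n_a>v<n_b>"` when omitted.
#' @return A tibble with columns `label`, `n_a`, `n_b`, `hidden`.
#' @examples
#' contrasts_tbl(n_a = c(8, 8), n_b = c(2, 6))
#' @export
contrasts_tbl <- function(n_a, n_b, hidden = n_a, label = NULL) {
  if (is.null(label)) label <- paste0(n_a, "v", n_b)
  out <- tibble::tibble(
    label = as.character(label),
    n_a = as.numeric(n_a),
    n_b = as.numeric(n_b),
    hidden = as.numeric(hidden)
  )
  validate_contrasts(out)
}

#' @rdname contrasts_tbl
#' @param x A data frame to validate against the contrast schema.
#' @export
validate_contrasts <- function(x) {
  require_columns(x, c("label", "n_a", "n_b", "hidden"), what = "contrast table")
  check_positive_counts(x$n_a, "n_a")
  check_positive_counts(x$n_b, "n_b")
  bad <- x$hidden != x$n_a & x$hidden != x$n_b
  if (any(bad)) {
    stop("invalid contrast: `hidden` must equal `n_a` or `n_b` (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  tibble::as_tibble(x)
}

check_positive_counts <- function(n, name) {
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("invalid parameter: `", name, "` must be a positive count", call. = FALSE)
  }
  invisible(n)
}

#' Signal-detection discriminability of a numerosity contrast
#'
#' Under the approximate-number-system model, the internal representation of a
#' count n is Gaussian on a log scale with mean log(n) and common standard
#' deviation `sigma`. The discriminability of a pair (a, b) is then the
#' standard index d' = |log(a) - log(b)| / sigma. It is symmetric, independent
#' of which alternative is hidden, and scale invariant (Weber's law):
#' multiplying both counts by a constant leaves d' unchanged.
#'
#' @param contrasts A contrast table (see [contrasts_tbl()]), or a numeric
#'   vector of first counts when `n_b` is supplied.
#' @param n_b Optional numeric vector of second counts (scalar interface).
#' @param sigma Positive internal-noise standard deviation on the log scale
#'   (dimensionless). Default 1 so d' is reported in natural-log units.
#' @return Numeric vector of nonnegative d' values, in units of `sigma`.
#' @examples
#' dprime(8, 2)               # log(4) ~ 1.386
#' dprime(contrasts_tbl(9, 3), sigma = 2)
#' @export
dprime <- function(contrasts, n_b = NULL, sigma = 1) {
  counts <- resolve_pair(contrasts, n_b)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("invalid parameter: `sigma` must be a positive number", call. = FALSE)
  }
  # |log a - log b| computed as log(max/min): algebraically identical, but the
  # ratio form keeps equal-ratio pairs (2v1, 4v2, ...) exactly tied in floating
  # point, so orderings agree bit-for-bit with the ratio heuristic.
  log(pmax(counts$a, counts$b) / pmin(counts$a, counts$b)) / sigma
}

#' Heuristic difficulty scores for numerosity contrasts
#'
#' Two heuristic alternatives to the signal-detection model: the absolute
#' difference of the two counts, and the negative ratio -min/max. Both are
#' oriented so that a larger score means an easier discrimination; the
#' identical pair is the hardest case under every model (`abs_diff` 0,
#' `neg_ratio` -1, `dprime` 0).
#'
#' @inheritParams dprime
#' @return Numeric vector: `abs_diff()` in marbles (nonnegative);
#'   `neg_ratio()` in (-1, 0] with -1 at an identical pair.
#' @examples
#' abs_diff(8, 2)   # 6
#' neg_ratio(8, 2)  # -0.25
#' @export
abs_diff <- function(contrasts, n_b = NULL) {
  counts <- resolve_pair(contrasts, n_b)
  abs(counts$a - counts$b)
}

#' @rdname abs_diff
#' @export
neg_ratio <- function(contrasts, n_b = NULL) {
  counts <- resolve_pair(contrasts, n_b)
  -pmin(counts$a, counts$b) / pmax(counts$a, counts$b)
}

resolve_pair <- function(contrasts, n_b) {
  if (is.data.frame(contrasts)) {
    contrasts <- validate_contrasts(contrasts)
    list(a = contrasts$n_a, b = contrasts$n_b)
  } else {
    if (is.null(n_b)) {
      stop("supply a contrast table, or both `contrasts` (= n_a) and `n_b`",
           call. = FALSE)
    }
    check_positive_counts(contrasts, "n_a")
    check_positive_counts(n_b, "n_b")
    list(a = as.numeric(contrasts), b = as.numeric(n_b))
  }
}

#' Difficulty score under a named model
#'
#' Dispatches to [dprime()], [abs_diff()] or [neg_ratio()]. All three scores
#' are oriented easier-is-larger; negate them to obtain difficulty-increasing
#' regression predictors (see [compare_models()]).
#'
#' @inheritParams dprime
#' @param model One of `"dprime"`, `"abs_diff"`, `"neg_ratio"`.
#' @return Numeric vector of scores.
#' @export
difficulty_score <- function(contrasts, model = c("dprime", "abs_diff", "neg_ratio"),
                             sigma = 1) {
  model <- match.arg(model)
  switch(model,
    dprime = dprime(contrasts, sigma = sigma),
    abs_diff = abs_diff(contrasts),
    neg_ratio = neg_ratio(contrasts)
  )
}

#' Ideal-observer accuracy for two-alternative forced choice
#'
#' Maps discriminability to the expected accuracy of an equal-variance ideal
#' observer choosing between two alternatives: `pnorm(d / sqrt(2))`. Chance
#' (0.5) at d' = 0, approaching 1 as d' grows.
#'
#' @param d Nonnegative numeric vector of d' values.
#' @return Probabilities in `[0.5, 1)`.
#' @examples
#' accuracy_2afc(0)        # 0.5
#' accuracy_2afc(log(4))   # ~ 0.836
#' @export
accuracy_2afc <- function(d) {
  if (any(!is.finite(d) & !is.infinite(d)) || any(d < 0)) {
    stop("invalid parameter: d' must be nonnegative", call. = FALSE)
  }
  stats::pnorm(d / sqrt(2))
}

#' Rank contrasts from easiest to hardest
#'
#' Sorts a contrast table easiest-first by the chosen difficulty model's
#' score. Ties are broken deterministically by smaller maximum count, then
#' smaller minimum count, so output is reproducible.
#'
#' @inheritParams difficulty_score
#' @return The input tibble, reordered, with a `score` column appended.
#' @examples
#' rank_contrasts(contrasts_tbl(c(8, 8), c(6, 2)))
#' @export
rank_contrasts <- function(contrasts, model = c("dprime", "abs_diff", "neg_ratio"),
                           sigma = 1) {
  model <- match.arg(model)
  contrasts <- validate_contrasts(contrasts)
  if (nrow(contrasts) == 0L) stop("empty contrast list", call. = FALSE)
  score <- difficulty_score(contrasts, model, sigma = sigma)
  hi <- pmax(contrasts$n_a, contrasts$n_b)
  lo <- pmin(contrasts$n_a, contrasts$n_b)
  ord <- order(-score, hi, lo)
  out <- contrasts[ord, , drop = FALSE]
  out$score <- score[ord]
  out
}

#' Read or write a contrast table as CSV
#'
#' The interchange schema has columns `label`, `n_a`, `n_b`, `hidden`.
#'
#' @param path File path.
#' @param contrasts A contrast table.
#' @return `read_contrasts()` returns a validated tibble;
#'   `write_contrasts()` returns `path` invisibly.
#' @export
read_contrasts <- function(path) {
  validate_contrasts(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_contrasts
#' @export
write_contrasts <- function(contrasts, path) {
  readr::write_csv(validate_contrasts(contrasts), path)
  invisible(path)
}

require_columns <- function(x, cols, what = "table") {
  if (!is.data.frame(x)) stop("data error: ", what, " must be a data frame", call. = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop("data error: ", what, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
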