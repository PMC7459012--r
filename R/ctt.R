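#' Per-examinee total and percent scores
#'
#' Sums item points per examinee and expresses them as per cent of the maximum
#' points (one point per item). The sample variance of the totals (denominator
#' `n - 1`, points scale) and the item count are attached as attributes
#' `"score_variance"`, `"n_items"` and `"max_points"` for downstream use.
#'
#' @param responses Tibble with `examinee_id` and one score column per item.
#' @return Tibble with `examinee_id`, `points`, `percent`.
#' @export
total_scores <- function(responses) {
  scores <- responses_matrix(responses)
  if (nrow(scores) < 2L) {
    abort("need at least 2 examinees: score variance is undefined otherwise")
  }
  k <- ncol(scores)
  totals <- unname(rowSums(scores))
  out <- tibble::tibble(
    examinee_id = responses$examinee_id,
    points = totals,
    percent = 100 * totals / k
  )
  attr(out, "score_variance") <- var(totals)
  attr(out, "n_items") <- k
  attr(out, "max_points") <- k
  out
}

#' Cronbach's alpha
#'
#' Global internal-consistency reliability,
#' `alpha = k / (k - 1) * (1 - sum(item variances) / total variance)`,
#' with sample variances (`n - 1`).
#'
#' @inheritParams total_scores
#' @return A single numeric value.
#' @export
cronbach_alpha <- function(responses) {
  scores <- responses_matrix(responses)
  k <- ncol(scores)
  if (k < 2L) abort("Cronbach's alpha needs at least 2 items")
  if (nrow(scores) < 2L) abort("Cronbach's alpha needs at least 2 examinees")
  total_var <- var(rowSums(scores))
  if (total_var <= 0) {
    abort("total-score variance is zero: Cronbach's alpha is undefined")
  }
  item_var <- sum(apply(scores, 2L, var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Binomial-error conditional standard error of measurement
#'
#' Lord's binomial error model gives the conditional SEM of a test score `X`
#' on a test of `k` items as `sqrt(X * (k - X) / (k - 1))` (points scale).
#' With partial-credit items `X` may be non-integer; the formula is evaluated
#' on the points scale with `k` the maximum attainable points.
#'
#' @param X Score(s) in points, `0 <= X <= k`.
#' @param k Maximum points (item count); `k >= 2`.
#' @return Numeric vector of conditional SEMs.
#' @export
binomial_csem <- function(X, k) {
  if (length(k) != 1L || k < 2) abort("`k` must be a single value >= 2")
  if (any(X < 0 | X > k)) abort("`X` must lie in [0, k]")
  sqrt(X * (k - X) / (k - 1))
}

#' CTT conditional reliability curve
#'
#' Standardises the binomial-error conditional SEM at the observed score
#' variance: `crel(X) = (var_x - csem(X)^2) / var_x`. The curve is evaluated
#' on the full achievable score grid (steps of 0.5 points when the exam
#' contains MTF items, else 1), reported on the percent scale; scores actually
#' achieved by at least one examinee are marked. Values above 1 are
#' impossible; negative values can occur in homogeneous cohorts (when
#' `csem^2` exceeds the score variance) and are flagged, not truncated.
#'
#' @inheritParams total_scores
#' @param exam Optional `exam_spec`, used to decide the grid increment;
#'   otherwise the increment is 0.5 when any half-point score is observed.
#' @return Tibble with `framework` (`"ctt"`), `percent_score`, `points`,
#'   `csem`, `crel`, `achieved`, `negative`; attributes `"variance_used"`
#'   (points-scale score variance) and `"has_negative_crel"`.
#' @export
ctt_crel_curve <- function(responses, exam = NULL) {
  summary <- total_scores(responses)
  v <- attr(summary, "score_variance")
  k <- attr(summary, "max_points")
  if (v <= 0) abort("zero score variance: conditional reliability is undefined")
  scores <- responses_matrix(responses)
  inc <- if (!is.null(exam)) {
    if (any(exam$items$kind == "mtf")) 0.5 else 1
  } else if (any(abs(scores - round(scores)) > 1e-9)) 0.5 else 1
  grid <- seq(0, k, by = inc)
  csem <- binomial_csem(grid, k)
  crel <- (v - csem^2) / v
  achieved <- grid %in% (round(summary$points / inc) * inc)
  out <- tibble::tibble(
    framework = "ctt",
    percent_score = 100 * grid / k,
    points = grid,
    csem = csem,
    crel = crel,
    achieved = achieved,
    negative = crel < 0
  )
  attr(out, "variance_used") <- v
  attr(out, "has_negative_crel") <- any(out$negative)
  out
}
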