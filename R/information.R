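#' Test information and IRT conditional SEM
#'
#' Test information at each ability value is the sum over items of the
#' model's category-score variance (the Fisher information about theta under
#' the partial credit model); the IRT conditional SEM on the theta metric is
#' its inverse square root, `csem(theta) = sqrt(1 / I(theta))`.
#'
#' @param fit A [pcm_fit][fit_pcm()] object.
#' @param theta_grid Numeric vector of ability values.
#' @return Tibble with `theta`, `info`, `csem_theta`.
#' @export
test_information <- function(fit, theta_grid) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (length(theta_grid) == 0L || any(!is.finite(theta_grid))) {
    abort("`theta_grid` must be a non-empty finite numeric vector")
  }
  info <- rep(0, length(theta_grid))
  for (d in fit$deltas) info <- info + pcm_moments(theta_grid, d)$var
  tibble::tibble(theta = theta_grid, info = info, csem_theta = 1 / sqrt(info))
}

#' Expected percent score at an ability value
#'
#' The test characteristic curve: the model-expected total points at `theta`
#' (type A items contribute their probability correct, MTF items half a point
#' per expected category step), divided by the maximum points, times 100.
#' Strictly increasing in `theta`.
#'
#' @inheritParams test_information
#' @param theta Numeric vector of ability values.
#' @return Numeric vector of expected percent scores in (0, 100).
#' @export
expected_percent_score <- function(fit, theta) {
  stopifnot(inherits(fit, "pcm_fit"))
  pts <- rep(0, length(theta))
  w <- fit$weights
  ids <- names(fit$deltas)
  for (i in seq_along(ids)) {
    pts <- pts + w[[i]] * pcm_moments(theta, fit$deltas[[i]])$mean
  }
  100 * pts / length(ids)
}

#' Ability value for a target expected percent score
#'
#' Numeric inverse of the test characteristic curve by monotone bisection.
#'
#' @inheritParams test_information
#' @param percent Target expected percent score(s), strictly inside the
#'   curve's attainable range.
#' @param bracket Search interval on the theta scale.
#' @return Numeric vector of abilities.
#' @export
theta_for_percent <- function(fit, percent, bracket = c(-10, 10)) {
  lo_p <- expected_percent_score(fit, bracket[1])
  hi_p <- expected_percent_score(fit, bracket[2])
  if (any(percent <= lo_p | percent >= hi_p)) {
    abort("`percent` outside the attainable expected-score range")
  }
  lo <- rep(bracket[1], length(percent))
  hi <- rep(bracket[2], length(percent))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- expected_percent_score(fit, mid) < percent
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' IRT conditional reliability curve
#'
#' Standardises the IRT conditional SEM at the variance of the estimated
#' abilities: `crel(theta) = (var(theta_hat) - csem(theta)^2) /
#' var(theta_hat)`. Each grid point is annotated with its expected percent
#' score via the test characteristic curve, so CTT and IRT curves share a
#' common x-axis.
#'
#' @inheritParams test_information
#' @param estimates Ability estimates from [wle_theta()]; their variance is
#'   the standardising variance.
#' @param theta_grid Ability grid; defaults to 121 points over the fit's
#'   quadrature range.
#' @return Tibble with `framework` (`"irt"`), `theta`, `info`, `csem_theta`,
#'   `crel`, `percent_score`, `negative`; attribute `"variance_used"`.
#' @export
irt_crel_curve <- function(fit, estimates, theta_grid = NULL) {
  stopifnot(inherits(fit, "pcm_fit"))
  v <- var(estimates$theta)
  if (!is.finite(v) || v <= 0) {
    abort("zero variance of ability estimates: conditional reliability undefined")
  }
  theta_grid <- theta_grid %||%
    seq(fit$quadrature_range[1], fit$quadrature_range[2], length.out = 121L)
  ic <- test_information(fit, theta_grid)
  crel <- (v - ic$csem_theta^2) / v
  out <- tibble::tibble(
    framework = "irt",
    theta = ic$theta,
    info = ic$info,
    csem_theta = ic$csem_theta,
    crel = crel,
    percent_score = expected_percent_score(fit, ic$theta),
    negative = crel < 0
  )
  attr(out, "variance_used") <- v
  attr(out, "has_negative_crel") <- any(out$negative)
  out
}
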