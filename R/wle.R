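#' Weighted likelihood (Warm) ability estimates
#'
#' Solves Warm's weighted likelihood equation per examinee,
#' `l'(theta) + J(theta) / (2 I(theta)) = 0`, where `l'` is the score
#' residual on the category metric, `I` the test information and
#' `J = dI/dtheta` (the sum of third central category moments under the
#' model). The bias-correction term keeps the estimate finite even for zero
#' and perfect raw scores. In the Rasch family the total category score is a
#' sufficient statistic, so estimation runs once per distinct raw score.
#' Roots are found by safeguarded bisection on `[-8, 8]` (widened if needed);
#' the standard error is `1 / sqrt(I(theta_hat))`.
#'
#' @param fit A [pcm_fit][fit_pcm()] object.
#' @param responses The responses the model was fitted to (or any responses
#'   on the same items).
#' @return Tibble with `examinee_id`, `theta`, `se_theta`, and attribute
#'   `"estimator" = "WLE"`.
#' @export
wle_theta <- function(fit, responses) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (!fit$converged) {
    warn("using ability estimates from a non-converged model fit")
  }
  scores <- responses_matrix(responses)
  scores <- scores[, names(fit$deltas), drop = FALSE]
  cats <- points_to_categories(scores, fit$weights[colnames(scores)])
  raw <- rowSums(cats)
  uniq <- sort(unique(raw))

  score_fun <- function(theta) {
    # returns list(f, info) for vector theta, f = l' + J/(2I)
    e <- v <- m3 <- numeric(length(theta))
    for (d in fit$deltas) {
      mom <- pcm_moments(theta, d)
      e <- e + mom$mean
      v <- v + mom$var
      m3 <- m3 + mom$mu3
    }
    list(e = e, info = v, mu3 = m3)
  }
  f_at <- function(th, r) {
    s <- score_fun(th)
    (r - s$e) + s$mu3 / (2 * pmax(s$info, 1e-12))
  }
  # Vectorised safeguarded bisection over all distinct raw scores at once.
  lo <- rep(-8, length(uniq)); hi <- rep(8, length(uniq))
  for (widen in 1:6) {
    bad <- !(f_at(lo, uniq) > 0 & f_at(hi, uniq) < 0)
    if (!any(bad)) break
    lo[bad] <- lo[bad] * 2
    hi[bad] <- hi[bad] * 2
  }
  if (any(!(f_at(lo, uniq) > 0 & f_at(hi, uniq) < 0))) {
    abort("weighted likelihood equation could not be bracketed")
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    up <- f_at(mid, uniq) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  theta_by_score <- (lo + hi) / 2
  info_at <- score_fun(theta_by_score)$info
  se_by_score <- 1 / sqrt(info_at)
  idx <- match(raw, uniq)
  out <- tibble::tibble(
    examinee_id = responses$examinee_id,
    theta = theta_by_score[idx],
    se_theta = se_by_score[idx]
  )
  attr(out, "estimator") <- "WLE"
  out
}

#' IRT person-separation reliability
#'
#' The separation index is the IRT analogue of Cronbach's alpha:
#' `(var(theta_hat) - mean(se_theta^2)) / var(theta_hat)` — the proportion of
#' observed ability variance not attributable to estimation error.
#'
#' @param estimates Tibble from [wle_theta()].
#' @return A single numeric value (can be negative in degenerate cohorts).
#' @export
separation_index <- function(estimates) {
  if (nrow(estimates) < 2L) abort("need at least 2 examinees")
  v <- var(estimates$theta)
  if (v <= 0) abort("zero ability variance: separation index is undefined")
  (v - mean(estimates$se_theta^2)) / v
}
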