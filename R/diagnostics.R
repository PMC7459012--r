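# Model-fit diagnostics: Q3 local independence, infit/outfit, SRMR/SRMSR.

# Expected category score and category-score variance for every
# examinee-item cell at the estimated abilities.
model_expectations <- function(fit, thetas) {
  k <- length(fit$deltas)
  E <- W <- matrix(0, length(thetas), k,
                   dimnames = list(NULL, names(fit$deltas)))
  for (i in seq_len(k)) {
    mom <- pcm_moments(thetas, fit$deltas[[i]])
    E[, i] <- mom$mean
    W[, i] <- mom$var
  }
  list(E = E, W = W)
}

residual_matrices <- function(fit, responses, estimates) {
  scores <- responses_matrix(responses)[, names(fit$deltas), drop = FALSE]
  cats <- points_to_categories(scores, fit$weights[colnames(scores)])
  stopifnot(nrow(cats) == nrow(estimates))
  mod <- model_expectations(fit, estimates$theta)
  list(resid = cats - mod$E, W = mod$W)
}

#' Q3 local-independence statistic
#'
#' Yen's Q3: for each item pair, the correlation across examinees of the
#' item-score residuals `observed - expected` under the fitted model at the
#' estimated abilities. Under local independence the pairwise values are
#' small, with a known slight negative expectation near `-1/(k - 1)`; the
#' headline summary is therefore the mean absolute Q3, with the
#' signed mean reported alongside.
#'
#' @param fit A [pcm_fit][fit_pcm()] object.
#' @param responses The scored responses.
#' @param estimates Ability estimates from [wle_theta()].
#' @return One-row tibble with `q3_mean_abs`, `q3_mean_signed`, `q3_min`,
#'   `q3_max`, `n_pairs`, `n_items_skipped`; the full pairwise matrix is in
#'   attribute `"q3_matrix"`.
#' @export
q3_statistic <- function(fit, responses, estimates) {
  rm_ <- residual_matrices(fit, responses, estimates)
  res <- rm_$resid
  keep <- apply(res, 2L, function(x) sd(x) > 1e-12)
  if (any(!keep)) {
    warn(sprintf("%d item(s) with constant residuals skipped in Q3",
                 sum(!keep)))
  }
  res <- res[, keep, drop = FALSE]
  if (ncol(res) < 2L) abort("fewer than 2 items with non-constant residuals")
  q3 <- cor(res)
  vals <- q3[lower.tri(q3)]
  out <- tibble::tibble(
    q3_mean_abs = mean(abs(vals)),
    q3_mean_signed = mean(vals),
    q3_min = min(vals),
    q3_max = max(vals),
    n_pairs = length(vals),
    n_items_skipped = sum(!keep)
  )
  attr(out, "q3_matrix") <- q3
  out
}

#' Infit and outfit item-fit statistics
#'
#' Mean-square residual fit statistics per item on the category metric.
#' With residual `r_vi = x_vi - E_vi` and model variance `W_vi` at the
#' estimated ability: outfit is the unweighted mean of the squared
#' standardised residuals `mean(r^2 / W)`, infit the information-weighted
#' form `sum(r^2) / sum(W)`. Both have expectation near 1 under model fit;
#' outfit is the more outlier-sensitive of the two. Cells with (numerically)
#' saturated probabilities (`W` about 0) are excluded and counted; items with
#' no usable cells are reported `NA`.
#'
#' @inheritParams q3_statistic
#' @return Tibble with `item_id`, `kind`, `infit`, `outfit`, `n_excluded`.
#' @export
infit_outfit <- function(fit, responses, estimates) {
  rm_ <- residual_matrices(fit, responses, estimates)
  r2 <- rm_$resid^2
  W <- rm_$W
  usable <- W > 1e-10
  out <- purrr::map_dfr(seq_len(ncol(W)), function(i) {
    u <- usable[, i]
    tibble::tibble(
      item_id = colnames(W)[i],
      kind = unname(fit$kinds[colnames(W)[i]]),
      infit = if (any(u)) sum(r2[u, i]) / sum(W[u, i]) else NA_real_,
      outfit = if (any(u)) mean(r2[u, i] / W[u, i]) else NA_real_,
      n_excluded = sum(!u)
    )
  })
  out
}

#' Percent of misfitting items
#'
#' Share of items whose mean-square fit statistic falls outside the given
#' bounds (default `[0.8, 1.2]`). Items with `NA` statistics are dropped.
#'
#' @param stats Tibble from [infit_outfit()].
#' @param statistic `"outfit"` or `"infit"`.
#' @param bounds Length-2 acceptance interval for the mean square.
#' @return Percent (0-100) of items outside the bounds.
#' @export
misfit_rate <- function(stats, statistic = c("outfit", "infit"),
                        bounds = c(0.8, 1.2)) {
  statistic <- match.arg(statistic)
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    abort("`bounds` must be c(lower, upper) with lower < upper")
  }
  x <- stats[[statistic]]
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  100 * mean(x < bounds[1] | x > bounds[2])
}

#' SRMR and SRMSR residual-correlation summaries
#'
#' Compares the observed inter-item correlation matrix with the model-implied
#' one (obtained by integrating item expectations over the fitted latent
#' distribution). With residual correlations `d_ij = r_obs - r_implied` over
#' off-diagonal pairs: SRMR is the mean absolute residual, SRMSR the square
#' root of the mean squared residual (so SRMSR >= SRMR always).
#'
#' @inheritParams q3_statistic
#' @return One-row tibble with `srmr`, `srmsr`, `n_pairs`,
#'   `n_items_excluded` (items constant in the data, which have no defined
#'   observed correlation).
#' @export
srmr_srmsr <- function(fit, responses) {
  scores <- responses_matrix(responses)[, names(fit$deltas), drop = FALSE]
  cats <- points_to_categories(scores, fit$weights[colnames(scores)])
  keep <- apply(cats, 2L, function(x) sd(x) > 1e-12)
  if (sum(keep) < 2L) abort("fewer than 2 non-constant items")
  obs <- cor(cats[, keep, drop = FALSE])

  quad <- pcm_quadrature(fit$settings, fit$sigma)
  deltas <- fit$deltas[keep]
  kq <- length(quad$nodes)
  Em <- sapply(deltas, function(d) pcm_moments(quad$nodes, d)$mean)
  Vm <- sapply(deltas, function(d) pcm_moments(quad$nodes, d)$var)
  mu <- drop(quad$weights %*% Em)
  exx <- crossprod(Em * quad$weights, Em)   # E[E_i E_j]
  cov_imp <- exx - tcrossprod(mu)
  v_imp <- drop(quad$weights %*% (Vm + Em^2)) - mu^2
  diag(cov_imp) <- v_imp
  imp <- stats::cov2cor(cov_imp)

  d <- (obs - imp)[lower.tri(obs)]
  tibble::tibble(
    srmr = mean(abs(d)),
    srmsr = sqrt(mean(d^2)),
    n_pairs = length(d),
    n_items_excluded = sum(!keep)
  )
}

# Internal: SRMR/SRMSR from two correlation matrices (shared by tests).
.srmr_from_matrices <- function(obs, imp) {
  d <- (obs - imp)[lower.tri(obs)]
  c(srmr = mean(abs(d)), srmsr = sqrt(mean(d^2)))
}

#' One-row model-fit report for an exam
#'
#' Bundles the Q3 summary, the infit/outfit distribution with misfit rates,
#' and SRMR/SRMSR into a single row, mirroring a fit-index table.
#'
#' @inheritParams q3_statistic
#' @param bounds Misfit bounds for the mean squares, see [misfit_rate()].
#' @return One-row tibble.
#' @export
fit_report <- function(fit, responses, estimates, bounds = c(0.8, 1.2)) {
  q3s <- q3_statistic(fit, responses, estimates)
  io <- infit_outfit(fit, responses, estimates)
  sr <- srmr_srmsr(fit, responses)
  tibble::tibble(
    q3 = q3s$q3_mean_abs,
    q3_signed = q3s$q3_mean_signed,
    infit_min = min(io$infit, na.rm = TRUE),
    infit_max = max(io$infit, na.rm = TRUE),
    infit_mean = mean(io$infit, na.rm = TRUE),
    pct_misfit_infit = misfit_rate(io, "infit", bounds),
    outfit_min = min(io$outfit, na.rm = TRUE),
    outfit_max = max(io$outfit, na.rm = TRUE),
    outfit_mean = mean(io$outfit, na.rm = TRUE),
    pct_misfit_outfit = misfit_rate(io, "outfit", bounds),
    srmr = sr$srmr,
    srmsr = sr$srmsr
  )
}
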