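# Partial credit model core: category probabilities and MML-EM estimation.
#
# The model is the 1-PL (Rasch-family) partial credit model on ordered integer
# categories 0..m_i: P(X = x | theta) proportional to
# exp(x * theta - sum_{j <= x} delta_j), with step parameters delta_j per
# item. Single-best-answer items have one step (m = 1), multiple true-false
# items have two (m = 2, categories worth half a point each).

# Category probabilities for one item at a vector of abilities.
# Returns a length(theta) x (m + 1) matrix.
pcm_probs <- function(theta, delta) {
  m <- length(delta)
  eta <- outer(theta, 0:m) -
    matrix(c(0, cumsum(delta)), length(theta), m + 1L, byrow = TRUE)
  eta <- eta - apply(eta, 1L, max)
  e <- exp(eta)
  e / rowSums(e)
}

# First three moments of the category score at each theta; used for expected
# scores, information (variance) and the Warm correction (third central
# moment, the derivative of the item information).
pcm_moments <- function(theta, delta) {
  p <- pcm_probs(theta, delta)
  k <- 0:length(delta)
  e1 <- drop(p %*% k)
  e2 <- drop(p %*% k^2)
  e3 <- drop(p %*% k^3)
  v <- pmax(e2 - e1^2, 0)
  mu3 <- e3 - 3 * e1 * e2 + 2 * e1^3
  list(mean = e1, var = v, mu3 = mu3)
}

# Quadrature grid with normal weights (latent mean 0, sd sigma).
pcm_quadrature <- function(settings, sigma = 1) {
  nodes <- seq(settings$quadrature_range[1], settings$quadrature_range[2],
               length.out = settings$n_quadrature)
  w <- dnorm(nodes, 0, sigma)
  list(nodes = nodes, weights = w / sum(w))
}

# Person-by-node log-likelihood matrix: L[v, q] = sum_i log P_i(x_vi | node_q).
# `cats` is the integer category matrix, `deltas` a list of step vectors.
pcm_loglik_matrix <- function(cats, deltas, nodes) {
  n <- nrow(cats)
  L <- matrix(0, n, length(nodes))
  for (i in seq_along(deltas)) {
    logp <- log(pcm_probs(nodes, deltas[[i]]))
    L <- L + t(logp[, cats[, i] + 1L, drop = FALSE])
  }
  L
}

# Marginal log-likelihood of the data for given steps and sigma.
pcm_marginal_loglik <- function(cats, deltas, settings, sigma = 1) {
  quad <- pcm_quadrature(settings, sigma)
  L <- pcm_loglik_matrix(cats, deltas, quad$nodes)
  sum(log_sum_exp_rows(sweep(L, 2L, log(quad$weights), "+")))
}

# Grouped E-step/M-step machinery. Items are processed in two blocks —
# dichotomous (one step) and three-category (two steps) — so the inner EM
# loop is a handful of BLAS matrix products instead of a per-item R loop.

# Stable log category probabilities for all dichotomous items at all nodes:
# list(lp0, lp1), each Q x k.
dich_logprobs <- function(nodes, b) {
  eta <- outer(nodes, b, function(t, bb) t - bb)
  list(lp0 = plogis(-eta, log.p = TRUE), lp1 = plogis(eta, log.p = TRUE))
}

# Same for three-category items with step matrix d (2 x k): list lp0..lp2.
tri_logprobs <- function(nodes, d) {
  eta1 <- outer(nodes, d[1, ], function(t, dd) t - dd)
  eta2 <- outer(2 * nodes, d[1, ] + d[2, ], function(t, dd) t - dd)
  m <- pmax(0, eta1, eta2)
  logden <- m + log(exp(-m) + exp(eta1 - m) + exp(eta2 - m))
  list(lp0 = -logden, lp1 = eta1 - logden, lp2 = eta2 - logden)
}

# Vectorised safeguarded-Newton M-step for the dichotomous block.
# r1: Q x k expected counts in category 1; r_tot: Q vector.
mstep_dich <- function(b, r1, r_tot, nodes, bound) {
  obj <- function(bb) {
    lp <- dich_logprobs(nodes, bb)
    colSums(r1 * lp$lp1) + colSums((r_tot - r1) * lp$lp0)
  }
  f0 <- obj(b)
  for (it in 1:30) {
    p1 <- plogis(outer(nodes, b, function(t, bb) t - bb))
    grad <- colSums(r_tot * p1) - colSums(r1)
    hess <- colSums(r_tot * p1 * (1 - p1))
    step <- grad / pmax(hess, 1e-12)   # Newton ascent: -(obj'')^{-1} obj', obj'' = -hess
    step <- pmin(pmax(step, -2), 2)
    new_b <- pmin(pmax(b + step, -bound), bound)
    f1 <- obj(new_b)
    worse <- f1 < f0 - 1e-12
    for (h in 1:12) {
      if (!any(worse)) break
      new_b[worse] <- (b[worse] + new_b[worse]) / 2
      f1[worse] <- obj(new_b)[worse]
      worse <- f1 < f0 - 1e-12
    }
    new_b[worse] <- b[worse]
    f1[worse] <- f0[worse]
    moved <- max(abs(new_b - b))
    b <- new_b
    f0 <- f1
    if (moved < 1e-9) break
  }
  b
}

# Vectorised M-step for the three-category block; d is 2 x k,
# r1/r2 Q x k expected counts in categories 1 and 2.
mstep_tri <- function(d, r1, r2, r_tot, nodes, bound) {
  obj <- function(dd) {
    lp <- tri_logprobs(nodes, dd)
    colSums((r_tot - r1 - r2) * lp$lp0) + colSums(r1 * lp$lp1) +
      colSums(r2 * lp$lp2)
  }
  f0 <- obj(d)
  for (it in 1:30) {
    lp <- tri_logprobs(nodes, d)
    p1 <- exp(lp$lp1); p2 <- exp(lp$lp2)
    s1 <- p1 + p2; s2 <- p2
    g1 <- colSums(r_tot * s1) - colSums(r1 + r2)
    g2 <- colSums(r_tot * s2) - colSums(r2)
    h11 <- colSums(r_tot * s1 * (1 - s1))
    h22 <- colSums(r_tot * s2 * (1 - s2))
    h12 <- colSums(r_tot * (s2 - s1 * s2))
    det <- pmax(h11 * h22 - h12^2, 1e-12)
    st1 <- (h22 * g1 - h12 * g2) / det   # ascent step: (-H)^{-1} grad
    st2 <- (h11 * g2 - h12 * g1) / det
    st1 <- pmin(pmax(st1, -2), 2)
    st2 <- pmin(pmax(st2, -2), 2)
    new_d <- rbind(pmin(pmax(d[1, ] + st1, -bound), bound),
                   pmin(pmax(d[2, ] + st2, -bound), bound))
    f1 <- obj(new_d)
    worse <- f1 < f0 - 1e-12
    for (h in 1:12) {
      if (!any(worse)) break
      new_d[, worse] <- (d[, worse, drop = FALSE] + new_d[, worse, drop = FALSE]) / 2
      f1[worse] <- obj(new_d)[worse]
      worse <- f1 < f0 - 1e-12
    }
    new_d[, worse] <- d[, worse]
    f1[worse] <- f0[worse]
    moved <- max(abs(new_d - d))
    d <- new_d
    f0 <- f1
    if (moved < 1e-9) break
  }
  d
}

#' Fit a 1-PL partial credit model by marginal maximum likelihood
#'
#' Estimates item step parameters of the Rasch partial credit model by an EM
#' algorithm over an equally spaced normal quadrature. The latent trait is
#' identified by fixing its mean at 0; its standard deviation is estimated by
#' default so that person-separation statistics reflect sample heterogeneity.
#' Single-best-answer (type A) items carry one step parameter (their
#' difficulty); multiple true-false items carry two steps on the integer
#' category metric `{0, 1, 2}`, each category step worth half a point.
#'
#' @param responses Tibble/data frame with an `examinee_id` column and one
#'   numeric score column per item (0/1 for type A, 0/0.5/1 for MTF).
#' @param exam Optional [exam spec][generate_exam_spec()]; when supplied, item
#'   kinds are taken from it, otherwise any item showing half points is
#'   treated as MTF.
#' @param settings Estimation settings, see [pcm_settings()].
#' @return An object of class `pcm_fit` with elements `item_params` (tibble:
#'   `item_id`, `kind`, `step`, `estimate`), `log_likelihood`, `sigma`,
#'   `converged`, `n_iter`, `iteration_trace`, plus the quadrature metadata.
#'   [tidy()] returns the item parameters, [glance()] the fit summary.
#' @export
fit_pcm <- function(responses, exam = NULL, settings = pcm_settings()) {
  scores <- responses_matrix(responses)
  if (nrow(scores) < 2L) abort("need at least 2 examinees to fit the model")
  kinds <- item_kinds_for(scores, exam)
  w <- kind_weight(kinds)
  cats <- points_to_categories(scores, w)
  n_cat <- ifelse(kinds == "mtf", 3L, 2L)

  observed <- lapply(seq_len(ncol(cats)), function(i) sort(unique(cats[, i])))
  bad <- vapply(observed, length, 1L) < 2L
  if (any(bad)) {
    abort(paste0("item(s) with fewer than 2 observed categories: ",
                 paste(colnames(cats)[bad], collapse = ", ")))
  }
  out_of_range <- vapply(seq_len(ncol(cats)), function(i) {
    any(cats[, i] < 0L | cats[, i] > n_cat[i] - 1L)
  }, TRUE)
  if (any(out_of_range)) {
    abort(paste0("illegal score values in item(s): ",
                 paste(colnames(cats)[out_of_range], collapse = ", ")))
  }

  n <- nrow(cats)
  idx_a <- which(n_cat == 2L)   # dichotomous block
  idx_m <- which(n_cat == 3L)   # three-category block
  Xa <- cats[, idx_a, drop = FALSE] * 1
  I1 <- (cats[, idx_m, drop = FALSE] == 1L) * 1
  I2 <- (cats[, idx_m, drop = FALSE] == 2L) * 1
  b <- rep(0, length(idx_a))
  d <- matrix(0, 2L, length(idx_m))

  sigma <- 1
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(settings$max_iter)) {
    quad <- pcm_quadrature(settings, sigma)
    L <- matrix(0, n, length(quad$nodes))
    if (length(idx_a)) {
      lpa <- dich_logprobs(quad$nodes, b)
      L <- L + Xa %*% t(lpa$lp1) +
        (1 - Xa) %*% t(lpa$lp0)
    }
    if (length(idx_m)) {
      lpm <- tri_logprobs(quad$nodes, d)
      L <- L + I1 %*% t(lpm$lp1) + I2 %*% t(lpm$lp2) +
        (1 - I1 - I2) %*% t(lpm$lp0)
    }
    Lw <- sweep(L, 2L, log(quad$weights), "+")
    lse <- log_sum_exp_rows(Lw)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < settings$tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    post <- exp(Lw - lse)
    r_tot <- colSums(post)
    if (length(idx_a)) {
      r1a <- crossprod(post, Xa)            # Q x k_a
      b <- mstep_dich(b, r1a, r_tot, quad$nodes, settings$step_bound)
    }
    if (length(idx_m)) {
      r1m <- crossprod(post, I1)
      r2m <- crossprod(post, I2)
      d <- mstep_tri(d, r1m, r2m, r_tot, quad$nodes, settings$step_bound)
    }
    if (settings$estimate_sigma) {
      # Exact M-step for the latent SD under the discretised normal prior
      # (grid-normalised weights), so the EM ascent property is preserved.
      nodes <- quad$nodes
      sigma <- stats::optimize(function(s) {
        lw <- dnorm(nodes, 0, s, log = TRUE)
        sum(r_tot * (lw - log(sum(exp(lw - max(lw)))) - max(lw)))
      }, interval = c(0.05, 5), maximum = TRUE, tol = 1e-7)$maximum
    }
  }
  if (!converged) {
    warn("EM did not reach the log-likelihood tolerance within `max_iter`")
  }

  deltas <- vector("list", ncol(cats))
  for (j in seq_along(idx_a)) deltas[[idx_a[j]]] <- unname(b[j])
  for (j in seq_along(idx_m)) deltas[[idx_m[j]]] <- unname(d[, j])
  item_params <- tibble::tibble(
    item_id = rep(colnames(cats), lengths(deltas)),
    kind = rep(kinds, lengths(deltas)),
    step = unlist(lapply(lengths(deltas), seq_len)),
    estimate = unlist(deltas)
  )
  structure(
    list(item_params = item_params,
         deltas = setNames(deltas, colnames(cats)),
         kinds = setNames(kinds, colnames(cats)),
         weights = setNames(w, colnames(cats)),
         log_likelihood = trace[length(trace)],
         sigma = sigma,
         converged = converged,
         n_iter = length(trace),
         iteration_trace = trace,
         n_examinees = n,
         n_quadrature = settings$n_quadrature,
         quadrature_range = settings$quadrature_range,
         settings = settings),
    class = "pcm_fit"
  )
}

item_kinds_for <- function(scores, exam) {
  if (is.null(exam)) return(infer_kinds(scores))
  items <- exam$items
  missing <- setdiff(colnames(scores), items$item_id)
  if (length(missing)) {
    abort(paste0("items not in exam spec: ", paste(missing, collapse = ", ")))
  }
  setNames(items$kind[match(colnames(scores), items$item_id)],
           colnames(scores))
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat("1-PL partial credit model (MML-EM)\n")
  cat(sprintf("  items: %d (%d MTF)   examinees: %d\n",
              length(x$deltas), sum(x$kinds == "mtf"), x$n_examinees))
  cat(sprintf("  log-likelihood: %.4f   sigma: %.4f\n",
              x$log_likelihood, x$sigma))
  cat(sprintf("  EM iterations: %d   converged: %s\n",
              x$n_iter, x$converged))
  invisible(x)
}

#' @rdname fit_pcm
#' @param x A `pcm_fit` object.
#' @param ... Unused.
#' @method tidy pcm_fit
#' @export
tidy.pcm_fit <- function(x, ...) x$item_params

#' @rdname fit_pcm
#' @method glance pcm_fit
#' @export
glance.pcm_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    sigma = x$sigma,
    n_items = length(x$deltas),
    n_examinees = x$n_examinees,
    n_iter = x$n_iter,
    converged = x$converged
  )
}
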