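# Independent oracles, deliberately naive: they share no code path with the
# implementation they check.

# Marginal log-likelihood by direct summation over an equally spaced normal
# quadrature, computed from scratch (explicit per-person loop).
oracle_marginal_loglik <- function(cats_matrix, steps, sigma = 1,
                                   nodes = seq(-6, 6, length.out = 41)) {
  w <- dnorm(nodes, 0, sigma)
  w <- w / sum(w)
  cat_prob <- function(delta, x) {
    # vector over nodes for one item/response
    eta <- outer(nodes, 0:length(delta)) -
      matrix(c(0, cumsum(delta)), length(nodes), length(delta) + 1,
             byrow = TRUE)
    p <- exp(eta) / rowSums(exp(eta))
    p[, x + 1L]
  }
  ll <- 0
  for (v in seq_len(nrow(cats_matrix))) {
    lik_nodes <- w
    for (i in seq_len(ncol(cats_matrix))) {
      lik_nodes <- lik_nodes * cat_prob(steps[[i]], cats_matrix[v, i])
    }
    ll <- ll + log(sum(lik_nodes))
  }
  unname(ll)
}

# Exhaustive grid search over all step-parameter combinations (only feasible
# for very small item sets); returns the best grid log-likelihood.
oracle_grid_search <- function(cats_matrix, grids, sigma = 1) {
  combos <- expand.grid(grids)
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    steps <- as.list(as.numeric(combos[r, ]))
    ll <- oracle_marginal_loglik(cats_matrix, steps, sigma)
    best <- max(best, ll)
  }
  best
}

# Cyclic coordinate-wise exhaustive grid ascent: sweeps a 0.05-step grid along
# each parameter in turn (others held fixed) until no sweep improves, i.e. a
# grid-local optimum of the marginal likelihood.
oracle_coordinate_grid <- function(cats_matrix, start_steps, sigma = 1,
                                   step = 0.05, half_width = 1.5) {
  steps <- start_steps
  flat <- unlist(steps)
  lengths_ <- lengths(steps)
  rebuild <- function(flat) {
    out <- vector("list", length(lengths_))
    pos <- 1L
    for (i in seq_along(lengths_)) {
      out[[i]] <- flat[pos:(pos + lengths_[i] - 1L)]
      pos <- pos + lengths_[i]
    }
    out
  }
  best <- oracle_marginal_loglik(cats_matrix, rebuild(flat), sigma)
  repeat {
    improved <- FALSE
    for (j in seq_along(flat)) {
      grid <- flat[j] + seq(-half_width, half_width, by = step)
      for (g in grid) {
        cand <- flat
        cand[j] <- g
        ll <- oracle_marginal_loglik(cats_matrix, rebuild(cand), sigma)
        if (ll > best + 1e-10) {
          best <- ll
          flat <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(loglik = best, steps = rebuild(flat))
}

# Cronbach's alpha from the covariance matrix, assembled with explicit loops.
oracle_alpha <- function(m) {
  k <- ncol(m)
  n <- nrow(m)
  covm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    covm[i, j] <- sum((m[, i] - mean(m[, i])) * (m[, j] - mean(m[, j]))) / (n - 1)
  }
  k / (k - 1) * (1 - sum(diag(covm)) / sum(covm))
}

# Data matrix whose *sample* covariance equals the target exactly: columns of
# Z are orthonormalised residuals, so cov(Z L') = L L' = Sigma.
exact_cov_data <- function(n, sigma_target, seed = 1) {
  k <- ncol(sigma_target)
  stopifnot(n > k)
  withr::with_seed(seed, {
    # Orthonormalise against the intercept too, so columns are exactly
    # centred and the sample covariance of Z is exactly the identity.
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * k), n, k))))[, -1, drop = FALSE]
    Z <- Q * sqrt(n - 1)
    Z %*% chol(sigma_target)
  })
}
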