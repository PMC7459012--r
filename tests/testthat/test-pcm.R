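test_that("items with identical response patterns get identical difficulties", {
  ex <- recovery_exam(6, 0, 1)
  rs <- simulate_responses(ex, cohort_spec(150), 2)
  rs$i002 <- rs$i001  # column copy
  fit <- fit_pcm(rs)
  est <- fit$item_params$estimate
  expect_equal(est[1], est[2], tolerance = 1e-6)
})

test_that("the EM ascent is monotone and beats a full 2-D grid oracle", {
  ex <- make_exam(list(-0.4, 0.7))
  rs <- simulate_responses(ex, cohort_spec(60), 3)
  fit <- fit_pcm(rs, ex, pcm_settings(estimate_sigma = FALSE))
  expect_true(all(diff(fit$iteration_trace) >= -1e-9))
  cats <- condrel:::responses_matrix(rs)
  grid_best <- oracle_grid_search(cats, list(seq(-2, 2, by = 0.05),
                                             seq(-2, 2, by = 0.05)))
  expect_gte(fit$log_likelihood, grid_best - 1e-4)
  # and the reported log-likelihood agrees with the naive oracle evaluation
  est <- split(fit$item_params$estimate, fit$item_params$item_id)
  expect_equal(fit$log_likelihood,
               oracle_marginal_loglik(cats, unname(est)),
               tolerance = 1e-8)
})

test_that("EM stays monotone across random mixed-format datasets", {
  for (seed in 1:5) {
    ex <- recovery_exam(8, 0.4, seed)
    rs <- simulate_responses(ex, cohort_spec(80), 100 + seed)
    fit <- suppressWarnings(fit_pcm(rs, ex))
    expect_true(all(diff(fit$iteration_trace) >= -1e-9))
  }
})

test_that("step parameters are recovered on a moderate sample", {
  ex <- recovery_exam(20, 0.3, 21)
  rs <- simulate_responses(ex, cohort_spec(400), 22)
  fit <- fit_pcm(rs, ex)
  err <- fit$item_params$estimate - true_steps(ex)
  expect_lt(sqrt(mean(err^2)), 0.2)
  expect_gt(cor(fit$item_params$estimate, true_steps(ex)), 0.95)
  expect_equal(fit$sigma, 1, tolerance = 0.15)
})

test_that("unidentified or illegal items raise informative errors", {
  m <- cbind(rbinom(30, 1, 0.5), rep(1, 30))
  colnames(m) <- c("ok", "allsame")
  expect_error(fit_pcm(make_responses(m)), "allsame")
  ex <- make_exam(list(0, 0))
  m2 <- cbind(rbinom(30, 1, 0.5), sample(c(0, 0.5, 1), 30, replace = TRUE))
  colnames(m2) <- c("i001", "i002")
  # half points on a declared type A item
  expect_error(fit_pcm(make_responses(m2), ex), "step weight")
})

test_that("tidy() and glance() expose the fit in broom style", {
  ex <- recovery_exam(5, 0.4, 31)
  rs <- simulate_responses(ex, cohort_spec(120), 32)
  fit <- fit_pcm(rs, ex)
  td <- tidy(fit)
  expect_named(td, c("item_id", "kind", "step", "estimate"))
  expect_equal(nrow(td), sum(ifelse(ex$items$kind == "mtf", 2, 1)))
  gl <- glance(fit)
  expect_equal(gl$n_items, 5)
  expect_true(gl$converged)
  expect_equal(gl$n_iter, length(fit$iteration_trace))
})

test_that("fitting is deterministic for fixed data", {
  ex <- recovery_exam(6, 0.3, 41)
  rs <- simulate_responses(ex, cohort_spec(100), 42)
  expect_identical(fit_pcm(rs, ex)$item_params, fit_pcm(rs, ex)$item_params)
})
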