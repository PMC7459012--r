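test_that("a duplicated item shows up as a Q3 correlation of 1", {
  ex <- recovery_exam(10, 0.2, 81)
  rs <- simulate_responses(ex, cohort_spec(150), 82)
  rs$i_dup <- rs$i001
  fit <- make_fit(c(ex$items$steps, ex$items$steps[1]))
  names(fit$deltas)[11] <- names(fit$kinds)[11] <- names(fit$weights)[11] <- "i_dup"
  th <- wle_theta(fit, rs)
  q3 <- q3_statistic(fit, rs, th)
  q3m <- attr(q3, "q3_matrix")
  expect_equal(unname(q3m["i001", "i_dup"]), 1)
  expect_equal(q3$q3_max, 1)
  expect_true(isSymmetric(q3m))
  expect_equal(unname(diag(q3m)), rep(1, ncol(q3m)))
})

test_that("constant residual columns are skipped with a warning", {
  fit <- make_fit(list(-0.3, 0.4, 0.1))
  m <- cbind(rep(1, 12),
             withr::with_seed(1, rbinom(12, 1, 0.5)),
             withr::with_seed(2, rbinom(12, 1, 0.5)))
  rs <- make_responses(m)
  est <- tibble::tibble(examinee_id = rs$examinee_id, theta = rep(0, 12),
                        se_theta = rep(1, 12))
  expect_warning(q3 <- q3_statistic(fit, rs, est), "skipped")
  expect_equal(q3$n_items_skipped, 1)
  expect_equal(q3$n_pairs, 1)
})

test_that("infit and outfit are invariant to relabelling examinees", {
  ex <- recovery_exam(12, 0.3, 91)
  rs <- simulate_responses(ex, cohort_spec(120), 92)
  fit <- fit_pcm(rs, ex)
  th <- wle_theta(fit, rs)
  io <- infit_outfit(fit, rs, th)
  perm <- withr::with_seed(3, sample.int(nrow(rs)))
  io_perm <- infit_outfit(fit, rs[perm, ], th[perm, ])
  expect_equal(io, io_perm)
  expect_true(all(io$infit > 0 & io$outfit > 0))
})

test_that("saturated cells are excluded and fully degenerate items reported NA", {
  fit <- make_fit(list(0, 0.5))
  rs <- make_responses(rbind(c(1, 1), c(1, 0), c(0, 1)))
  est <- tibble::tibble(examinee_id = rs$examinee_id,
                        theta = c(40, 40, 40), se_theta = rep(1, 3))
  io <- infit_outfit(fit, rs, est)
  expect_equal(io$n_excluded, c(3, 3))
  expect_true(all(is.na(io$infit)))
  expect_true(is.na(misfit_rate(io)))
})

test_that("misfit rates are plain percentages over the bounds", {
  stats <- tibble::tibble(
    item_id = sprintf("i%02d", 1:60),
    infit = c(rep(1, 57), 1.3, 0.7, 1.25),
    outfit = rep(1, 60)
  )
  expect_equal(misfit_rate(stats, "infit"), 5)
  expect_equal(misfit_rate(stats, "outfit"), 0)
  expect_equal(misfit_rate(stats, "infit", bounds = c(0.5, 1.5)), 0)
  expect_error(misfit_rate(stats, "infit", bounds = c(1, 0)), "lower < upper")
})

test_that("SRMR and SRMSR vanish when observed equals implied and order correctly", {
  obs <- diag(4)
  obs[lower.tri(obs)] <- obs[upper.tri(obs)] <- c(0.3, 0.2, 0.1, 0.25, 0.15, 0.05)
  out <- condrel:::.srmr_from_matrices(obs, obs)
  expect_equal(unname(out), c(0, 0))
  # root-mean-square always dominates the mean absolute residual
  for (seed in 1:5) {
    d <- withr::with_seed(seed, {
      obs2 <- obs
      obs2[lower.tri(obs2)] <- obs2[lower.tri(obs2)] + rnorm(6, 0, 0.05)
      obs2[upper.tri(obs2)] <- t(obs2)[upper.tri(obs2)]
      condrel:::.srmr_from_matrices(obs2, obs)
    })
    expect_gte(d[["srmsr"]], d[["srmr"]])
  }
})

test_that("residual correlations are small when the model is true", {
  ex <- recovery_exam(20, 0.3, 95)
  rs <- simulate_responses(ex, cohort_spec(1500), 96)
  fit <- fit_pcm(rs, ex)
  sr <- srmr_srmsr(fit, rs)
  expect_lt(sr$srmsr, 0.05)
  expect_gte(sr$srmsr, sr$srmr)
  expect_equal(sr$n_pairs, choose(20, 2))
})
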