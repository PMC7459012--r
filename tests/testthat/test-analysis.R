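# Synthetic per-exam report rows for testing the study-level statistics
# without running the whole pipeline.
fake_report <- function(n = 32, seed = 1) {
  withr::with_seed(seed, {
    year <- rep_len(1:5, n)
    range_ <- 85 - 10 * year + rnorm(n, 0, 3)
    items <- round(runif(n, 59, 150))
    mtf <- runif(n, 19, 53)
    ctt <- 0.3 + 0.005 * range_ + 0.001 * items + rnorm(n, 0, 0.02)
    irt <- ctt + 0.1 + 0.002 * range_ + rnorm(n, 0, 0.01)
    tibble::tibble(
      exam_id = sprintf("exam%02d", 1:n),
      crel_cut_ctt = ctt, crel_cut_irt = irt,
      perf_range = range_, n_items = items,
      school = rep_len(c("A", "B", "C"), n),
      pct_mtf = mtf, year = year
    )
  })
}

test_that("cut-score lookup interpolates linearly and respects the support", {
  curve <- tibble::tibble(framework = "ctt",
                          percent_score = c(0, 10, 20),
                          crel = c(0.8, 0.9, 0.7))
  expect_equal(crel_at_cut(curve, 10), 0.9)    # exact grid point
  expect_equal(crel_at_cut(curve, 5), 0.85)    # midway
  expect_equal(crel_at_cut(curve, 17.5), 0.75)
  expect_error(crel_at_cut(curve, 25), "outside")
})

test_that("performance range is max minus min percent", {
  s <- tibble::tibble(examinee_id = c("a", "b", "c"),
                      points = c(4, 10, 14), percent = c(20, 50, 70))
  expect_equal(performance_range(s), 50)
  s$percent <- rep(40, 3)
  expect_equal(performance_range(s), 0)
})

test_that("paired framework ANOVA equals the squared paired t", {
  rep2 <- tibble::tibble(crel_cut_ctt = c(0.5, 0.5),
                         crel_cut_irt = c(0.6, 0.8))
  a <- paired_theory_anova(rep2)
  expect_equal(a$F, 4)           # t = 2 by hand on differences {0.1, 0.3}
  expect_equal(c(a$df1, a$df2), c(1, 1))
  # identical columns: no effect at all
  rep0 <- tibble::tibble(crel_cut_ctt = c(0.7, 0.8, 0.9),
                         crel_cut_irt = c(0.7, 0.8, 0.9))
  expect_equal(paired_theory_anova(rep0)$F, 0)
  # property: F = t^2 on random inputs
  for (seed in 1:5) {
    r <- fake_report(12, seed)
    a <- paired_theory_anova(r)
    tt <- t.test(r$crel_cut_irt, r$crel_cut_ctt, paired = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a$df2, 11)
    expect_gte(a$partial_eta2, 0); expect_lte(a$partial_eta2, 1)
  }
})

test_that("stacked regression has the right structure and exact-fit behaviour", {
  r <- fake_report(32, 2)
  fit <- stacked_regression(r)
  expect_equal(glance(fit)$df1, 9)
  expect_equal(glance(fit)$df2, 64 - 9 - 1)
  expect_equal(fit$n, 64)
  expect_named(tidy(fit), c("term", "B", "SE_B", "beta_std", "t", "p"))
  # response that is an exact linear function of the predictors
  long <- condrel:::stack_report(r)
  r2 <- r
  r2$crel_cut_ctt <- 0.2 + 0.004 * r$perf_range + 0.001 * r$n_items
  r2$crel_cut_irt <- r2$crel_cut_ctt + 0.05
  fit2 <- suppressWarnings(stacked_regression(r2))  # lm warns on perfect fit
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
})

test_that("standardised betas are invariant to rescaling a predictor", {
  r <- fake_report(32, 3)
  b1 <- tidy(stacked_regression(r))
  r_scaled <- r
  r_scaled$perf_range <- r_scaled$perf_range * 10
  b2 <- tidy(stacked_regression(r_scaled))
  expect_equal(b1$beta_std, b2$beta_std, tolerance = 1e-8)
  expect_equal(b1$t, b2$t, tolerance = 1e-8)
  # unstandardised B for the rescaled predictor shrinks by the same factor
  i <- match("perf_range", b1$term)
  expect_equal(b2$B[i], b1$B[i] / 10, tolerance = 1e-10)
})

test_that("rank deficiency is reported with the collinear column", {
  r <- fake_report(32, 4)
  r$pct_mtf <- 30  # constant: its interaction duplicates the theory column
  expect_error(stacked_regression(r), "collinear")
})

test_that("collinearity screen flags redundant predictors, year first", {
  r <- fake_report(32, 5)
  sc <- collinearity_screen(r)
  expect_true("year" %in% sc$excluded)
  ryr <- sc$correlations[sc$correlations$var1 == "year" &
                         sc$correlations$var2 == "perf_range", ]
  expect_lt(ryr$r, -0.7)
  # duplicated predictor is flagged
  r$dup <- r$perf_range
  sc2 <- collinearity_screen(r, c("perf_range", "dup"))
  expect_equal(sc2$correlations$r, 1)
  expect_length(sc2$excluded, 1)
  # independent predictors: no exclusions
  r3 <- withr::with_seed(6, tibble::tibble(
    a = rnorm(64), b = rnorm(64), c = rnorm(64)))
  sc3 <- collinearity_screen(r3, c("a", "b", "c"))
  expect_length(sc3$excluded, 0)
})
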