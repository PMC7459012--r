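test_that("fixed item count and MTF fraction are honoured exactly", {
  cfg <- exam_config(k = 100, mtf_frac = 0.30, cut_percent = 60)
  ex <- generate_exam_spec(cfg, 1)
  expect_equal(nrow(ex$items), 100)
  expect_equal(sum(ex$items$kind == "mtf"), 30)
  expect_equal(ex$max_points, 100)
  expect_equal(ex$items$n_options, ifelse(ex$items$kind == "mtf", 4L, 5L))
  expect_equal(lengths(ex$items$steps),
               ifelse(ex$items$kind == "mtf", 2L, 1L))
})

test_that("banded draws stay inside the configured bands", {
  cfg <- exam_config(k = c(59, 150), mtf_frac = c(0.19, 0.53),
                     cut_percent = c(47.5, 70))
  for (seed in 1:10) {
    ex <- generate_exam_spec(cfg, seed)
    k <- nrow(ex$items)
    expect_gte(k, 59); expect_lte(k, 150)
    n_mtf <- sum(ex$items$kind == "mtf")
    # within +/- 1 item of the configured fraction band
    expect_gte(n_mtf, floor(0.19 * k) - 1)
    expect_lte(n_mtf, ceiling(0.53 * k) + 1)
    expect_gte(ex$cut_percent, 47.5); expect_lte(ex$cut_percent, 70)
    expect_true(all(is.finite(unlist(ex$items$steps))))
  }
})

test_that("generation is deterministic in (config, seed)", {
  cfg <- exam_config(k = c(59, 150))
  expect_identical(generate_exam_spec(cfg, 7), generate_exam_spec(cfg, 7))
  ex <- generate_exam_spec(cfg, 7)
  co <- cohort_spec(40)
  expect_identical(simulate_responses(ex, co, 3), simulate_responses(ex, co, 3))
  sc <- study_config(n_exams = 2, n_examinees = c(20, 30),
                     exam = exam_config(k = c(10, 15)))
  s1 <- generate_study(sc, 5)
  s2 <- generate_study(sc, 5)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$exams[[1]]$responses, s2$exams[[1]]$responses)
})

test_that("invalid generator configurations are rejected", {
  expect_error(exam_config(k = c(100, 50)), "empty")
  expect_error(exam_config(mtf_frac = 1.2), "within")
  expect_error(cohort_spec(1), "at least 2")
  expect_error(cohort_spec(10, ability_sd = 0), "positive")
  expect_error(cohort_spec(10, truncation = c(1, -1)), "low < high")
})

test_that("response probabilities match the logistic model at fixed ability", {
  # single type A item with step 0, abilities pinned at 0: P(score 1) = 0.5
  ex <- make_exam(list(0))
  co <- cohort_spec(10000, ability_mean = 0, ability_sd = 1e-9)
  rs <- simulate_responses(ex, co, 42)
  expect_equal(mean(rs$i001), 0.5, tolerance = 0.015)
  # step -1 at ability 0: P = plogis(1)
  ex2 <- make_exam(list(-1))
  rs2 <- simulate_responses(ex2, co, 43)
  expect_equal(mean(rs2$i001), plogis(1), tolerance = 0.015)
})

test_that("scores saturate at the ability extremes and stay in legal sets", {
  ex <- make_exam(list(0, c(-0.5, 0.5), 1))
  hi <- simulate_responses(ex, cohort_spec(50, 10, 1e-9), 1)
  expect_true(all(hi$i001 == 1 & hi$i002 == 1 & hi$i003 == 1))
  lo <- simulate_responses(ex, cohort_spec(50, -10, 1e-9), 1)
  expect_true(all(lo$i001 == 0 & lo$i002 == 0 & lo$i003 == 0))
  rs <- simulate_responses(ex, cohort_spec(200), 2)
  expect_true(all(rs$i001 %in% c(0, 1)))
  expect_true(all(rs$i002 %in% c(0, 0.5, 1)))
})

test_that("tighter ability truncation shrinks the observed percent-score range", {
  cfg <- exam_config(k = 40, mtf_frac = 0.3, cut_percent = 60)
  ex <- generate_exam_spec(cfg, 9)
  ranges <- vapply(1:20, function(s) {
    wide <- simulate_responses(ex, cohort_spec(150), s)
    narrow <- simulate_responses(ex, cohort_spec(150, truncation = c(-0.5, 0.5)),
                                 1000 + s)
    c(performance_range(total_scores(wide)),
      performance_range(total_scores(narrow)))
  }, c(w = 0, n = 0))
  expect_lt(mean(ranges["n", ]), mean(ranges["w", ]))
})

test_that("a multi-exam study has default-band sizes and year-linked range restriction", {
  study <- generate_study(study_config(), 11)
  expect_equal(nrow(study$manifest), 32)
  expect_true(all(study$manifest$n_examinees >= 146 &
                  study$manifest$n_examinees <= 378))
  expect_true(all(study$manifest$n_items >= 59 & study$manifest$n_items <= 150))
  ranges <- vapply(study$exams, function(e) {
    performance_range(total_scores(e$responses))
  }, 0)
  expect_lt(cor(study$manifest$year, ranges), 0)
  # singleton study
  s1 <- generate_study(study_config(n_exams = 1, n_examinees = c(20, 25),
                                    exam = exam_config(k = 12)), 3)
  expect_equal(length(s1$exams), 1L)
})

test_that("classical item difficulty spans a wide, easy-leaning range", {
  study <- generate_study(study_config(n_exams = 6), 13)
  p <- unlist(lapply(study$exams, function(e) {
    colMeans(condrel:::responses_matrix(e$responses))
  }))
  expect_gt(mean(p), 0.6)
  expect_lt(mean(p), 0.8)
  expect_lt(min(p), 0.25)
  expect_gt(max(p), 0.97)
})
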