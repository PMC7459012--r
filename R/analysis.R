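#' Conditional reliability at the cut score
#'
#' Reads a conditional reliability curve at the exam's cut score (per cent of
#' maximum points) by linear interpolation between the two flanking grid
#' points; exact when the cut coincides with a grid point. Curves are dense
#' (one point per achievable score), so interpolation error is negligible.
#'
#' @param curve A curve tibble from [ctt_crel_curve()] or [irt_crel_curve()]
#'   (needs columns `percent_score` and `crel`).
#' @param cut_percent Cut score in per cent of maximum points.
#' @return A single numeric conditional reliability.
#' @export
crel_at_cut <- function(curve, cut_percent) {
  rng <- range(curve$percent_score)
  if (cut_percent < rng[1] || cut_percent > rng[2]) {
    abort(sprintf("cut %.2f%% lies outside the curve's support [%.2f, %.2f]",
                  cut_percent, rng[1], rng[2]))
  }
  ord <- order(curve$percent_score)
  approx(curve$percent_score[ord], curve$crel[ord], xout = cut_percent,
         ties = "ordered")$y
}

#' Observed performance range of an exam
#'
#' Difference between the maximum and minimum percent score achieved.
#'
#' @param summary Tibble from [total_scores()] (needs column `percent`).
#' @return Range in percentage points.
#' @export
performance_range <- function(summary) {
  if (nrow(summary) < 2L) abort("need at least 2 examinees")
  max(summary$percent) - min(summary$percent)
}

#' Paired comparison of the two frameworks by repeated-measures ANOVA
#'
#' One-way repeated-measures ANOVA with the psychometric framework (CTT vs
#' IRT) as the within-exam factor on conditional reliability at the cut
#' score. With two levels the F statistic equals the squared paired t.
#' Partial eta-squared is `SS_theory / (SS_theory + SS_error)`.
#'
#' @param report Per-exam report tibble with columns `crel_cut_ctt` and
#'   `crel_cut_irt` (see [analyze_exam()]).
#' @return One-row tibble: `F`, `df1`, `df2`, `p`, `partial_eta2`,
#'   `mean_diff` (IRT minus CTT), `boundary` (TRUE when all differences are
#'   identical, where the F statistic is unbounded).
#' @export
paired_theory_anova <- function(report) {
  d <- report$crel_cut_irt - report$crel_cut_ctt
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) abort("need at least 2 exams with both framework values")
  ss_theory <- n * mean(d)^2 / 2
  ss_error <- sum((d - mean(d))^2) / 2
  boundary <- ss_error < 1e-14
  f <- if (boundary) {
    if (ss_theory > 0) Inf else 0
  } else {
    ss_theory / (ss_error / (n - 1))
  }
  tibble::tibble(
    F = f,
    df1 = 1L,
    df2 = n - 1L,
    p = pf(f, 1, n - 1, lower.tail = FALSE),
    partial_eta2 = if (ss_theory + ss_error > 0) {
      ss_theory / (ss_theory + ss_error)
    } else NA_real_,
    mean_diff = mean(d),
    boundary = boundary
  )
}

#' Stacked interaction regression of conditional reliability at the cut
#'
#' Stacks the per-exam report into long format (one row per exam and
#' framework) and fits ordinary least squares of conditional reliability at
#' the cut score on: a framework indicator (0 = CTT, 1 = IRT), performance
#' range, item count, school (single numeric code), percent MTF items, and
#' the four framework-interaction terms — nine predictors plus intercept.
#' Standardised betas come from refitting on z-scored response and
#' predictors, with interactions standardised after forming the product.
#'
#' @param report Per-exam report tibble (see [analyze_exam()]); needs
#'   `crel_cut_ctt`, `crel_cut_irt`, `perf_range`, `n_items`, `school`,
#'   `pct_mtf`.
#' @return An object of class `crel_regression`; [tidy()] gives the
#'   coefficient table (`term`, `B`, `SE_B`, `beta_std`, `t`, `p`),
#'   [glance()] the overall `F`, dfs, `r_squared` and `p`.
#' @export
stacked_regression <- function(report) {
  long <- stack_report(report)
  preds <- c("theory", "perf_range", "n_items", "school_code", "pct_mtf")
  X <- as.matrix(long[preds])
  inter <- X[, "theory"] * X[, preds[-1]]
  colnames(inter) <- paste0("theory_x_", preds[-1])
  M <- cbind(X, inter)
  qr_m <- qr(cbind(1, M))
  if (qr_m$rank < ncol(M) + 1L) {
    dropped <- setdiff(c("(Intercept)", colnames(M)),
                       c("(Intercept)", colnames(M))[qr_m$pivot[seq_len(qr_m$rank)]])
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  df_ <- data.frame(y = long$crel_cut, M, check.names = FALSE)
  fit <- lm(y ~ ., data = df_)
  sm <- summary(fit)
  zs <- function(x) (x - mean(x)) / sd(x)
  dz <- data.frame(y = zs(long$crel_cut), apply(M, 2L, zs),
                   check.names = FALSE)
  beta <- coef(lm(y ~ ., data = dz))
  co <- sm$coefficients
  out <- list(
    coefficients = tibble::tibble(
      term = rownames(co),
      B = co[, 1], SE_B = co[, 2],
      beta_std = ifelse(rownames(co) == "(Intercept)", 0,
                        beta[match(rownames(co), names(beta))]),
      t = co[, 3], p = co[, 4]
    ),
    r_squared = sm$r.squared,
    F = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]),
    df2 = unname(sm$fstatistic[3]),
    n = nrow(long),
    model = fit,
    data = long
  )
  out$p_overall <- pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  class(out) <- "crel_regression"
  out
}

# Long format: one row per exam x framework, theory coded 0 = CTT, 1 = IRT,
# school as a single numeric code (factor level index).
stack_report <- function(report) {
  need <- c("exam_id", "crel_cut_ctt", "crel_cut_irt", "perf_range",
            "n_items", "school", "pct_mtf")
  missing <- setdiff(need, names(report))
  if (length(missing)) {
    abort(paste0("report lacks column(s): ", paste(missing, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(
    report[need], c("crel_cut_ctt", "crel_cut_irt"),
    names_to = "framework", names_prefix = "crel_cut_",
    values_to = "crel_cut"
  )
  long$theory <- as.integer(long$framework == "irt")
  long$school_code <- as.numeric(factor(long$school))
  long[!is.na(long$crel_cut), ]
}

#' @export
print.crel_regression <- function(x, ...) {
  cat(sprintf("Stacked OLS: crel at cut ~ theory * (range, items, school, %%MTF)\n"))
  cat(sprintf("  n = %d, R^2 = %.3f, F(%d/%d) = %.2f, p = %.3g\n",
              x$n, x$r_squared, x$df1, x$df2, x$F, x$p_overall))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname stacked_regression
#' @param x A `crel_regression` object.
#' @param ... Unused.
#' @method tidy crel_regression
#' @export
tidy.crel_regression <- function(x, ...) x$coefficients

#' @rdname stacked_regression
#' @method glance crel_regression
#' @export
glance.crel_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, F = x$F, df1 = x$df1, df2 = x$df2,
                 p = x$p_overall, n = x$n)
}

#' Collinearity screen for the influencing variables
#'
#' Pairwise correlations (with tests) among candidate numeric predictors of
#' the per-exam report. Predictors correlated beyond the threshold with
#' another retained predictor are flagged for exclusion; year of study is
#' dropped first, mirroring the common situation where cohort homogenisation
#' makes year and performance range nearly redundant.
#'
#' @param report Per-exam report tibble.
#' @param predictors Character vector of numeric report columns to screen.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return List with `correlations` (tibble `var1`, `var2`, `r`, `p`),
#'   `excluded` (character) and `retained` (character).
#' @export
collinearity_screen <- function(report,
                                predictors = c("year", "perf_range",
                                               "n_items", "pct_mtf"),
                                threshold = 0.7) {
  missing <- setdiff(predictors, names(report))
  if (length(missing)) {
    abort(paste0("report lacks predictor(s): ", paste(missing, collapse = ", ")))
  }
  X <- report[predictors]
  if (!all(vapply(X, is.numeric, TRUE))) abort("predictors must be numeric")
  pairs <- utils::combn(predictors, 2L)
  cors <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ct <- cor.test(X[[a]], X[[b]])
    tibble::tibble(var1 = a, var2 = b, r = unname(ct$estimate),
                   p = ct$p.value)
  })
  excluded <- character(0)
  # Exclusion order: year first, then by descending involvement.
  order_pref <- c(intersect("year", predictors),
                  setdiff(predictors, "year"))
  repeat {
    active <- cors[!(cors$var1 %in% excluded) & !(cors$var2 %in% excluded), ]
    hot <- active[abs(active$r) > threshold, ]
    if (nrow(hot) == 0L) break
    involved <- unique(c(hot$var1, hot$var2))
    drop <- order_pref[order_pref %in% involved][1]
    excluded <- c(excluded, drop)
  }
  list(correlations = cors, excluded = excluded,
       retained = setdiff(predictors, excluded))
}
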