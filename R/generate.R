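#' Generate a synthetic exam specification
#'
#' Draws an exam blueprint — item count, item kinds (single-best-answer
#' type A vs multiple true-false), step parameters on the logit scale, and a
#' content-style cut score — from the generator settings. Type A items have
#' five answer options and one step parameter; MTF items have four options
#' and two steps (categories 0, 0.5, 1 rescaled to 0, 1, 2). Each item is
#' worth one point, so `max_points` equals the item count.
#'
#' @param config Generator settings, see [exam_config()].
#' @param seed Integer seed; the same `(config, seed)` pair always yields an
#'   identical spec.
#' @return A list of class `exam_spec`: `exam_id`, `items` (tibble with
#'   `item_id`, `kind`, `n_options`, `w`, list-column `steps`), `cut_percent`,
#'   `school`, `year`, `max_points`.
#' @export
generate_exam_spec <- function(config, seed) {
  stopifnot(inherits(config, "exam_config"))
  withr::with_seed(as.integer(seed), {
    k <- draw_int_band(config$k)
    frac <- draw_trunc(config$mtf_frac, config$mtf_frac_mean, config$mtf_frac_sd)
    cut <- draw_trunc(config$cut_percent, config$cut_mean, config$cut_sd)
    n_mtf <- round(frac * k)
    kind <- rep("typeA", k)
    if (n_mtf > 0) kind[sample.int(k, n_mtf)] <- "mtf"
    locs <- draw_item_locations(k, config$difficulty)
    spread <- runif(k, config$mtf_spread[1], config$mtf_spread[2])
    steps <- lapply(seq_len(k), function(i) {
      if (kind[i] == "mtf") c(locs[i] - spread[i], locs[i] + spread[i]) else locs[i]
    })
    items <- tibble::tibble(
      item_id = sprintf("i%03d", seq_len(k)),
      kind = kind,
      n_options = ifelse(kind == "mtf", 4L, 5L),
      w = kind_weight(kind),
      steps = steps
    )
    new_exam_spec(config$exam_id, items, cut, config$school, config$year)
  })
}

new_exam_spec <- function(exam_id, items, cut_percent, school, year) {
  stopifnot(all(items$kind %in% c("typeA", "mtf")))
  n_steps <- lengths(items$steps)
  if (any(n_steps[items$kind == "typeA"] != 1L) ||
      any(n_steps[items$kind == "mtf"] != 2L)) {
    abort("typeA items take exactly 1 step parameter, mtf items exactly 2")
  }
  if (any(!is.finite(unlist(items$steps)))) abort("step parameters must be finite")
  if (cut_percent <= 0 || cut_percent >= 100) {
    abort("`cut_percent` must lie in (0, 100)")
  }
  structure(
    list(exam_id = exam_id, items = items, cut_percent = cut_percent,
         school = school, year = as.integer(year),
         max_points = nrow(items)),
    class = "exam_spec"
  )
}

draw_int_band <- function(band) {
  if (length(band) == 1L) return(as.integer(band))
  as.integer(sample(seq(band[1], band[2]), 1L))
}

draw_trunc <- function(band, mean, sd) {
  if (length(band) == 1L) return(band)
  rtruncnorm(1L, mean, sd, band[1], band[2])
}

# Item locations: main mid-difficulty component plus an easy-item tail, so
# classical difficulty spans most of the unit interval with mean near 0.69
# and the test is informative at low ability.
draw_item_locations <- function(k, d) {
  easy <- runif(k) < d$easy_prob
  ifelse(easy,
         stats::rnorm(k, d$easy_mean, d$easy_sd),
         stats::rnorm(k, d$loc_mean, d$loc_sd))
}

#' Simulate scored responses under the partial credit model
#'
#' Draws examinee abilities from the cohort's (optionally truncated) normal
#' distribution and, for every examinee-item pair, samples the score category
#' from the 1-PL partial-credit category probabilities at that ability.
#' Type A items produce scores in `{0, 1}`, MTF items in `{0, 0.5, 1}`.
#'
#' @param exam An `exam_spec`, see [generate_exam_spec()].
#' @param cohort A [cohort_spec()].
#' @param seed Integer seed.
#' @return Tibble with `examinee_id` and one score column per item, carrying
#'   the drawn abilities in attribute `"abilities"`.
#' @export
simulate_responses <- function(exam, cohort, seed) {
  stopifnot(inherits(exam, "exam_spec"), inherits(cohort, "cohort_spec"))
  withr::with_seed(as.integer(seed), {
    n <- cohort$n_examinees
    tr <- cohort$truncation %||% c(-Inf, Inf)
    theta <- rtruncnorm(n, cohort$ability_mean, cohort$ability_sd, tr[1], tr[2])
    cols <- lapply(seq_len(nrow(exam$items)), function(i) {
      p <- pcm_probs(theta, exam$items$steps[[i]])
      u <- runif(n)
      cat <- rowSums(u > t(apply(p, 1L, cumsum)))
      cat * exam$items$w[i]
    })
    names(cols) <- exam$items$item_id
    out <- tibble::tibble(
      examinee_id = sprintf("p%04d", seq_len(n)),
      !!!cols
    )
    attr(out, "abilities") <- theta
    out
  })
}

#' Generate a full synthetic multi-exam study
#'
#' Produces a collection of exams and scored response matrices with the
#' structure the downstream analysis assumes: per-exam item counts, MTF
#' fractions, cut scores and examinee counts drawn within the configured
#' bands, exams cycled over study years and schools, and a year-linked
#' truncation of the ability distribution so that later-year cohorts show a
#' smaller observed performance range.
#'
#' @param config Study settings, see [study_config()].
#' @param seed Integer seed; the full output is reproducible from
#'   `(config, seed)`.
#' @return A list of class `crel_study` with `exams` (named list of
#'   `list(exam, responses)`) and a `manifest` tibble of per-exam metadata.
#' @export
generate_study <- function(config, seed) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_exams
  seeds <- matrix(derive_seeds(seed, 3L * n), ncol = 3L)
  years <- rep_len(config$years, n)
  schools <- rep_len(config$schools, n)
  exams <- vector("list", n)
  rows <- vector("list", n)
  for (e in seq_len(n)) {
    ec <- config$exam
    ec$exam_id <- sprintf("exam%02d", e)
    ec$school <- schools[e]
    ec$year <- years[e]
    exam <- generate_exam_spec(ec, seeds[e, 1L])
    n_ex <- withr::with_seed(seeds[e, 2L], draw_int_band(config$n_examinees))
    half <- config$trunc_base - config$trunc_slope * (years[e] - 1L)
    trunc <- if (is.finite(half)) {
      config$ability_mean + c(-1, 1) * half * config$ability_sd
    } else NULL
    cohort <- cohort_spec(n_ex, config$ability_mean, config$ability_sd, trunc)
    responses <- simulate_responses(exam, cohort, seeds[e, 3L])
    exams[[e]] <- list(exam = exam, cohort = cohort, responses = responses)
    rows[[e]] <- tibble::tibble(
      exam_id = exam$exam_id,
      n_examinees = n_ex,
      n_items = exam$max_points,
      pct_mtf = 100 * mean(exam$items$kind == "mtf"),
      cut_percent = exam$cut_percent,
      school = schools[e],
      year = years[e],
      trunc_low = if (is.null(trunc)) NA_real_ else trunc[1],
      trunc_high = if (is.null(trunc)) NA_real_ else trunc[2]
    )
  }
  names(exams) <- vapply(exams, function(x) x$exam$exam_id, "")
  structure(
    list(exams = exams, manifest = dplyr::bind_rows(rows), seed = seed,
         config = config),
    class = "crel_study"
  )
}

#' Exam specification from fitted item parameters
#'
#' Rebuilds an `exam_spec` whose step parameters are the estimates of a
#' fitted partial credit model, so that new response data can be simulated
#' from the fitted model itself (parametric-bootstrap style, e.g. for fit
#' calibration checks). Abilities should then be drawn with
#' `ability_sd = fit$sigma`.
#'
#' @param fit A [pcm_fit][fit_pcm()] object.
#' @param exam_id Identifier for the rebuilt exam.
#' @param cut_percent Cut score carried along (default 60).
#' @param school,year Metadata carried along.
#' @return An `exam_spec`.
#' @export
exam_from_fit <- function(fit, exam_id = "fitted", cut_percent = 60,
                          school = "A", year = 1L) {
  stopifnot(inherits(fit, "pcm_fit"))
  items <- tibble::tibble(
    item_id = names(fit$deltas),
    kind = unname(fit$kinds),
    n_options = ifelse(fit$kinds == "mtf", 4L, 5L),
    w = unname(fit$weights),
    steps = unname(fit$deltas)
  )
  new_exam_spec(exam_id, items, cut_percent, school, year)
}

#' @export
print.crel_study <- function(x, ...) {
  cat(sprintf("Synthetic exam study: %d exams (seed %s)\n",
              nrow(x$manifest), format(x$seed)))
  print(x$manifest, n = 8)
  invisible(x)
}
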