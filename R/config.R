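#' Exam generator configuration
#'
#' Settings controlling how a single synthetic exam is drawn. Each of `k`,
#' `mtf_frac` and `cut_percent` can be a single fixed value or a length-2
#' band `c(min, max)`; banded values are drawn per exam (item count uniformly,
#' MTF fraction and cut per cent from a truncated normal whose centre and
#' spread default to the cohort-study values).
#'
#' Item locations (logits) are drawn from a two-component normal mixture with
#' an easy-item tail, so that classical difficulty (mean points per item)
#' averages about 0.69 while spanning nearly the whole unit interval, and the
#' test carries information at the low end of the ability scale. MTF items
#' get two step parameters `centre -/+ spread` on the integer category metric
#' `{0, 1, 2}` (half-point steps).
#'
#' @param k Item count, fixed or band. Default band 59-150.
#' @param mtf_frac Fraction of MTF items, fixed or band. Default band
#'   0.19-0.53 drawn around `mtf_frac_mean`.
#' @param cut_percent Cut score as per cent of maximum points, fixed or band.
#' @param mtf_frac_mean,mtf_frac_sd Centre/spread of the MTF-fraction draw.
#' @param cut_mean,cut_sd Centre/spread of the cut-score draw.
#' @param difficulty List with the location-mixture parameters: `loc_mean`,
#'   `loc_sd` (main component), `easy_mean`, `easy_sd`, `easy_prob`
#'   (easy-item tail).
#' @param mtf_spread Band for the MTF half-spread between the two steps.
#' @param exam_id,school,year Metadata attached to the generated exam.
#' @return A list of class `exam_config`.
#' @export
exam_config <- function(k = c(59, 150),
                        mtf_frac = c(0.19, 0.53),
                        cut_percent = c(47.5, 70),
                        mtf_frac_mean = 0.306,
                        mtf_frac_sd = 0.08,
                        cut_mean = 56.6,
                        cut_sd = 4.7,
                        difficulty = list(loc_mean = -0.8, loc_sd = 0.9,
                                          easy_mean = -2.5, easy_sd = 1,
                                          easy_prob = 0.15),
                        mtf_spread = c(0.4, 1),
                        exam_id = "exam01",
                        school = "A",
                        year = 1L) {
  check_band <- function(x, name, lo, hi) {
    if (!length(x) %in% 1:2 || !is.numeric(x) || any(!is.finite(x))) {
      abort(sprintf("`%s` must be a finite value or a length-2 band", name))
    }
    if (length(x) == 2L && x[1] > x[2]) {
      abort(sprintf("`%s` band is empty (min > max)", name))
    }
    if (any(x < lo | x > hi)) {
      abort(sprintf("`%s` must lie within [%s, %s]", name, lo, hi))
    }
    x
  }
  structure(
    list(
      k = check_band(k, "k", 2, Inf),
      mtf_frac = check_band(mtf_frac, "mtf_frac", 0, 1),
      cut_percent = check_band(cut_percent, "cut_percent", 0, 100),
      mtf_frac_mean = mtf_frac_mean, mtf_frac_sd = mtf_frac_sd,
      cut_mean = cut_mean, cut_sd = cut_sd,
      difficulty = difficulty, mtf_spread = mtf_spread,
      exam_id = exam_id, school = school, year = as.integer(year)
    ),
    class = "exam_config"
  )
}

#' Cohort specification
#'
#' Describes the examinee population for one exam: its size and the (optionally
#' truncated) normal ability distribution on the logit scale. Symmetric
#' truncation models cohort homogenisation (range restriction): in later study
#' years the weakest and strongest candidates are missing, so the observed
#' score range shrinks.
#'
#' @param n_examinees Number of examinees (>= 2).
#' @param ability_mean,ability_sd Mean and SD of the latent ability (logits).
#' @param truncation `NULL` for no truncation, else `c(low, high)` in logits.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_examinees, ability_mean = 0, ability_sd = 1,
                        truncation = NULL) {
  n_examinees <- as.integer(n_examinees)
  if (n_examinees < 2L) abort("`n_examinees` must be at least 2")
  if (!is.numeric(ability_sd) || ability_sd <= 0) {
    abort("`ability_sd` must be positive")
  }
  if (!is.null(truncation)) {
    if (length(truncation) != 2L || truncation[1] >= truncation[2]) {
      abort("`truncation` must be c(low, high) with low < high")
    }
  }
  structure(
    list(n_examinees = n_examinees, ability_mean = ability_mean,
         ability_sd = ability_sd, truncation = truncation),
    class = "cohort_spec"
  )
}

#' Study-level generator configuration
#'
#' Settings for a whole multi-exam study. Exams cycle through study years 1-5
#' and three school labels; the ability distribution is normal with a
#' year-linked symmetric truncation of half-width
#' `trunc_base - trunc_slope * (year - 1)` (in SD units), so later-year
#' cohorts are more homogeneous and their observed score range smaller.
#'
#' @param n_exams Number of exams in the study.
#' @param n_examinees Band for per-exam examinee counts.
#' @param exam Per-exam generator settings, see [exam_config()].
#' @param ability_mean,ability_sd Latent ability distribution (logits).
#' @param trunc_base,trunc_slope Year-linked truncation schedule (SD units);
#'   set `trunc_base = Inf` to disable range restriction. The default ability
#'   SD of 0.7 calibrates the generator to the grand reliability level
#'   typical of high-stakes medical end-of-term exams (Cronbach's alpha
#'   around 0.85).
#' @param schools School labels cycled across exams.
#' @param years Study years cycled across exams.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_exams = 32L,
                         n_examinees = c(146, 378),
                         exam = exam_config(),
                         ability_mean = 0,
                         ability_sd = 0.7,
                         trunc_base = 2.75,
                         trunc_slope = 0.45,
                         schools = c("A", "B", "C"),
                         years = 1:5) {
  n_exams <- as.integer(n_exams)
  if (n_exams < 1L) abort("`n_exams` must be at least 1")
  if (length(n_examinees) == 1L) n_examinees <- rep(n_examinees, 2L)
  if (n_examinees[1] > n_examinees[2] || n_examinees[1] < 2) {
    abort("`n_examinees` band must be non-empty with min >= 2")
  }
  structure(
    list(n_exams = n_exams, n_examinees = n_examinees, exam = exam,
         ability_mean = ability_mean, ability_sd = ability_sd,
         trunc_base = trunc_base, trunc_slope = trunc_slope,
         schools = schools, years = as.integer(years)),
    class = "study_config"
  )
}

#' Estimation settings for the partial credit model
#'
#' @param n_quadrature Number of equally spaced quadrature nodes.
#' @param quadrature_range Node range on the latent scale (logits).
#' @param tol EM convergence tolerance on the marginal log-likelihood gain.
#' @param max_iter Maximum EM iterations; exceeding it flags the fit as not
#'   converged rather than erroring.
#' @param estimate_sigma Estimate the latent SD (mean stays fixed at 0)?
#'   When `FALSE` the latent trait is standard normal.
#' @param step_bound Absolute bound on step parameters during estimation.
#' @return A list of class `pcm_settings`.
#' @export
pcm_settings <- function(n_quadrature = 41L,
                         quadrature_range = c(-6, 6),
                         tol = 1e-5,
                         max_iter = 1000L,
                         estimate_sigma = TRUE,
                         step_bound = 10) {
  stopifnot(n_quadrature >= 5L, quadrature_range[1] < quadrature_range[2],
            tol > 0, max_iter >= 1L, step_bound > 0)
  structure(
    list(n_quadrature = as.integer(n_quadrature),
         quadrature_range = quadrature_range,
         tol = tol, max_iter = as.integer(max_iter),
         estimate_sigma = isTRUE(estimate_sigma),
         step_bound = step_bound),
    class = "pcm_settings"
  )
}
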