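#' Full per-exam analysis: scores, curves, fit, diagnostics, report row
#'
#' Runs the complete single-exam pipeline: total scores and Cronbach's alpha;
#' the CTT conditional reliability curve from the binomial error model; the
#' 1-PL partial credit model fit with Q3/infit/outfit/SRMR diagnostics;
#' weighted likelihood ability estimates, test information and the IRT
#' conditional reliability curve; and conditional reliability at the cut
#' score in both frameworks. Maximum and average conditional reliability are
#' taken over the scores actually achieved in the exam (for IRT, over the
#' ability estimates of the achieved scores), not over the whole grid.
#'
#' @param exam An `exam_spec`.
#' @param responses Scored responses for that exam.
#' @param settings Estimation settings, see [pcm_settings()].
#' @param misfit_bounds Mean-square bounds for the misfit rates.
#' @param drop_items Optional character vector of item ids to drop before
#'   analysis (post-hoc eliminated items).
#' @return A list of class `exam_analysis`: `report` (one-row tibble),
#'   `ctt_curve`, `irt_curve`, `fit`, `thetas`, `fit_report`, `scores`.
#' @export
analyze_exam <- function(exam, responses, settings = pcm_settings(),
                         misfit_bounds = c(0.8, 1.2), drop_items = NULL) {
  stopifnot(inherits(exam, "exam_spec"))
  if (length(drop_items)) {
    unknown <- setdiff(drop_items, exam$items$item_id)
    if (length(unknown)) {
      abort(paste0("drop_items not in exam: ", paste(unknown, collapse = ", ")))
    }
    exam$items <- exam$items[!exam$items$item_id %in% drop_items, ]
    exam$max_points <- nrow(exam$items)
    responses <- responses[, c("examinee_id", exam$items$item_id)]
  }
  # Items every examinee scored identically (classical difficulty 0 or 1)
  # carry no information in either framework and leave the partial credit
  # model unidentified; they are removed from the analysed test form.
  const <- vapply(exam$items$item_id, function(id) {
    length(unique(responses[[id]])) < 2L
  }, TRUE)
  if (any(const)) {
    inform(sprintf("[%s] dropping %d constant item(s): %s", exam$exam_id,
                   sum(const),
                   paste(exam$items$item_id[const], collapse = ", ")))
    exam$items <- exam$items[!const, ]
    exam$max_points <- nrow(exam$items)
    responses <- responses[, c("examinee_id", exam$items$item_id)]
  }

  summary <- total_scores(responses)
  alpha <- cronbach_alpha(responses)
  ctt_curve <- ctt_crel_curve(responses, exam)
  cut <- exam$cut_percent
  ctt_achieved <- ctt_curve[ctt_curve$achieved, ]

  fit <- fit_pcm(responses, exam, settings)
  thetas <- wle_theta(fit, responses)
  irt_curve <- irt_crel_curve(fit, thetas)
  v_theta <- attr(irt_curve, "variance_used")
  theta_achieved <- unique(thetas$theta)
  info_achieved <- test_information(fit, theta_achieved)$info
  crel_achieved_irt <- (v_theta - 1 / info_achieved) / v_theta
  fitrep <- fit_report(fit, responses, thetas, misfit_bounds)

  report <- tibble::tibble(
    exam_id = exam$exam_id,
    crel_cut_ctt = crel_at_cut(ctt_curve, cut),
    crel_cut_irt = crel_at_cut(irt_curve, cut),
    crel_max_ctt = max(ctt_achieved$crel),
    crel_max_irt = max(crel_achieved_irt),
    crel_mean_ctt = mean(ctt_achieved$crel),
    crel_mean_irt = mean(crel_achieved_irt),
    alpha = alpha,
    separation = separation_index(thetas),
    perf_range = performance_range(summary),
    n_items = exam$max_points,
    pct_mtf = 100 * mean(exam$items$kind == "mtf"),
    school = exam$school,
    year = exam$year,
    cut_percent = cut,
    n_examinees = nrow(responses)
  )
  structure(
    list(report = report, ctt_curve = ctt_curve, irt_curve = irt_curve,
         fit = fit, thetas = thetas, fit_report = fitrep, scores = summary),
    class = "exam_analysis"
  )
}

#' Analyse every exam of a generated study and compare the frameworks
#'
#' Applies [analyze_exam()] to each exam (a failure in one exam is reported
#' and skips only that exam), assembles the per-exam cut-score report, and
#' runs the study-level comparisons: the paired framework ANOVA, the
#' collinearity screen of influencing variables (excluding, by default, year
#' of study when it is redundant with performance range), and the stacked
#' interaction regression.
#'
#' @param study A `crel_study` from [generate_study()].
#' @inheritParams analyze_exam
#' @param drop_items Optional named list: exam id -> item ids to drop.
#' @return A list of class `crel_study_result` with `report`, `fit_reports`,
#'   `anova`, `screen`, `regression`, `curves` (per-exam CTT/IRT curve
#'   tibbles), `manifest`, `failed` (character vector of failed exam ids).
#' @export
analyze_study <- function(study, settings = pcm_settings(),
                          misfit_bounds = c(0.8, 1.2), drop_items = list()) {
  stopifnot(inherits(study, "crel_study"))
  analyses <- vector("list", length(study$exams))
  names(analyses) <- names(study$exams)
  failed <- character(0)
  for (id in names(study$exams)) {
    analyses[[id]] <- tryCatch(
      analyze_exam(study$exams[[id]]$exam, study$exams[[id]]$responses,
                   settings, misfit_bounds, drop_items[[id]]),
      error = function(e) {
        inform(sprintf("[%s] analysis failed: %s", id, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(analyses[[id]])) failed <- c(failed, id)
  }
  ok <- !vapply(analyses, is.null, TRUE)
  report <- dplyr::bind_rows(lapply(analyses[ok], function(a) a$report))
  fit_reports <- dplyr::bind_cols(
    tibble::tibble(exam_id = report$exam_id),
    dplyr::bind_rows(lapply(analyses[ok], function(a) a$fit_report))
  )
  curves <- lapply(analyses[ok], function(a) {
    list(ctt = a$ctt_curve, irt = a$irt_curve)
  })
  anova <- if (nrow(report) >= 2L) paired_theory_anova(report) else NULL
  screen <- if (nrow(report) >= 4L) collinearity_screen(report) else NULL
  regression <- if (nrow(report) >= 7L) {
    tryCatch(stacked_regression(report), error = function(e) {
      inform(paste0("stacked regression failed: ", conditionMessage(e)))
      NULL
    })
  } else NULL
  structure(
    list(report = report, fit_reports = fit_reports, anova = anova,
         screen = screen, regression = regression, curves = curves,
         manifest = study$manifest, failed = failed, seed = study$seed,
         config = study$config),
    class = "crel_study_result"
  )
}

#' Generate and analyse a synthetic study end to end
#'
#' Convenience driver: [generate_study()] then [analyze_study()], optionally
#' writing the full output tree (manifest, per-exam reports, fit indices,
#' comparison results, curve CSVs and the summary figure) to a directory.
#'
#' @param config Study settings, see [study_config()].
#' @param seed Integer seed; the whole run is reproducible from
#'   `(config, seed)`.
#' @param out_dir Optional output directory, created if needed.
#' @inheritParams analyze_study
#' @return A `crel_study_result` (invisibly when `out_dir` is given).
#' @export
run_study <- function(config = study_config(), seed, out_dir = NULL,
                      settings = pcm_settings(),
                      misfit_bounds = c(0.8, 1.2), drop_items = list()) {
  study <- generate_study(config, seed)
  result <- analyze_study(study, settings, misfit_bounds, drop_items)
  if (!is.null(out_dir)) {
    write_study_outputs(result, out_dir)
    return(invisible(result))
  }
  result
}

#' @export
print.crel_study_result <- function(x, ...) {
  cat(sprintf("Study result: %d exams analysed (%d failed)\n",
              nrow(x$report), length(x$failed)))
  if (nrow(x$report)) {
    cat(sprintf("  mean crel at cut: CTT %.3f, IRT %.3f\n",
                mean(x$report$crel_cut_ctt), mean(x$report$crel_cut_irt)))
  }
  if (!is.null(x$anova)) {
    cat(sprintf("  paired ANOVA: F(%d/%d) = %.2f, p = %.3g, partial eta2 = %.2f\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p,
                x$anova$partial_eta2))
  }
  if (!is.null(x$regression)) {
    cat(sprintf("  regression: R^2 = %.3f, F(%d/%d) = %.2f\n",
                x$regression$r_squared, x$regression$df1, x$regression$df2,
                x$regression$F))
  }
  invisible(x)
}

#' Write the full output tree of a study result
#'
#' Writes `manifest.tsv`, `report.tsv`, `fit_indices.tsv`, `anova.json`,
#' `regression.tsv`, `correlations.tsv`, per-exam curve CSVs under `curves/`,
#' the summary figure `crel_curves.png` and its plotted numbers
#' `crel_curves.csv`. Machine-readable files keep full precision.
#'
#' @param result A `crel_study_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_outputs <- function(result, dir) {
  stopifnot(inherits(result, "crel_study_result"))
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$manifest, file.path(dir, "manifest.tsv"))
  if (!is.null(result$config)) {
    # resolved configuration + seed: everything needed to regenerate the run
    jsonlite::write_json(
      list(seed = result$seed, config = unclass_deep(result$config)),
      file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  }
  readr::write_tsv(result$report, file.path(dir, "report.tsv"))
  readr::write_tsv(result$fit_reports, file.path(dir, "fit_indices.tsv"))
  if (!is.null(result$anova)) {
    jsonlite::write_json(as.list(result$anova), file.path(dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$regression)) {
    readr::write_tsv(tidy(result$regression), file.path(dir, "regression.tsv"))
  }
  if (!is.null(result$screen)) {
    readr::write_tsv(result$screen$correlations,
                     file.path(dir, "correlations.tsv"))
  }
  for (id in names(result$curves)) {
    readr::write_csv(curve_export(result$curves[[id]]$ctt),
                     file.path(dir, "curves", paste0(id, "_ctt.csv")))
    readr::write_csv(curve_export(result$curves[[id]]$irt),
                     file.path(dir, "curves", paste0(id, "_irt.csv")))
  }
  band <- curve_band_data(result$curves)
  readr::write_csv(band, file.path(dir, "crel_curves.csv"))
  p <- plot_crel_curves(result$curves)
  ggplot2::ggsave(file.path(dir, "crel_curves.png"), p,
                  width = 7, height = 4.5, dpi = 150)
  invisible(dir)
}

curve_export <- function(curve) {
  keep <- intersect(c("framework", "percent_score", "points", "theta", "info",
                      "csem", "csem_theta", "crel", "achieved", "negative"),
                    names(curve))
  curve[keep]
}
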