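#' Mean conditional reliability bands across exams
#'
#' Resamples each exam's conditional reliability curve onto a common percent
#' score grid (linear interpolation inside each curve's support, `NA`
#' outside) and summarises per framework and grid point by the mean and SD
#' across exams. These are exactly the numbers drawn by
#' [plot_crel_curves()], so the figure is auditable.
#'
#' @param curves Either a `crel_study_result`, its `curves` element (a list
#'   of per-exam lists of curve tibbles), or a flat list of curve tibbles.
#' @param percent_grid Common percent-score grid.
#' @return Tibble with `framework`, `percent_score`, `mean_crel`, `sd_crel`,
#'   `n_exams`.
#' @export
curve_band_data <- function(curves, percent_grid = 1:99) {
  flat <- flatten_curves(curves)
  if (length(flat) == 0L) abort("no curves supplied")
  resampled <- purrr::imap_dfr(flat, function(curve, nm) {
    ord <- order(curve$percent_score)
    y <- approx(curve$percent_score[ord], curve$crel[ord],
                xout = percent_grid, ties = "ordered", rule = 1)$y
    tibble::tibble(curve_id = nm,
                   framework = curve$framework[1],
                   percent_score = percent_grid,
                   crel = y)
  })
  resampled |>
    dplyr::filter(!is.na(.data$crel)) |>
    dplyr::group_by(.data$framework, .data$percent_score) |>
    dplyr::summarise(mean_crel = mean(.data$crel),
                     sd_crel = if (dplyr::n() > 1L) sd(.data$crel) else 0,
                     n_exams = dplyr::n(), .groups = "drop")
}

flatten_curves <- function(curves) {
  if (inherits(curves, "crel_study_result")) curves <- curves$curves
  if (is.data.frame(curves)) curves <- list(curves)
  out <- list()
  for (i in seq_along(curves)) {
    el <- curves[[i]]
    nm <- names(curves)[i] %||% as.character(i)
    if (is.data.frame(el)) {
      out[[paste0(nm, "_", el$framework[1])]] <- el
    } else {
      for (j in seq_along(el)) {
        out[[paste0(nm, "_", el[[j]]$framework[1])]] <- el[[j]]
      }
    }
  }
  out
}

#' Plot mean conditional reliability curves with SD bands
#'
#' One series per framework (CTT, IRT) on a shared percent-correct axis:
#' line at the across-exam mean, ribbon at mean +/- 1 SD. A single exam
#' yields a band of width zero; a single framework yields a single series.
#'
#' @inheritParams curve_band_data
#' @return A ggplot object.
#' @export
plot_crel_curves <- function(curves, percent_grid = 1:99) {
  band <- curve_band_data(curves, percent_grid)
  ggplot2::ggplot(band,
                  ggplot2::aes(x = .data$percent_score, y = .data$mean_crel,
                               colour = toupper(.data$framework),
                               fill = toupper(.data$framework))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_crel - .data$sd_crel,
                                      ymax = .data$mean_crel + .data$sd_crel),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Score (% correct)", y = "Conditional reliability",
                  colour = "Framework", fill = "Framework") +
    ggplot2::theme_minimal()
}

#' @rdname plot_crel_curves
#' @param object A `crel_study_result`.
#' @param ... Passed on to [plot_crel_curves()].
#' @importFrom ggplot2 autoplot
#' @method autoplot crel_study_result
#' @export
autoplot.crel_study_result <- function(object, ...) {
  plot_crel_curves(object$curves, ...)
}
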