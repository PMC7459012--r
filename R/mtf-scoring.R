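#' Partial-credit score for a multiple true-false item
#'
#' Multiple true-false (MTF) items present several independent true/false
#' ratings (four by default). An examinee earns one point when every rating is
#' marked correctly, half a point when more than half (but not all) are
#' correct, and zero points otherwise.
#'
#' @param ratings_correct Integer vector, number of correctly marked ratings.
#' @param n_ratings Number of true/false ratings per item (default 4).
#' @return Numeric vector of points in `{0, 0.5, 1}`.
#' @examples
#' score_mtf_item(0:4)
#' @export
score_mtf_item <- function(ratings_correct, n_ratings = 4L) {
  if (length(n_ratings) != 1L || n_ratings < 1L) {
    abort("`n_ratings` must be a single positive integer")
  }
  if (any(ratings_correct < 0 | ratings_correct > n_ratings)) {
    abort("`ratings_correct` must lie in [0, n_ratings]")
  }
  if (any(ratings_correct != round(ratings_correct))) {
    abort("`ratings_correct` must be whole numbers")
  }
  dplyr::case_when(
    ratings_correct == n_ratings ~ 1,
    ratings_correct > n_ratings / 2 ~ 0.5,
    .default = 0
  )
}
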