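#' Write and read scored response matrices as CSV
#'
#' The on-disk format is one header row (`examinee_id` then item ids) and one
#' row per examinee, full precision. Reading validates the file: rectangular,
#' no missing cells, at least 2 examinees, at least 2 distinct total scores,
#' and every entry in the legal score set for its item (`{0, 1}` for type A,
#' `{0, 0.5, 1}` for MTF; without an exam spec, `{0, 0.5, 1}` throughout).
#' Violations are reported with the offending examinee/item coordinates.
#'
#' @param responses Responses tibble.
#' @param path File path.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   the validated responses tibble.
#' @export
write_responses <- function(responses, path) {
  stopifnot("examinee_id" %in% names(responses))
  readr::write_csv(responses, path)
  invisible(path)
}

#' @rdname write_responses
#' @param exam Optional `exam_spec` to validate item ids and per-kind score
#'   sets against.
#' @export
read_responses <- function(path, exam = NULL) {
  responses <- readr::read_csv(path, col_types = readr::cols(
    examinee_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_responses(responses, exam)
}

#' @rdname write_responses
#' @export
validate_responses <- function(responses, exam = NULL) {
  if (names(responses)[1] != "examinee_id") {
    abort("first column must be `examinee_id`")
  }
  scores <- responses_matrix(responses)
  if (nrow(scores) < 2L) {
    abort(paste0("only ", nrow(scores), " examinee(s): variance-based ",
                 "statistics (reliability, cSEM standardisation) are undefined"))
  }
  na_idx <- which(is.na(scores), arr.ind = TRUE)
  if (nrow(na_idx)) {
    abort(sprintf("missing score for examinee '%s', item '%s'",
                  rownames(scores)[na_idx[1, 1]],
                  colnames(scores)[na_idx[1, 2]]))
  }
  kinds <- if (is.null(exam)) {
    setNames(rep("mtf", ncol(scores)), colnames(scores))  # permissive set
  } else {
    item_kinds_for(scores, exam)
  }
  for (i in seq_len(ncol(scores))) {
    allowed <- if (kinds[i] == "mtf") c(0, 0.5, 1) else c(0, 1)
    bad <- which(!scores[, i] %in% allowed)
    if (length(bad)) {
      abort(sprintf(
        "illegal score %s for examinee '%s', item '%s' (allowed: %s)",
        format(scores[bad[1], i]), rownames(scores)[bad[1]],
        colnames(scores)[i], paste(allowed, collapse = "/")))
    }
  }
  if (length(unique(rowSums(scores))) < 2L) {
    abort("all examinees have the same total score: variance-based statistics are undefined")
  }
  responses
}

#' Write and read exam specifications as JSON or YAML
#'
#' The format (chosen by file extension, `.json` vs `.yml`/`.yaml`) stores
#' `exam_id`, `cut_percent`, `school`, `year` and the per-item records
#' (`item_id`, `kind`, `n_options`, `steps`).
#'
#' @param exam An `exam_spec`.
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `write_exam_spec()` returns `path` invisibly; `read_exam_spec()`
#'   the reconstructed `exam_spec`.
#' @export
write_exam_spec <- function(exam, path) {
  stopifnot(inherits(exam, "exam_spec"))
  obj <- list(
    exam_id = exam$exam_id,
    cut_percent = exam$cut_percent,
    school = exam$school,
    year = exam$year,
    items = lapply(seq_len(nrow(exam$items)), function(i) {
      list(item_id = exam$items$item_id[i],
           kind = exam$items$kind[i],
           n_options = exam$items$n_options[i],
           steps = exam$items$steps[[i]])
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    abort("`path` must end in .json, .yml or .yaml")
  }
  invisible(path)
}

#' @rdname write_exam_spec
#' @export
read_exam_spec <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    abort("`path` must end in .json, .yml or .yaml")
  }
  items <- tibble::tibble(
    item_id = vapply(obj$items, function(x) x$item_id, ""),
    kind = vapply(obj$items, function(x) x$kind, ""),
    n_options = vapply(obj$items, function(x) as.integer(x$n_options), 1L),
    w = kind_weight(vapply(obj$items, function(x) x$kind, "")),
    steps = lapply(obj$items, function(x) as.numeric(unlist(x$steps)))
  )
  new_exam_spec(obj$exam_id, items, obj$cut_percent, obj$school, obj$year)
}
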