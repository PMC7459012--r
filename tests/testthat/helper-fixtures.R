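# Shared builders for test fixtures: all data are generated in code.

# Responses tibble from a plain score matrix.
make_responses <- function(m) {
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    colnames(m) <- sprintf("i%03d", seq_len(ncol(m)))
  }
  tibble::tibble(
    examinee_id = sprintf("p%04d", seq_len(nrow(m))),
    !!!as.data.frame(m)
  )
}

# Hand-built exam spec (bypasses the generator) from a list of step vectors.
make_exam <- function(steps, cut_percent = 60, exam_id = "handmade",
                      school = "A", year = 1L) {
  kind <- ifelse(lengths(steps) == 2L, "mtf", "typeA")
  items <- tibble::tibble(
    item_id = sprintf("i%03d", seq_along(steps)),
    kind = kind,
    n_options = ifelse(kind == "mtf", 4L, 5L),
    w = ifelse(kind == "mtf", 0.5, 1),
    steps = steps
  )
  condrel:::new_exam_spec(exam_id, items, cut_percent, school, year)
}

# pcm_fit object with known parameters (no estimation), for unit-testing the
# person-side machinery in isolation.
make_fit <- function(steps, sigma = 1) {
  exam <- make_exam(steps)
  deltas <- setNames(steps, exam$items$item_id)
  structure(
    list(item_params = tibble::tibble(
           item_id = rep(exam$items$item_id, lengths(steps)),
           kind = rep(exam$items$kind, lengths(steps)),
           step = unlist(lapply(lengths(steps), seq_len)),
           estimate = unlist(steps)),
         deltas = deltas,
         kinds = setNames(exam$items$kind, exam$items$item_id),
         weights = setNames(exam$items$w, exam$items$item_id),
         log_likelihood = NA_real_, sigma = sigma, converged = TRUE,
         n_iter = 0L, iteration_trace = numeric(0),
         n_examinees = NA_integer_, n_quadrature = 41L,
         quadrature_range = c(-6, 6), settings = pcm_settings()),
    class = "pcm_fit"
  )
}

# Parameter-recovery study design: type A locations uniform on [-2, 2], MTF
# centres uniform on [-1.5, 1.5] with half-spreads on [0.4, 0.8] (keeps all
# categories observable at moderate n).
recovery_exam <- function(k, mtf_frac, seed) {
  withr::with_seed(seed, {
    n_mtf <- round(mtf_frac * k)
    kind <- rep("typeA", k)
    if (n_mtf > 0) kind[sample.int(k, n_mtf)] <- "mtf"
    ctr <- ifelse(kind == "mtf", runif(k, -1.5, 1.5), runif(k, -2, 2))
    sp <- runif(k, 0.4, 0.8)
    steps <- lapply(seq_len(k), function(i) {
      if (kind[i] == "mtf") c(ctr[i] - sp[i], ctr[i] + sp[i]) else ctr[i]
    })
    make_exam(steps, exam_id = sprintf("recovery_k%d", k))
  })
}

true_steps <- function(exam) unlist(exam$items$steps)

`%||%` <- rlang::`%||%`
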