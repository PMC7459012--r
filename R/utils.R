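# Internal helpers shared across modules.

# Draw from a normal truncated to [lo, hi] by inverse-CDF; lo/hi may be -Inf/Inf.
rtruncnorm <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  stopifnot(sd > 0, lo < hi)
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

# Derive a stream of child seeds from one user seed without touching the
# caller's RNG state. Values stay well below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147480000L, n))
}

# Convert a wide responses tibble (examinee_id + one column per item) to a
# plain numeric matrix of points with examinee ids as rownames.
responses_matrix <- function(responses) {
  stopifnot(is.data.frame(responses), "examinee_id" %in% names(responses))
  items <- setdiff(names(responses), "examinee_id")
  if (length(items) == 0L) abort("responses contain no item columns")
  m <- as.matrix(responses[items])
  if (!is.numeric(m)) abort("item columns must be numeric scores")
  rownames(m) <- as.character(responses$examinee_id)
  m
}

# Item step weight in points per category step: 1 for typeA, 0.5 for mtf.
kind_weight <- function(kind) ifelse(kind == "mtf", 0.5, 1)

# Infer item kinds from observed score columns when no exam spec is supplied:
# any half-point value marks an mtf item.
infer_kinds <- function(scores) {
  apply(scores, 2L, function(x) {
    if (any(abs(x - round(x)) > 1e-9)) "mtf" else "typeA"
  })
}

# Category-metric matrix (integers 0..m_i) from a points matrix + weights.
points_to_categories <- function(scores, w) {
  cats <- sweep(scores, 2L, w, "/")
  if (max(abs(cats - round(cats))) > 1e-6) {
    abort("scores are not multiples of their item's step weight")
  }
  round(cats)
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Strip S3 classes recursively so configuration lists serialise as plain JSON.
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
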