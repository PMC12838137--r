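#' @importFrom rlang %||% abort warn inform
#' @importFrom stats var sd cor rnorm runif rbinom rchisq setNames
#' @importFrom stats dist hclust cutree cophenetic cmdscale kmeans residuals
#' @importFrom stats aggregate coef predict t.test acf quantile median
#' @importFrom utils head tail
NULL

# child seeds derived from one global seed by fixed offsets, kept < 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

assert_fraction <- function(x, name, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a fraction in %s0, 1].", name,
                  if (allow_zero) "[" else "("))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# deterministic top-k by value, ties broken by id (lexicographic)
top_k_ids <- function(ids, values, k) {
  ord <- order(-values, ids)
  ids[ord][seq_len(min(k, length(ids)))]
}

upper_tri_vec <- function(m) m[upper.tri(m)]
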