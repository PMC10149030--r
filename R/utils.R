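# Internal helpers shared across modules.

# Deterministic sub-seed for a named sub-stream, keeping everything inside a
# 32-bit signed range.  Each artifact (cohort, genome, qPCR plate) draws from
# its own namespaced stream so that adding one stage never perturbs another.
derive_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x) || x < lower) {
    abort(sprintf("`%s` must be a single integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}

# Matrix with feature rownames / sample colnames from a feature-by-sample
# data frame whose first column holds the feature ids.
df_to_matrix <- function(df, feature_col = 1L) {
  ids <- as.character(df[[feature_col]])
  m <- as.matrix(df[, -feature_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, feature_col) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!feature_col := rownames(m)), out)
}
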