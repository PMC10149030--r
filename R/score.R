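#' Single-sample rank score for a gene signature
#'
#' Rank-based signature score in the style of single-sample gene-set
#' scoring: all `n` genes of the sample are ranked ascending with average
#' ties, and the up-component is the normalized displacement of the up
#' set's mean rank from its minimum attainable value,
#' \deqn{(\,\overline{rank}(up) - (m_u + 1)/2\,)/(n - m_u) - 0.5,}
#' which spans \[-0.5, 0.5\].  The down-component applies the same formula
#' to the reversed ranks \eqn{n + 1 - rank}.  The score is the sum of the
#' available components, so it lies in \[-1, 1\] for a bidirectional
#' signature and \[-0.5, 0.5\] for an up-only one.  Being purely rank-based
#' it is invariant to any strictly monotone transform of the expression
#' values.
#'
#' @param expr named numeric vector: one sample's expression over all genes.
#' @param up,down character vectors of signature genes; genes absent from
#'   `expr` are dropped with a warning; either set may be empty or `NULL`
#'   (its term is omitted) but not both.
#' @return A single score.  A set spanning the whole transcriptome has no
#'   rank freedom; its component is defined as 0 with a `degenerate`
#'   attribute.
#' @examples
#' rank_score(c(g1 = 10, g2 = 2, g3 = 7, g4 = 1, g5 = 9), up = c("g1", "g5"))
#' @export
rank_score <- function(expr, up, down = NULL) {
  n <- length(expr)
  r <- rank(expr, ties.method = "average")
  component <- function(set, ranks) {
    m <- length(set)
    if (m == 0) return(NULL)
    if (m == n) {
      warn("signature set spans the whole transcriptome; component degenerate")
      return(structure(0, degenerate = TRUE))
    }
    (mean(ranks[set]) - (m + 1) / 2) / (n - m) - 0.5
  }
  drop_missing <- function(set) {
    if (is.null(set)) return(NULL)
    missing <- setdiff(set, names(expr))
    if (length(missing) > 0) {
      warn(sprintf("%d signature gene(s) absent from expression, dropped",
                   length(missing)))
    }
    intersect(set, names(expr))
  }
  up <- drop_missing(up)
  down <- drop_missing(down)
  if (length(up) == 0 && length(down) == 0) {
    abort("both signature sets empty after dropping missing genes")
  }
  cu <- component(up, r)
  cd <- component(down, n + 1 - r)
  degenerate <- isTRUE(attr(cu, "degenerate")) || isTRUE(attr(cd, "degenerate"))
  out <- as.numeric(cu %||% 0) + as.numeric(cd %||% 0)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Score every sample against every subtype signature
#'
#' @param expression genes x samples matrix.
#' @param signatures a [derive_signatures()] result (unusable signatures are
#'   skipped with a warning) or a named list of lists with `up` and
#'   optionally `down` character vectors.
#' @return Tibble: `sample_id` plus one `score_<subtype>` column per usable
#'   signature.  Samples with all-constant expression get score 0 and are
#'   flagged in the `constant_sample` column.
#' @export
score_matrix <- function(expression, signatures) {
  usable <- Filter(function(s) !isFALSE(s$usable), signatures)
  if (length(usable) == 0) abort("no usable signatures")
  if (length(usable) < length(signatures)) {
    warn(sprintf("%d unusable signature(s) skipped",
                 length(signatures) - length(usable)))
  }
  constant <- apply(expression, 2, function(x) max(x) == min(x))
  scores <- vapply(usable, function(sg) {
    apply(expression, 2, function(x) {
      as.numeric(rank_score(x, sg$up, if (length(sg$down)) sg$down else NULL))
    })
  }, numeric(ncol(expression)))
  scores <- matrix(scores, ncol = length(usable),
                   dimnames = list(colnames(expression),
                                   paste0("score_", names(usable))))
  scores[constant, ] <- 0
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(expression)),
    tibble::as_tibble(scores)
  )
  out$constant_sample <- unname(constant)
  out
}

#' k-nearest-neighbor subtype assignment in signature-score space
#'
#' Each score dimension is standardized by the training mean and sd, test
#' samples are matched to their `k` nearest training samples by Euclidean
#' distance, and the per-subtype probability is the unweighted fraction of
#' those neighbors carrying each label (so probabilities are exact
#' multiples of 1/k).  The assignment is the argmax; ties between subtypes
#' are broken by the label of the single nearest neighbor among the tied
#' subtypes.  Equal distances are ordered deterministically by
#' (distance, training sample id).
#'
#' @param train_scores,test_scores tibbles from [score_matrix()] (or any
#'   data frame with `sample_id` and shared numeric score columns).
#' @param train_labels named character vector: subtype per training
#'   sample id.
#' @param k neighborhood size, `1 <= k <=` number of training samples
#'   (default 30).
#' @return Tibble: `sample_id`, `assigned`, one `p_<subtype>` probability
#'   column per subtype.
#' @export
knn_assign <- function(train_scores, train_labels, test_scores, k = 30) {
  score_cols <- intersect(
    grep("^score_", names(train_scores), value = TRUE),
    grep("^score_", names(test_scores), value = TRUE)
  )
  if (length(score_cols) == 0) abort("no shared score_* columns")
  tr <- as.matrix(train_scores[, score_cols])
  rownames(tr) <- train_scores$sample_id
  te <- as.matrix(test_scores[, score_cols])
  rownames(te) <- test_scores$sample_id
  k <- assert_count(k, "k", 1)
  if (k > nrow(tr)) abort(sprintf("k = %d exceeds %d training samples", k, nrow(tr)))
  labels <- train_labels[rownames(tr)]
  if (anyNA(labels)) abort("every training sample needs a label")
  subtypes <- sort(unique(labels))

  mu <- colMeans(tr)
  sdv <- apply(tr, 2, sd)
  sdv[sdv == 0] <- 1
  trs <- sweep(sweep(tr, 2, mu), 2, sdv, `/`)
  tes <- sweep(sweep(te, 2, mu), 2, sdv, `/`)

  # deterministic neighbor order: distance, then training sample id
  assign_one <- function(x) {
    d <- sqrt(colSums((t(trs) - x)^2))
    ord <- order(d, rownames(trs), method = "radix")
    nb <- ord[seq_len(k)]
    probs <- vapply(subtypes, function(s) sum(labels[nb] == s) / k, numeric(1))
    top <- subtypes[probs == max(probs)]
    if (length(top) > 1) {
      first_tied <- nb[labels[nb] %in% top][1]
      top <- labels[[first_tied]]
    }
    list(assigned = top, probs = probs)
  }
  res <- apply(tes, 1, assign_one)
  probs <- t(vapply(res, `[[`, numeric(length(subtypes)), "probs"))
  colnames(probs) <- paste0("p_", subtypes)
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(te),
                   assigned = unname(vapply(res, `[[`, character(1), "assigned"))),
    tibble::as_tibble(probs)
  )
}
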