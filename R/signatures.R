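#' Derive per-subtype expression signatures from labeled tumors
#'
#' Runs a one-vs-rest moderated-t contrast for each known subtype with a
#' fold-change threshold test at `logfc_threshold`: the up set holds genes
#' with `logfc > logfc_threshold` and BH-adjusted threshold p-value below
#' `alpha`, the down set the mirror image.  The resulting gene lists are
#' the signatures consumed by [score_matrix()] for label transfer.
#'
#' @param expression genes x samples matrix (log scale).
#' @param labels named character vector: subtype (`"1"`, `"2"`, `"3"`, ...)
#'   per labeled tumor sample id; each subtype needs >= 2 samples.
#' @param logfc_threshold fold-change threshold on the log2 scale
#'   (default 1.5).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param prior optional shared [estimate_prior()] result; estimated per
#'   contrast when `NULL`.
#' @return A named list of class `gene_signatures`; per subtype a list with
#'   `up`, `down` (character vectors), `usable` (both sets considered;
#'   `FALSE` when both empty) and `de` (the full `moderated_t_fit` tibble).
#' @export
derive_signatures <- function(expression, labels, logfc_threshold = 1.5,
                              alpha = 0.05, prior = NULL) {
  labels <- labels[labels != "unknown" & !is.na(labels)]
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2) abort("need >= 2 known subtypes")
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(sprintf("subtype(s) with < 2 labeled tumors: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  out <- lapply(subtypes, function(s) {
    in_s <- names(labels)[labels == s]
    rest <- names(labels)[labels != s]
    de <- moderated_t_de(expression, in_s, rest, prior = prior,
                         tau = logfc_threshold)
    up <- de$gene_id[!is.na(de$p_adj) & de$p_adj < alpha &
                       de$logfc > logfc_threshold]
    down <- de$gene_id[!is.na(de$p_adj) & de$p_adj < alpha &
                         de$logfc < -logfc_threshold]
    usable <- length(up) + length(down) > 0
    if (!usable) {
      warn(sprintf("subtype %s: empty up and down sets; signature unusable", s))
    }
    inform(sprintf("subtype %s signature: %d up, %d down", s,
                   length(up), length(down)))
    list(subtype = s, up = up, down = down, usable = usable, de = de)
  })
  names(out) <- subtypes
  structure(out, class = "gene_signatures")
}

#' @export
print.gene_signatures <- function(x, ...) {
  cat("<gene_signatures>\n")
  for (s in names(x)) {
    cat(sprintf("  subtype %s: %d up / %d down%s\n", s, length(x[[s]]$up),
                length(x[[s]]$down), if (x[[s]]$usable) "" else " (unusable)"))
  }
  invisible(x)
}

#' Export signatures as a tidy table
#'
#' @param signatures a [derive_signatures()] result.
#' @return Tibble with columns `subtype`, `gene_id`, `direction`, `logfc`,
#'   `p_adj`.
#' @export
signatures_to_table <- function(signatures) {
  purrr::map_dfr(signatures, function(sg) {
    de <- sg$de
    dplyr::bind_rows(
      tibble::tibble(subtype = sg$subtype, gene_id = sg$up, direction = "up"),
      tibble::tibble(subtype = sg$subtype, gene_id = sg$down, direction = "down")
    ) |>
      dplyr::left_join(de[, c("gene_id", "logfc", "p_adj")], by = "gene_id")
  })
}
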