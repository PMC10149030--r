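#' Summarize promoter methylation per gene
#'
#' Collapses probe-level beta-values onto genes through the promoter map.
#'
#' @param methylation probes x samples matrix of beta-values.
#' @param promoter_map tibble with `probe_id`, `gene_id`.
#' @param method `"mean"` (default) or `"max"` across a gene's promoter
#'   probes; missing probes are excluded pairwise, a gene with all probes
#'   missing in a sample gets `NA`.
#' @return genes x samples matrix of summarized beta-values.
#' @export
promoter_summary <- function(methylation, promoter_map, method = c("mean", "max")) {
  method <- match.arg(method)
  pm <- promoter_map[promoter_map$probe_id %in% rownames(methylation), ]
  if (nrow(pm) == 0) abort("no promoter probes present in the methylation matrix")
  genes <- unique(pm$gene_id)
  fun <- if (method == "mean") {
    function(m) colMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 2, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  }
  out <- t(vapply(genes, function(g) {
    probes <- pm$probe_id[pm$gene_id == g]
    v <- fun(methylation[probes, , drop = FALSE])
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(ncol(methylation))))
  dimnames(out) <- list(genes, colnames(methylation))
  out
}

# vectorized per-row Spearman between two aligned matrices (no missing data
# fast path; rows with NA fall back to pairwise-complete cor)
row_spearman <- function(x, y) {
  stopifnot(dim(x) == dim(y))
  rho <- rep(NA_real_, nrow(x))
  has_na <- rowSums(is.na(x) | is.na(y)) > 0
  if (any(!has_na)) {
    rx <- t(apply(x[!has_na, , drop = FALSE], 1, rank))
    ry <- t(apply(y[!has_na, , drop = FALSE], 1, rank))
    rx <- rx - rowMeans(rx); ry <- ry - rowMeans(ry)
    denom <- sqrt(rowSums(rx^2) * rowSums(ry^2))
    num <- rowSums(rx * ry)
    rho[!has_na] <- ifelse(denom == 0, NA_real_, num / denom)
  }
  for (i in which(has_na)) {
    rho[i] <- suppressWarnings(
      cor(x[i, ], y[i, ], method = "spearman", use = "pairwise.complete.obs"))
  }
  rho
}

#' Screen genes for expression-methylation anticorrelation
#'
#' For every gene, computes the Spearman correlation between summarized
#' promoter beta and logTPM across tumors (p-value via the t approximation
#' on n - 2 df, BH-adjusted across genes) plus a one-sided Mann-Whitney
#' test that expression is higher in normals than tumors.  A gene is a
#' silencing candidate when \eqn{\rho \le} `rho_max`, its BH-adjusted
#' correlation p is below `alpha`, and the normal-higher p is below
#' `alpha`.  Candidates are ranked by ascending rho.
#'
#' @param expression genes x samples matrix.
#' @param beta_summary genes x samples matrix from [promoter_summary()].
#' @param annotation sample annotation tibble (`sample_id`, `tissue`).
#' @param rho_max maximum (most permissive) Spearman correlation for a
#'   candidate; default -0.3.
#' @param alpha significance cutoff for both tests; default 0.05.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble of class `silencing_screen`, one row per evaluable gene:
#'   `gene_id`, `rho`, `p`, `p_adj`, `normal_higher_p`, `median_diff`
#'   (normal - tumor median logTPM), `candidate`; sorted by `rho`.  Genes
#'   with undefined correlation (constant values) are excluded and listed
#'   in the `excluded` attribute.
#' @export
anticorrelation_screen <- function(expression, beta_summary, annotation,
                                   rho_max = -0.3, alpha = 0.05,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  tumors <- annotation$sample_id[annotation$tissue == "tumor"]
  normals <- annotation$sample_id[annotation$tissue == "normal"]
  tumors <- intersect(tumors, colnames(expression))
  normals <- intersect(normals, colnames(expression))
  if (length(tumors) < 10) abort("need >= 10 tumors for the screen")
  if (length(normals) < 3) abort("need >= 3 normal samples for the normal-higher test")
  genes <- intersect(rownames(expression), rownames(beta_summary))
  e <- expression[genes, tumors, drop = FALSE]
  b <- beta_summary[genes, tumors, drop = FALSE]

  rho <- if (method == "spearman") row_spearman(b, e) else {
    bs <- b - rowMeans(b, na.rm = TRUE); es <- e - rowMeans(e, na.rm = TRUE)
    rowSums(bs * es, na.rm = TRUE) /
      sqrt(rowSums(bs^2, na.rm = TRUE) * rowSums(es^2, na.rm = TRUE))
  }
  n <- rowSums(!(is.na(b) | is.na(e)))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)

  en <- expression[genes, normals, drop = FALSE]
  nh <- apply(cbind(en, e), 1, function(x) {
    xn <- x[seq_along(normals)]; xt <- x[-seq_along(normals)]
    suppressWarnings(
      wilcox.test(xn, xt, alternative = "greater", exact = FALSE)$p.value)
  })
  med_diff <- apply(en, 1, median, na.rm = TRUE) - apply(e, 1, median, na.rm = TRUE)

  out <- tibble::tibble(
    gene_id = genes, rho = rho, p = p,
    normal_higher_p = unname(nh), median_diff = unname(med_diff)
  )
  excluded <- out$gene_id[is.na(out$rho)]
  out <- out[!is.na(out$rho), ]
  out$p_adj <- bh_adjust(out$p)
  out$candidate <- out$rho <= rho_max & out$p_adj < alpha &
    out$normal_higher_p < alpha
  out <- dplyr::arrange(out, .data$rho)
  out <- out[, c("gene_id", "rho", "p", "p_adj", "normal_higher_p",
                 "median_diff", "candidate")]
  attr(out, "excluded") <- excluded
  attr(out, "params") <- list(rho_max = rho_max, alpha = alpha, method = method,
                              n_tumors = length(tumors), n_normals = length(normals))
  class(out) <- c("silencing_screen", class(out))
  out
}

#' Call per-patient promoter hypermethylation
#'
#' A tumor is called hypermethylated for a gene when a promoter probe's
#' beta-value strictly exceeds the maximum beta of that probe across all
#' normal samples.  Under the default `"any-probe"` rule any one exceeding
#' probe suffices; under `"summary"` the gene-level mean beta must exceed
#' the summarized normal maximum.
#'
#' @param methylation probes x samples beta matrix.
#' @param promoter_map tibble `probe_id`, `gene_id`.
#' @param normal_samples character vector of normal sample ids (>= 1 with
#'   measured probes).
#' @param tumor_samples tumor sample ids; defaults to all non-normal
#'   columns.
#' @param rule `"any-probe"` (default) or `"summary"`.
#' @return genes x tumors logical matrix (`NA` where no probe is
#'   measurable).
#' @export
call_hypermethylation <- function(methylation, promoter_map, normal_samples,
                                  tumor_samples = NULL,
                                  rule = c("any-probe", "summary")) {
  rule <- match.arg(rule)
  normal_samples <- intersect(normal_samples, colnames(methylation))
  if (length(normal_samples) == 0) abort("no normal samples present in the methylation matrix")
  tumor_samples <- tumor_samples %||% setdiff(colnames(methylation), normal_samples)

  if (rule == "any-probe") {
    norm_max <- apply(methylation[, normal_samples, drop = FALSE], 1, function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    })
    exceeds <- methylation[, tumor_samples, drop = FALSE] > norm_max
    pm <- promoter_map[promoter_map$probe_id %in% rownames(methylation), ]
    genes <- unique(pm$gene_id)
    out <- t(vapply(genes, function(g) {
      probes <- pm$probe_id[pm$gene_id == g]
      ex <- exceeds[probes, , drop = FALSE]
      apply(ex, 2, function(x) if (all(is.na(x))) NA else any(x, na.rm = TRUE))
    }, logical(length(tumor_samples))))
    dimnames(out) <- list(genes, tumor_samples)
  } else {
    summ <- promoter_summary(methylation, promoter_map)
    norm_max <- apply(summ[, normal_samples, drop = FALSE], 1, function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    })
    out <- summ[, tumor_samples, drop = FALSE] > norm_max
  }
  out
}

#' Combine hypermethylation and copy-number into targetability calls
#'
#' A (gene, tumor) pair is targetable — a sensible candidate for CRISPRa
#' reactivation — when the gene is hypermethylated in that tumor and shows
#' no copy-number loss (call >= 0).  Missing copy-number is treated as
#' no-loss and flagged.
#'
#' @param hypermethylated genes x tumors logical matrix from
#'   [call_hypermethylation()].
#' @param cnv genes x samples integer call matrix in \{-2..2\}.
#' @return A list of class `targetability` with logical matrices
#'   `hypermethylated`, `no_loss`, `targetable` (all genes x tumors) and
#'   `cnv_missing`.
#' @export
targetable_matrix <- function(hypermethylated, cnv) {
  genes <- intersect(rownames(hypermethylated), rownames(cnv))
  tumors <- intersect(colnames(hypermethylated), colnames(cnv))
  if (length(genes) == 0 || length(tumors) == 0) {
    abort("no shared genes/samples between hypermethylation calls and CNV")
  }
  hm <- hypermethylated[genes, tumors, drop = FALSE]
  cc <- cnv[genes, tumors, drop = FALSE]
  missing_cnv <- is.na(cc)
  no_loss <- missing_cnv | cc >= 0
  hm_f <- !is.na(hm) & hm
  structure(
    list(hypermethylated = hm_f, no_loss = no_loss,
         targetable = hm_f & no_loss, cnv_missing = missing_cnv),
    class = "targetability"
  )
}

#' @export
print.targetability <- function(x, ...) {
  cat(sprintf("<targetability> %d genes x %d tumors, %d targetable pairs\n",
              nrow(x$targetable), ncol(x$targetable), sum(x$targetable)))
  invisible(x)
}
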