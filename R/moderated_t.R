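#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment \eqn{\tilde p_{(i)} = \min_{j \ge i} p_{(j)} m / j}
#' capped at 1, returned in input order.  Thin validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Newton solve of trigamma(y) = x, the standard approach for inverting the
# (strictly decreasing, convex in 1/y) trigamma on (0, Inf).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate an empirical-Bayes variance prior
#'
#' Fits the scaled inverse chi-square prior
#' \eqn{s_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}} by matching moments of the log
#' sample variances: with
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}, the prior degrees of
#' freedom solve \eqn{\psi'(d_0/2) = \mathrm{var}(e_g) - \overline{\psi'(d_g/2)}}
#' (infinite when the right-hand side is non-positive, i.e. no excess
#' spread) and \eqn{s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}}.
#'
#' @param s_sq per-gene sample variances (length >= 50 after removing
#'   non-positive df entries).
#' @param df per-gene residual degrees of freedom (recycled).
#' @return A list of class `variance_prior` with elements `d0` (prior df,
#'   possibly `Inf`) and `s0_sq` (prior variance).
#' @export
estimate_prior <- function(s_sq, df) {
  df <- rep_len(df, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & df >= 1
  if (sum(ok) < 50) {
    abort("need >= 50 genes with positive variance and df >= 1; supply a fixed prior instead")
  }
  s_sq <- s_sq[ok]; df <- df[ok]
  e <- log(s_sq) - digamma(df / 2) + log(df / 2)
  rhs <- var(e) - mean(trigamma(df / 2))
  if (rhs <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("<variance_prior> d0 = %s, s0^2 = %.4g\n",
              format(x$d0, digits = 4), x$s0_sq))
  invisible(x)
}

#' Moderated two-sample t-test per gene
#'
#' For each gene, the log fold change is `mean(A) - mean(B)`, the pooled
#' variance \eqn{s_g^2} has \eqn{d_g = n_A + n_B - 2} degrees of freedom,
#' and the posterior variance shrinks it toward the prior:
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}.  The moderated
#' statistic \eqn{t = \mathrm{logFC} / (\tilde s \sqrt{1/n_A + 1/n_B})}
#' is referred to a t distribution on \eqn{d_0 + d_g} df (standard Normal
#' when \eqn{d_0 = \infty}).  With `d0 = 0` this is exactly the ordinary
#' pooled-variance t-test.
#'
#' @param expression genes x samples numeric matrix (log scale).
#' @param group_a,group_b sample id vectors (>= 2 each, disjoint).
#' @param prior a [estimate_prior()] result, or `NULL` to estimate it from
#'   the pooled per-gene variances of this contrast.
#' @param tau fold-change threshold for TREAT-style testing; `0` (default)
#'   tests against zero.  When `tau > 0`, `p` is the threshold p-value of
#'   [treat_pvalue()].
#' @return A tibble of class `moderated_t_fit` with columns `gene_id`,
#'   `logfc`, `t`, `df_residual`, `df_total`, `se`, `p`, `p_adj` (BH) and a
#'   `degenerate` flag for genes with zero pooled variance under a `d0 = 0`
#'   prior.
#' @export
moderated_t_de <- function(expression, group_a, group_b, prior = NULL, tau = 0) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("both groups need >= 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(expression))
  if (length(missing) > 0) {
    abort(sprintf("samples not in expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  a <- expression[, group_a, drop = FALSE]
  b <- expression[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  logfc <- rowMeans(a) - rowMeans(b)
  d_g <- na + nb - 2
  ss_a <- rowSums((a - rowMeans(a))^2)
  ss_b <- rowSums((b - rowMeans(b))^2)
  s_sq <- (ss_a + ss_b) / d_g

  if (is.null(prior)) prior <- estimate_prior(s_sq, d_g)
  d0 <- prior$d0; s0_sq <- prior$s0_sq

  if (is.infinite(d0)) {
    post_var <- rep(s0_sq, length(s_sq))
    df_total <- rep(Inf, length(s_sq))
  } else {
    post_var <- (d0 * s0_sq + d_g * s_sq) / (d0 + d_g)
    df_total <- rep(d0 + d_g, length(s_sq))
  }
  se <- sqrt(post_var * (1 / na + 1 / nb))
  degenerate <- post_var == 0
  tstat <- ifelse(degenerate, NA_real_, logfc / se)
  p <- if (tau > 0) {
    treat_pvalue(logfc, se, df_total, tau)
  } else {
    2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
  }
  p[degenerate] <- NA_real_
  out <- tibble::tibble(
    gene_id = rownames(expression) %||% as.character(seq_along(logfc)),
    logfc = unname(logfc), t = unname(tstat), df_residual = d_g,
    df_total = df_total, se = unname(se), p = unname(p),
    p_adj = bh_adjust(unname(p)), degenerate = unname(degenerate)
  )
  attr(out, "prior") <- prior
  class(out) <- c("moderated_t_fit", class(out))
  out
}

#' Fold-change threshold (TREAT-style) p-value
#'
#' Tests whether \eqn{|\mathrm{logFC}|} exceeds the threshold `tau` rather
#' than zero:
#' \deqn{p = P(T_{df} \ge (|logFC| - \tau)/se) + P(T_{df} \ge (|logFC| + \tau)/se)}
#' clipped to (0, 1\].  With `tau = 0` this reduces to the ordinary
#' two-sided t p-value; at \eqn{|logFC| = \tau} it approaches 0.5 from
#' above.
#'
#' @param logfc observed log fold changes.
#' @param se standard errors (> 0).
#' @param df_total t degrees of freedom (`Inf` for Normal).
#' @param tau non-negative threshold, same units as `logfc`.
#' @return p-values, same length as `logfc`.
#' @export
treat_pvalue <- function(logfc, se, df_total, tau) {
  if (any(se <= 0, na.rm = TRUE)) abort("`se` must be positive")
  if (tau < 0) abort("`tau` must be non-negative")
  p <- pt((abs(logfc) - tau) / se, df = df_total, lower.tail = FALSE) +
    pt((abs(logfc) + tau) / se, df = df_total, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}
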