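#' Relative quantification by the delta-delta-Ct method
#'
#' Per replicate, \eqn{\Delta Ct = Ct_{target} - \overline{Ct}_{HK}} where
#' the housekeeping reference is the arithmetic mean of the reference-gene
#' Cts (equivalently the geometric mean of their abundances).  For each
#' condition, \eqn{\Delta\Delta Ct = \overline{\Delta Ct}(condition) -
#' \overline{\Delta Ct}(control)} and the fold change is
#' \eqn{2^{-\Delta\Delta Ct}}.  Replicate-level folds
#' \eqn{2^{-(\Delta Ct_{rep} - \overline{\Delta Ct}(control))}} are
#' returned for downstream testing.  Replicates missing a housekeeping
#' measurement are dropped with a warning; a condition whose target wells
#' are all at the 40-cycle cap is censored and its fold reported as an
#' upper bound with `censored = TRUE`.
#'
#' @param ct_table long-format tibble with columns `condition`, `target`,
#'   `replicate`, `ct` and optionally `undetected` (defaults to
#'   `ct >= 40`).
#' @param housekeeping character vector of reference gene names present in
#'   `target`.
#' @param control name of the control condition.
#' @return Tibble of class `ddct_result`, one row per (target, condition):
#'   `target`, `condition`, `ddct`, `fold`, `n_reps`, `censored`, and a
#'   `rep_folds` list-column of replicate-level fold changes.
#' @export
delta_delta_ct <- function(ct_table, housekeeping, control = "control") {
  ct <- tibble::as_tibble(ct_table)
  required <- c("condition", "target", "replicate", "ct")
  if (!all(required %in% names(ct))) {
    abort(sprintf("ct_table needs columns: %s", paste(required, collapse = ", ")))
  }
  if (!"undetected" %in% names(ct)) ct$undetected <- ct$ct >= 40
  if (!control %in% ct$condition) abort(sprintf("control condition '%s' absent", control))
  targets <- setdiff(unique(ct$target), housekeeping)
  if (length(targets) == 0) abort("no non-housekeeping targets in ct_table")
  if (!any(ct$target %in% housekeeping)) abort("no housekeeping wells in ct_table")

  hk <- ct |>
    dplyr::filter(.data$target %in% housekeeping) |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(hk_ct = mean(.data$ct), n_hk = dplyr::n(), .groups = "drop")

  dct <- ct |>
    dplyr::filter(.data$target %in% targets) |>
    dplyr::left_join(hk, by = c("condition", "replicate"))
  dropped <- is.na(dct$hk_ct)
  if (any(dropped)) {
    warn(sprintf("%d replicate well(s) without housekeeping measurements dropped",
                 sum(dropped)))
    dct <- dct[!dropped, ]
  }
  dct$dct <- dct$ct - dct$hk_ct

  ctrl <- dct |>
    dplyr::filter(.data$condition == control) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(ctrl_dct = mean(.data$dct), .groups = "drop")

  out <- dct |>
    dplyr::group_by(.data$target, .data$condition) |>
    dplyr::summarise(
      mean_dct = mean(.data$dct),
      n_reps = dplyr::n(),
      censored = all(.data$undetected),
      rep_dct = list(.data$dct),
      .groups = "drop"
    ) |>
    dplyr::left_join(ctrl, by = "target") |>
    dplyr::mutate(
      ddct = .data$mean_dct - .data$ctrl_dct,
      fold = 2^(-.data$ddct),
      rep_folds = purrr::map2(.data$rep_dct, .data$ctrl_dct,
                              function(d, c0) 2^(-(d - c0)))
    ) |>
    dplyr::select("target", "condition", "ddct", "fold", "n_reps",
                  "censored", "rep_folds")
  if (any(out$censored)) {
    warn("condition(s) with all wells undetected: fold is a censored bound")
  }
  class(out) <- c("ddct_result", class(out))
  out
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Adaptive linear step-up control of the false discovery rate at level
#' `q`.  Stage 1 runs Benjamini-Hochberg at \eqn{q' = q/(1+q)}, yielding
#' \eqn{r_1} rejections that estimate the number of true nulls as
#' \eqn{m - r_1}.  If \eqn{r_1 = 0} nothing is rejected; if \eqn{r_1 = m}
#' everything is.  Otherwise stage 2 reruns the step-up at
#' \eqn{q^* = q' m/(m - r_1)}.  Stage-2 rejections always contain the
#' stage-1 set.
#'
#' @param p p-values in \[0, 1\].
#' @param q target FDR level in (0, 1); default 0.05.
#' @return Logical rejection flags in input order.
#' @export
bky_two_stage <- function(p, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("`q` must be a single value in (0, 1)")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  q1 <- q / (1 + q)
  step_up <- function(p, level) {
    ord <- order(p)
    ps <- p[ord]
    below <- which(ps <= level * seq_len(m) / m)
    r <- if (length(below) == 0) 0L else max(below)
    rej <- logical(m)
    if (r > 0) rej[ord[seq_len(r)]] <- TRUE
    rej
  }
  stage1 <- step_up(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(p, q1 * m / (m - r1))
}
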