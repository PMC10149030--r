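#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a moderated-t fit
#'
#' @param x a `moderated_t_fit` from [moderated_t_de()].
#' @param ... unused.
#' @return The per-gene results as a plain tibble.
#' @export
tidy.moderated_t_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "moderated_t_fit")
  attr(out, "prior") <- NULL
  out
}

#' @rdname tidy.moderated_t_fit
#' @export
glance.moderated_t_fit <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$p_adj < 0.05, na.rm = TRUE),
    d0 = prior$d0,
    s0_sq = prior$s0_sq,
    df_residual = x$df_residual[1]
  )
}

#' Tidy a silencing screen
#'
#' @param x a `silencing_screen` from [anticorrelation_screen()].
#' @param ... unused.
#' @return The per-gene screen table as a plain tibble.
#' @export
tidy.silencing_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "silencing_screen")
  attr(out, "excluded") <- attr(out, "params") <- NULL
  out
}

#' @rdname tidy.silencing_screen
#' @export
glance.silencing_screen <- function(x, ...) {
  params <- attr(x, "params")
  tibble::tibble(
    n_genes = nrow(x),
    n_candidates = sum(x$candidate),
    n_excluded = length(attr(x, "excluded")),
    n_tumors = params$n_tumors,
    n_normals = params$n_normals,
    rho_max = params$rho_max,
    alpha = params$alpha
  )
}

#' Tidy a greedy panel selection
#'
#' @param x a `greedy_panel` from [greedy_panel()].
#' @param ... unused.
#' @return The coverage trajectory tibble, one row per added gene.
#' @export
tidy.greedy_panel <- function(x, ...) x$trajectory

#' @rdname tidy.greedy_panel
#' @export
glance.greedy_panel <- function(x, ...) {
  tibble::tibble(
    panel_size = length(x$panel),
    final_coverage_pct = max(x$trajectory$coverage_pct),
    final_min_group_pct = x$trajectory$min_group_pct[nrow(x$trajectory)]
  )
}

#' Tidy a delta-delta-Ct result
#'
#' @param x a `ddct_result` from [delta_delta_ct()].
#' @param ... unused.
#' @return The per-(target, condition) tibble without the list-column.
#' @export
tidy.ddct_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ddct_result")
  dplyr::select(out, -"rep_folds")
}
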