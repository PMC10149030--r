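#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline labs theme_minimal scale_color_manual
#' @export
ggplot2::autoplot

#' Plot a silencing screen as rho vs significance
#'
#' Each point is a gene; the x axis is the Spearman correlation between
#' promoter methylation and expression across tumors, the y axis
#' \eqn{-\log_{10}} of the BH-adjusted p-value.  Candidate genes are
#' highlighted.
#'
#' @param object a `silencing_screen` from [anticorrelation_screen()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.silencing_screen <- function(object, ...) {
  params <- attr(object, "params")
  df <- tidy(object)
  ggplot(df, aes(x = .data$rho, y = -log10(.data$p_adj),
                 color = .data$candidate)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_vline(xintercept = params$rho_max, linetype = "dashed") +
    geom_hline(yintercept = -log10(params$alpha), linetype = "dashed") +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "Spearman rho (promoter beta vs logTPM)",
         y = expression(-log[10] ~ "adjusted p"),
         color = "candidate") +
    theme_minimal()
}

#' Plot a greedy panel coverage trajectory
#'
#' @param object a `greedy_panel` from [greedy_panel()].
#' @param ... unused.
#' @return A ggplot object: overall and worst-group patient coverage after
#'   each gene addition.
#' @export
autoplot.greedy_panel <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trajectory,
                            c("coverage_pct", "min_group_pct"),
                            names_to = "metric", values_to = "pct")
  ggplot(df, aes(x = .data$step, y = .data$pct, color = .data$metric)) +
    geom_line() +
    geom_point() +
    labs(x = "panel size", y = "patients covered (%)", color = NULL) +
    theme_minimal()
}

#' Plot signature scores of tumors
#'
#' @param scores tibble from [score_matrix()].
#' @param assignments optional tibble from [knn_assign()]; colors points by
#'   assigned subtype.
#' @param dims two score column names to plot; defaults to the first two.
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, assignments = NULL, dims = NULL) {
  score_cols <- grep("^score_", names(scores), value = TRUE)
  if (length(score_cols) < 2) abort("need at least two score_* columns")
  dims <- dims %||% score_cols[1:2]
  df <- scores
  if (!is.null(assignments)) {
    df <- dplyr::left_join(df, assignments[, c("sample_id", "assigned")],
                           by = "sample_id")
  } else {
    df$assigned <- "unassigned"
  }
  ggplot(df, aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                 color = .data$assigned)) +
    geom_point(alpha = 0.7) +
    labs(color = "subtype") +
    theme_minimal()
}
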