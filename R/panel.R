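#' Patient coverage of a gene panel
#'
#' Coverage of a panel within a group of tumors is the percentage of tumors
#' with at least one targetable panel gene.  Reported per group (e.g.
#' molecular subtype) and overall, together with each panel gene's marginal
#' single-gene coverage.
#'
#' @param targetability a [targetable_matrix()] result, or a genes x tumors
#'   logical matrix of targetable calls.
#' @param groups named character vector: group label per tumor sample id;
#'   defaults to a single `"all"` group.  Groups must partition the tumors.
#' @param panel character vector of panel genes (subset of the gene set).
#' @return A list of class `panel_coverage`: `panel`, `coverage` (tibble
#'   `group`, `n`, `covered`, `coverage_pct`; the `"overall"` row last;
#'   empty groups get `NA` coverage), and `per_gene` (tibble `gene_id`,
#'   `coverage_pct` overall).
#' @export
panel_coverage <- function(targetability, groups = NULL, panel) {
  tgt <- if (inherits(targetability, "targetability")) targetability$targetable else targetability
  stopifnot(is.matrix(tgt))
  extra <- setdiff(panel, rownames(tgt))
  if (length(extra) > 0) {
    abort(sprintf("panel gene(s) not in the targetability matrix: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  tumors <- colnames(tgt)
  groups <- groups %||% setNames(rep("all", length(tumors)), tumors)
  groups <- groups[tumors]

  covered <- if (length(panel) == 0) {
    rep(FALSE, length(tumors))
  } else {
    colSums(tgt[panel, , drop = FALSE], na.rm = TRUE) > 0
  }
  cov_pct <- function(idx) {
    if (length(idx) == 0) return(c(n = 0, covered = 0, coverage_pct = NA_real_))
    c(n = length(idx), covered = sum(covered[idx]),
      coverage_pct = 100 * sum(covered[idx]) / length(idx))
  }
  levels <- sort(unique(groups))
  rows <- lapply(levels, function(g) cov_pct(which(groups == g)))
  rows <- c(rows, list(cov_pct(seq_along(tumors))))
  coverage <- dplyr::bind_cols(
    tibble::tibble(group = c(levels, "overall")),
    tibble::as_tibble(do.call(rbind, rows))
  )
  per_gene <- tibble::tibble(
    gene_id = panel,
    coverage_pct = if (length(panel) == 0) numeric(0) else {
      100 * rowSums(tgt[panel, , drop = FALSE], na.rm = TRUE) / length(tumors)
    }
  )
  structure(list(panel = panel, coverage = coverage, per_gene = per_gene),
            class = "panel_coverage")
}

#' @export
print.panel_coverage <- function(x, ...) {
  cat(sprintf("<panel_coverage> panel of %d gene(s)\n", length(x$panel)))
  print(x$coverage)
  invisible(x)
}

#' Greedy set-cover selection of a patient-covering gene panel
#'
#' Builds a panel by repeatedly adding the gene with the greatest marginal
#' overall coverage; ties are broken by the higher minimum per-group
#' coverage of the resulting panel, then lexicographically by gene id.
#' Stops at `max_size` genes or full coverage.  Greedy set cover is
#' guaranteed to reach at least \eqn{1 - 1/e} of the optimal coverage for
#' any panel size.
#'
#' @inheritParams panel_coverage
#' @param max_size maximum panel size (>= 1).
#' @return A list of class `greedy_panel`: `panel` (ordered genes) and
#'   `trajectory`, a tibble with one row per addition (`step`, `gene_id`,
#'   `coverage_pct` overall after the addition, `min_group_pct`).
#' @export
greedy_panel <- function(targetability, groups = NULL, max_size) {
  assert_count(max_size, "max_size", 1)
  tgt <- if (inherits(targetability, "targetability")) targetability$targetable else targetability
  tumors <- colnames(tgt)
  groups <- (groups %||% setNames(rep("all", length(tumors)), tumors))[tumors]
  levels <- sort(unique(groups))

  panel <- character(0)
  covered <- rep(FALSE, length(tumors))
  traj <- list()
  candidates <- sort(rownames(tgt))
  for (step in seq_len(max_size)) {
    gain <- vapply(candidates, function(g) sum(tgt[g, ] & !covered, na.rm = TRUE),
                   numeric(1))
    best_gain <- max(gain)
    if (best_gain == 0 && step > 1) break
    tied <- candidates[gain == best_gain]
    if (length(tied) > 1) {
      min_group <- vapply(tied, function(g) {
        cov_g <- covered | tgt[g, ]
        min(vapply(levels, function(l) {
          idx <- groups == l
          if (!any(idx)) NA_real_ else mean(cov_g[idx])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      tied <- tied[min_group == max(min_group)]
    }
    pick <- sort(tied)[1]
    panel <- c(panel, pick)
    covered <- covered | (tgt[pick, ] & !is.na(tgt[pick, ]))
    candidates <- setdiff(candidates, pick)
    min_group_pct <- min(vapply(levels, function(l) {
      idx <- groups == l
      if (!any(idx)) NA_real_ else 100 * mean(covered[idx])
    }, numeric(1)), na.rm = TRUE)
    traj[[step]] <- tibble::tibble(
      step = step, gene_id = pick,
      coverage_pct = 100 * mean(covered),
      min_group_pct = min_group_pct
    )
    if (all(covered) || length(candidates) == 0) break
  }
  structure(list(panel = panel, trajectory = dplyr::bind_rows(traj)),
            class = "greedy_panel")
}

#' @export
print.greedy_panel <- function(x, ...) {
  cat(sprintf("<greedy_panel> %d gene(s), final coverage %.1f%%\n",
              length(x$panel), max(x$trajectory$coverage_pct)))
  print(x$trajectory)
  invisible(x)
}
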