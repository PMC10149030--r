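#' Pipeline configuration
#'
#' Flat, typed configuration for [run_pipeline()].  Unknown keys are an
#' error (fail-fast), and the realized configuration is serialized next to
#' the outputs so every artifact is re-derivable from config + seed alone.
#'
#' @param sim a [cohort_sim_config()] describing the synthetic cohort, or
#'   `NULL` when `input_dir` points at cohort TSVs written by
#'   [write_cohort()].
#' @param input_dir directory with `expression.tsv`, `methylation.tsv`,
#'   `promoter_map.tsv`, `cnv.tsv`, `annotation.tsv`; ignored when `sim`
#'   is given.
#' @param logfc_threshold,sig_alpha signature derivation thresholds
#'   (log2 fold-change threshold, BH-adjusted alpha).  The default
#'   threshold 0.25 is matched to the synthetic cohort's planted subtype
#'   shift of 1 sd (a quarter of the effect, leaving a wide rejection margin
#'   for true markers); for real cohorts with large subtype separation the
#'   conventional 1.5 (the [derive_signatures()] default) is appropriate.
#' @param k_neighbors kNN neighborhood size for label transfer (default 30).
#' @param rho_max,screen_alpha anticorrelation screen thresholds.
#' @param hyper_rule `"any-probe"` or `"summary"` hypermethylation rule.
#' @param panel_max_size maximum greedy panel size.
#' @param seed integer seed for the simulated branch.
#' @param out_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = cohort_sim_config(), input_dir = NULL,
                            logfc_threshold = 0.25, sig_alpha = 0.05,
                            k_neighbors = 30, rho_max = -0.3,
                            screen_alpha = 0.05,
                            hyper_rule = c("any-probe", "summary"),
                            panel_max_size = 12, seed = 1L,
                            out_dir = tempfile("epitarget_run_")) {
  hyper_rule <- match.arg(hyper_rule)
  if (is.null(sim) && is.null(input_dir)) {
    abort("either `sim` or `input_dir` must be given")
  }
  structure(list(
    sim = sim, input_dir = input_dir,
    logfc_threshold = assert_number(logfc_threshold, "logfc_threshold", 0),
    sig_alpha = assert_number(sig_alpha, "sig_alpha", 0, 1),
    k_neighbors = assert_count(k_neighbors, "k_neighbors", 1),
    rho_max = assert_number(rho_max, "rho_max", -1, 1),
    screen_alpha = assert_number(screen_alpha, "screen_alpha", 0, 1),
    hyper_rule = hyper_rule,
    panel_max_size = assert_count(panel_max_size, "panel_max_size", 1),
    seed = assert_count(seed, "seed", 0),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full silencing-screen pipeline
#'
#' Simulates (or loads) a cohort, derives subtype signatures from labeled
#' tumors, transfers labels to unlabeled tumors by rank scoring + kNN,
#' screens for expression-methylation anticorrelation, computes per-patient
#' targetability, and selects a greedy patient-covering panel.  Writes all
#' stage outputs as TSV plus a machine-readable `summary.json`; known
#' labels are kept, inferred labels are reported separately (groups
#' `known_<s>` and `inferred_<s>`).  Reruns with the same config and seed
#' are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`bundle`, `validation`, `signatures`, `scores`, `assignments`,
#'   `screen`, `targetability`, `panel`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  cfg_out <- config[setdiff(names(config), "sim")]
  cfg_out$sim <- if (is.null(config$sim)) NULL else unclass(config$sim)
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  log_msg("seed %d", config$seed)

  # -- cohort ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim <- simulate_cohort(do.call(cohort_sim_config, unclass(sim_cfg)))
    bundle <- sim$bundle
    truth <- sim$truth
    log_msg("simulated cohort: %d genes, %d samples", nrow(bundle$expression),
            ncol(bundle$expression))
  } else {
    bundle <- read_cohort(
      file.path(config$input_dir, "expression.tsv"),
      file.path(config$input_dir, "methylation.tsv"),
      file.path(config$input_dir, "promoter_map.tsv"),
      file.path(config$input_dir, "cnv.tsv"),
      file.path(config$input_dir, "annotation.tsv")
    )
    log_msg("loaded cohort from %s", config$input_dir)
  }
  validation <- validate_cohort(bundle)
  readr::write_tsv(validation, file.path(config$out_dir, "validation.tsv"))
  if (!attr(validation, "pass")) {
    abort("stage 'validate': cohort failed validation; see validation.tsv")
  }

  ann <- bundle$annotation
  tumors <- ann$sample_id[ann$tissue == "tumor"]
  labeled <- ann$sample_id[ann$tissue == "tumor" & ann$subtype_label != "unknown"]
  unlabeled <- setdiff(tumors, labeled)
  labels <- setNames(ann$subtype_label[match(labeled, ann$sample_id)], labeled)

  # -- signatures -----------------------------------------------------------
  signatures <- derive_signatures(
    bundle$expression[, labeled, drop = FALSE], labels,
    logfc_threshold = config$logfc_threshold, alpha = config$sig_alpha
  )
  readr::write_tsv(signatures_to_table(signatures),
                   file.path(config$out_dir, "signatures.tsv"))
  log_msg("signatures derived for %d subtypes", length(signatures))

  # -- label transfer -------------------------------------------------------
  scores <- score_matrix(bundle$expression[, tumors, drop = FALSE], signatures)
  readr::write_tsv(scores, file.path(config$out_dir, "scores.tsv"))
  train_scores <- scores[scores$sample_id %in% labeled, ]
  assignments <- if (length(unlabeled) > 0) {
    knn_assign(train_scores, labels, scores[scores$sample_id %in% unlabeled, ],
               k = min(config$k_neighbors, nrow(train_scores)))
  } else {
    tibble::tibble(sample_id = character(0), assigned = character(0))
  }
  readr::write_tsv(assignments, file.path(config$out_dir, "assignments.tsv"))
  log_msg("transferred labels to %d unlabeled tumors", length(unlabeled))

  subtype_of <- c(labels, setNames(assignments$assigned, assignments$sample_id))
  origin <- c(setNames(rep("known", length(labels)), names(labels)),
              setNames(rep("inferred", nrow(assignments)), assignments$sample_id))

  # -- silencing screen -----------------------------------------------------
  beta_summary <- promoter_summary(bundle$methylation, bundle$promoter_map)
  screen <- anticorrelation_screen(bundle$expression, beta_summary, ann,
                                   rho_max = config$rho_max,
                                   alpha = config$screen_alpha)
  readr::write_tsv(tibble::as_tibble(screen),
                   file.path(config$out_dir, "candidates.tsv"))
  candidates <- screen$gene_id[screen$candidate]
  log_msg("screen: %d candidate gene(s)", length(candidates))

  # -- targetability + panel ------------------------------------------------
  normals <- ann$sample_id[ann$tissue == "normal"]
  hyper <- call_hypermethylation(bundle$methylation, bundle$promoter_map,
                                 normals, tumors, rule = config$hyper_rule)
  tgt <- targetable_matrix(hyper, bundle$cnv)
  cand_present <- intersect(candidates, rownames(tgt$targetable))
  tgt_cand <- tgt
  tgt_cand$targetable <- tgt$targetable[cand_present, , drop = FALSE]
  readr::write_tsv(
    matrix_to_tibble(tgt_cand$targetable * 1L, "gene_id"),
    file.path(config$out_dir, "targetability.tsv")
  )

  groups <- setNames(paste0(origin[tumors], "_", subtype_of[tumors]), tumors)
  panel <- NULL
  coverage <- NULL
  if (length(cand_present) > 0) {
    panel <- greedy_panel(tgt_cand$targetable, groups,
                          max_size = min(config$panel_max_size, length(cand_present)))
    coverage <- panel_coverage(tgt_cand$targetable, groups, panel$panel)
    readr::write_tsv(panel$trajectory, file.path(config$out_dir, "panel_trajectory.tsv"))
    readr::write_tsv(coverage$coverage, file.path(config$out_dir, "coverage.tsv"))
    log_msg("greedy panel of %d gene(s), overall coverage %.1f%%",
            length(panel$panel), max(panel$trajectory$coverage_pct))
  } else {
    log_msg("no candidates: panel stage skipped")
  }

  group_sizes <- as.list(table(groups))
  summary <- list(
    n_genes = nrow(bundle$expression),
    n_tumors = length(tumors),
    n_normals = length(normals),
    n_candidates = length(candidates),
    panel = if (is.null(panel)) character(0) else panel$panel,
    overall_coverage_pct = if (is.null(coverage)) NA else
      coverage$coverage$coverage_pct[coverage$coverage$group == "overall"],
    group_sizes = group_sizes,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)

  invisible(list(bundle = bundle, truth = truth, validation = validation,
                 signatures = signatures, scores = scores,
                 assignments = assignments, screen = screen,
                 targetability = tgt, panel = panel, coverage = coverage,
                 summary = summary, out_dir = config$out_dir))
}
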