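#' Configuration for the synthetic tumor cohort generator
#'
#' The defaults describe the cohort structure the analysis assumes: three
#' latent molecular subtypes separable in expression space, a small set of
#' genes silenced by promoter hypermethylation in a subset of patients, and
#' matched adjacent-normal samples with low promoter methylation and
#' unshifted expression.
#'
#' @param n_per_subtype tumors per subtype (3 subtypes).
#' @param n_normals matched normal samples (each paired with a tumor).
#' @param n_genes total genes.
#' @param n_signature_genes up-regulated marker genes per subtype.
#' @param effect_size expression shift (sd units of logTPM noise) applied to
#'   a subtype's signature genes in that subtype's tumors.
#' @param n_silenced planted epigenetically silenced genes (disjoint from
#'   signature genes).
#' @param silenced_fraction fraction of tumors hypermethylated per silenced
#'   gene, in (0, 1\].
#' @param anticor_strength target magnitude of the cohort-wide Spearman
#'   anticorrelation between promoter beta and logTPM for silenced genes;
#'   the generator aims above this and the realized value is required to be
#'   \eqn{\le -(strength - 0.1)}.
#' @param beta_noise sd of probe-level noise on the logit-beta scale.
#' @param cnv_loss_prob marginal probability of a loss call (-1 or -2);
#'   gains get a fixed 0.15 mass, the rest is neutral.
#' @param labeled_fraction fraction of tumors carrying a known subtype label.
#' @param seed integer random seed; identical seeds give bit-identical
#'   cohorts.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_per_subtype = 100, n_normals = 50,
                              n_genes = 2000, n_signature_genes = 200,
                              effect_size = 1.0, n_silenced = 12,
                              silenced_fraction = 0.5, anticor_strength = 0.8,
                              beta_noise = 0.5, cnv_loss_prob = 0.2,
                              labeled_fraction = 0.6, seed = 1L) {
  cfg <- list(
    n_per_subtype = assert_count(n_per_subtype, "n_per_subtype", 2),
    n_normals = assert_count(n_normals, "n_normals", 0),
    n_genes = assert_count(n_genes, "n_genes", 10),
    n_signature_genes = assert_count(n_signature_genes, "n_signature_genes", 1),
    effect_size = assert_number(effect_size, "effect_size", 0),
    n_silenced = assert_count(n_silenced, "n_silenced", 0),
    silenced_fraction = assert_number(silenced_fraction, "silenced_fraction", 1e-9, 1),
    anticor_strength = assert_number(anticor_strength, "anticor_strength", 0, 0.99),
    beta_noise = assert_number(beta_noise, "beta_noise", 0),
    cnv_loss_prob = assert_number(cnv_loss_prob, "cnv_loss_prob", 0, 0.8),
    labeled_fraction = assert_number(labeled_fraction, "labeled_fraction", 0, 1),
    seed = assert_count(seed, "seed", 0)
  )
  if (cfg$n_silenced + 3 * cfg$n_signature_genes > cfg$n_genes) {
    abort("infeasible config: silenced + signature genes exceed n_genes")
  }
  if (cfg$n_normals > 3 * cfg$n_per_subtype) {
    abort("infeasible config: more matched normals than tumors")
  }
  structure(cfg, class = c("cohort_sim_config", "list"))
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate a multi-omic tumor cohort with ground truth
#'
#' Expression is baseline Normal(mu_g, 1) logTPM with a `+effect_size` shift
#' on each subtype's signature genes in that subtype's tumors.  Each planted
#' silenced gene picks a `silenced_fraction` of tumors whose promoter
#' beta-values are drawn high (logit-normal around logit(0.7)) while their
#' expression is shifted down through a shared latent severity, so the
#' cohort-wide Spearman correlation between promoter beta and logTPM is
#' strongly negative.  Matched normals draw beta around logit(0.2) and keep
#' unshifted expression.  Every gene carries two promoter probes; copy-number
#' calls are iid categorical over \{-2..2\}.
#'
#' @param config a [cohort_sim_config()].
#' @return A list with elements `bundle` (a [cohort_bundle()]) and `truth`,
#'   a list holding `subtype` (named vector over tumors), `silenced_genes`,
#'   `silenced_patients` (named list of tumor ids per silenced gene),
#'   `signature_genes` (named list of up-gene sets per subtype) and
#'   `realized_rho` (named vector of cohort Spearman correlations for the
#'   silenced genes).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  cfg <- config

  n_tum <- 3L * cfg$n_per_subtype
  tumor_ids <- sprintf("T%03d", seq_len(n_tum))
  normal_ids <- sprintf("N%03d", seq_len(cfg$n_normals))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  subtype <- rep(c("1", "2", "3"), each = cfg$n_per_subtype)
  names(subtype) <- tumor_ids
  matched_tumor <- tumor_ids[seq_len(cfg$n_normals)]

  sig_genes <- split(gene_ids[seq_len(3 * cfg$n_signature_genes)],
                     rep(c("1", "2", "3"), each = cfg$n_signature_genes))
  silenced <- gene_ids[3 * cfg$n_signature_genes + seq_len(cfg$n_silenced)]

  # baselines shared between a tumor and its matched normal
  mu_g <- rnorm(cfg$n_genes, mean = 5, sd = 1.5)
  names(mu_g) <- gene_ids
  pair_offset <- rnorm(n_tum, sd = 0.3)
  names(pair_offset) <- tumor_ids

  all_ids <- c(tumor_ids, normal_ids)
  expr <- matrix(rnorm(cfg$n_genes * length(all_ids)), cfg$n_genes,
                 dimnames = list(gene_ids, all_ids))
  expr <- expr + mu_g
  expr <- sweep(expr, 2, c(pair_offset, pair_offset[matched_tumor]), `+`)
  for (s in c("1", "2", "3")) {
    expr[sig_genes[[s]], tumor_ids[subtype == s]] <-
      expr[sig_genes[[s]], tumor_ids[subtype == s]] + cfg$effect_size
  }

  # latent severity drives both hypermethylation and silencing; the
  # coefficient is solved so the latent/expression correlation exceeds the
  # target strength, leaving ~0.1 headroom for beta noise and rank tie loss
  silenced_patients <- list()
  severity <- matrix(0, length(silenced), n_tum,
                     dimnames = list(silenced, tumor_ids))
  f <- cfg$silenced_fraction
  target_r <- min(0.97, cfg$anticor_strength + 0.08)
  for (g in silenced) {
    hit <- sort(sample(tumor_ids, max(1L, round(f * n_tum))))
    silenced_patients[[g]] <- hit
    sv <- rnorm(n_tum, mean = 0, sd = 0.6)
    sv[tumor_ids %in% hit] <- sv[tumor_ids %in% hit] + 2
    severity[g, ] <- sv
    if (cfg$anticor_strength > 0) {
      v <- var(sv)
      coef <- target_r / sqrt(v * (1 - target_r^2))
      # downshift only (silenced tumors drop below the shared baseline, the
      # rest stay near it) so normals remain the higher-expressing group
      expr[g, tumor_ids] <- mu_g[g] + pair_offset +
        rnorm(n_tum) - coef * pmax(sv, 0)
    }
  }

  # two promoter probes per gene on the logit-beta scale
  probe_ids <- paste0(rep(gene_ids, each = 2), c("_p1", "_p2"))
  base_logit <- logit(0.2)
  high_logit <- logit(0.7)
  lat <- matrix(base_logit, cfg$n_genes, length(all_ids),
                dimnames = list(gene_ids, all_ids))
  # severity ~0 for unsilenced, ~2 for silenced tumors, maps linearly onto
  # the logit(0.2)..logit(0.7) span
  lat[silenced, tumor_ids] <- base_logit +
    severity * (high_logit - base_logit) / 2
  meth <- matrix(NA_real_, length(probe_ids), length(all_ids),
                 dimnames = list(probe_ids, all_ids))
  meth[seq(1, by = 2, length.out = cfg$n_genes), ] <-
    lat + rnorm(length(lat), sd = cfg$beta_noise)
  meth[seq(2, by = 2, length.out = cfg$n_genes), ] <-
    lat + rnorm(length(lat), sd = cfg$beta_noise)
  meth <- inv_logit(meth)

  promoter_map <- tibble::tibble(
    probe_id = probe_ids,
    gene_id = rep(gene_ids, each = 2),
    tss_distance = rep(c(-200L, 150L), cfg$n_genes)
  )

  p_loss <- cfg$cnv_loss_prob
  probs <- c(p_loss / 3, 2 * p_loss / 3, 1 - p_loss - 0.15, 0.10, 0.05)
  cnv <- matrix(sample(-2:2, cfg$n_genes * length(all_ids), replace = TRUE, prob = probs),
                cfg$n_genes, dimnames = list(gene_ids, all_ids))

  n_labeled <- round(cfg$labeled_fraction * n_tum)
  labeled <- sample(tumor_ids, n_labeled)
  ann <- tibble::tibble(
    sample_id = all_ids,
    tissue = c(rep("tumor", n_tum), rep("normal", cfg$n_normals)),
    matched_pair_id = c(rep(NA_character_, n_tum), matched_tumor),
    subtype_label = c(ifelse(tumor_ids %in% labeled, subtype, "unknown"),
                      rep("unknown", cfg$n_normals))
  )

  bundle <- suppressMessages(suppressWarnings(
    cohort_bundle(expr, meth, promoter_map, cnv, ann)
  ))

  realized_rho <- vapply(silenced, function(g) {
    b <- colMeans(meth[paste0(g, c("_p1", "_p2")), tumor_ids])
    cor(b, expr[g, tumor_ids], method = "spearman")
  }, numeric(1))
  if (cfg$anticor_strength > 0 &&
      any(realized_rho > -(cfg$anticor_strength - 0.1))) {
    warn(sprintf("planted anticorrelation weaker than target for: %s",
                 paste(silenced[realized_rho > -(cfg$anticor_strength - 0.1)],
                       collapse = ", ")))
  }

  truth <- list(
    subtype = subtype,
    silenced_genes = silenced,
    silenced_patients = silenced_patients,
    signature_genes = sig_genes,
    realized_rho = realized_rho
  )
  list(bundle = bundle, truth = truth)
}
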