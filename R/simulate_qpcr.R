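#' Simulate a qPCR plate for relative quantification
#'
#' Draws per-target control Ct values, housekeeping Cts shared within each
#' replicate, and treated Cts shifted by \eqn{-\log_2(\mathrm{fold})} so
#' that the delta-delta-Ct method recovers `true_folds` exactly at zero
#' noise.  Ct values are capped at 40 cycles and flagged `undetected`.
#'
#' @param targets character vector of target gene names.
#' @param housekeeping character vector of reference gene names.
#' @param true_folds positive numeric vector (recycled over targets): true
#'   expression fold change of `"treated"` relative to `"control"`.
#' @param ct_noise_sd sd of Gaussian measurement noise on each well (cycles).
#' @param n_replicates replicates per condition (>= 2).
#' @param seed integer seed.
#' @return A list: `ct` — long-format tibble (`sample`, `condition`,
#'   `target`, `replicate`, `ct`, `undetected`) including housekeeping
#'   wells — and `truth`, a tibble of `target`, `true_fold`.
#' @export
simulate_qpcr <- function(targets, housekeeping = c("GAPDH", "GUSB", "PPIA"),
                          true_folds = 2, ct_noise_sd = 0.1,
                          n_replicates = 3, seed = 1L) {
  stopifnot(length(targets) >= 1, length(housekeeping) >= 1)
  if (any(true_folds <= 0)) abort("`true_folds` must be positive")
  assert_count(n_replicates, "n_replicates", 2)
  assert_number(ct_noise_sd, "ct_noise_sd", 0)
  set.seed(derive_seed(seed, "qpcr"))

  true_folds <- rep_len(true_folds, length(targets))
  conditions <- c("control", "treated")
  base_ct <- setNames(runif(length(targets), 24, 32), targets)
  hk_ct <- setNames(runif(length(housekeeping), 18, 22), housekeeping)

  rows <- tidyr::expand_grid(
    condition = conditions,
    gene = c(targets, housekeeping),
    replicate = seq_len(n_replicates)
  )
  ct <- purrr::pmap_dbl(rows, function(condition, gene, replicate) {
    mu <- if (gene %in% housekeeping) hk_ct[[gene]] else {
      base_ct[[gene]] -
        if (condition == "treated") log2(true_folds[match(gene, targets)]) else 0
    }
    mu + rnorm(1, sd = ct_noise_sd)
  })
  out <- tibble::tibble(
    sample = paste0(rows$condition, "_r", rows$replicate),
    condition = rows$condition,
    target = rows$gene,
    replicate = rows$replicate,
    ct = pmin(ct, 40),
    undetected = ct >= 40
  )
  list(ct = out, truth = tibble::tibble(target = targets, true_fold = true_folds))
}
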