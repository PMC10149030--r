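# Small in-code fixtures shared across tests.

tiny_bundle <- function(seed = 42) {
  suppressMessages(suppressWarnings(
    simulate_cohort(cohort_sim_config(
      n_per_subtype = 10, n_normals = 6, n_genes = 120,
      n_signature_genes = 10, n_silenced = 4, seed = seed
    ))
  ))
}

# independent brute-force re-implementation of the rank score, written from
# the definition: normalized mean-rank displacement, summed over directions
oracle_rank_score <- function(expr, up, down = NULL) {
  n <- length(expr)
  r <- rank(expr, ties.method = "average")
  comp <- function(set, rr) {
    m <- length(set)
    mean_rank <- mean(rr[match(set, names(expr))])
    (mean_rank - (m + 1) / 2) / (n - m) - 0.5
  }
  out <- comp(up, r)
  if (!is.null(down) && length(down) > 0) out <- out + comp(down, n + 1 - r)
  out
}

# naive per-position off-target scan: substring comparison at every offset
oracle_offtargets <- function(genome, protospacer, pam = "NGG", max_mismatches = 3) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                N = c("A", "C", "G", "T"), R = c("A", "G"), Y = c("C", "T"))
  pam_chars <- strsplit(pam, "")[[1]]
  guide <- strsplit(protospacer, "")[[1]]
  hits <- list()
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (contig in names(genome)) {
    fwd <- toupper(genome[[contig]])
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rc(fwd)
      schars <- strsplit(s, "")[[1]]
      for (p0 in 0:(L - 20 - length(pam_chars))) {
        site <- schars[(p0 + 1):(p0 + 20)]
        mm <- sum(site != guide)
        if (mm > max_mismatches) next
        pam_site <- schars[(p0 + 21):(p0 + 20 + length(pam_chars))]
        if (!all(mapply(function(b, code) b %in% iupac[[code]], pam_site, pam_chars))) next
        start <- if (strand == "+") p0 else L - (p0 + 20)
        hits[[length(hits) + 1]] <- data.frame(
          contig = contig, start = start, strand = strand, mismatches = mm)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# exhaustive panel coverage: loop over tumors, check each panel gene
oracle_coverage_pct <- function(tgt, panel) {
  if (ncol(tgt) == 0) return(NA_real_)
  covered <- 0
  for (j in seq_len(ncol(tgt))) {
    hit <- FALSE
    for (g in panel) if (isTRUE(tgt[g, j])) hit <- TRUE
    if (hit) covered <- covered + 1
  }
  100 * covered / ncol(tgt)
}

# best achievable coverage over all panels of size <= k (exhaustive search)
oracle_best_coverage <- function(tgt, k) {
  genes <- rownames(tgt)
  best <- 0
  for (size in seq_len(min(k, length(genes)))) {
    combos <- utils::combn(genes, size, simplify = FALSE)
    for (cc in combos) {
      best <- max(best, oracle_coverage_pct(tgt, cc))
    }
  }
  best
}
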