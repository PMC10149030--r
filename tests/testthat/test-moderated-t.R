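ordinary_t <- function(x, y) {
  # textbook pooled-variance two-sample t-test
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(abs(t), df = nx + ny - 2, lower.tail = FALSE))
}

test_that("d0 = 0 reduces the moderated test to the ordinary pooled t-test", {
  set.seed(21)
  m <- matrix(rnorm(40 * 9), 40, dimnames = list(sprintf("g%02d", 1:40),
                                                 sprintf("s%d", 1:9)))
  a <- sprintf("s%d", 1:4); b <- sprintf("s%d", 5:9)
  res <- moderated_t_de(m, a, b, prior = list(d0 = 0, s0_sq = 1))
  for (i in 1:40) {
    ref <- ordinary_t(m[i, a], m[i, b])
    expect_equal(res$t[i], ref$t, tolerance = 1e-12)
    expect_equal(res$p[i], ref$p, tolerance = 1e-12)
  }
})

test_that("equal group means give logFC 0, t 0, p 1 at any prior", {
  m <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  colnames(m) <- sprintf("s%d", 1:6)
  for (prior in list(list(d0 = 0, s0_sq = 1), list(d0 = 5, s0_sq = 0.2),
                     list(d0 = Inf, s0_sq = 0.5))) {
    res <- moderated_t_de(m, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                          prior = prior)
    expect_equal(res$logfc, 0)
    expect_equal(res$t, 0)
    expect_equal(res$p, 1)
  }
})

test_that("moderated t interpolates between ordinary t and fixed-variance z", {
  set.seed(22)
  m <- matrix(rnorm(20 * 12), 20, dimnames = list(sprintf("g%02d", 1:20),
                                                  sprintf("s%d", 1:12)))
  a <- sprintf("s%d", 1:6); b <- sprintf("s%d", 7:12)
  near0 <- moderated_t_de(m, a, b, prior = list(d0 = 1e-9, s0_sq = 0.5))
  ref0 <- moderated_t_de(m, a, b, prior = list(d0 = 0, s0_sq = 0.5))
  expect_equal(near0$t, ref0$t, tolerance = 1e-6)

  huge <- moderated_t_de(m, a, b, prior = list(d0 = 1e9, s0_sq = 0.5))
  se_fixed <- sqrt(0.5 * (1 / 6 + 1 / 6))
  z <- (rowMeans(m[, a]) - rowMeans(m[, b])) / se_fixed
  expect_equal(huge$t, unname(z), tolerance = 1e-6)
  inf_prior <- moderated_t_de(m, a, b, prior = list(d0 = Inf, s0_sq = 0.5))
  expect_equal(inf_prior$p, 2 * pnorm(abs(unname(z)), lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("zero-variance genes under a d0 = 0 prior are flagged with missing p", {
  m <- rbind(flat = c(2, 2, 2, 2, 5, 5, 5, 5))
  colnames(m) <- sprintf("s%d", 1:8)
  res <- moderated_t_de(m, sprintf("s%d", 1:4), sprintf("s%d", 5:8),
                        prior = list(d0 = 0, s0_sq = 1))
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
})

test_that("type-I error of the moderated test with estimated prior is calibrated", {
  set.seed(23)
  m <- matrix(rnorm(10000 * 20), 10000,
              dimnames = list(sprintf("g%05d", 1:10000), sprintf("s%d", 1:20)))
  res <- moderated_t_de(m, sprintf("s%d", 1:10), sprintf("s%d", 11:20))
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.040)
  expect_lte(frac, 0.060)
})

test_that("estimate_prior recovers planted d0 and s0_sq and respects scale", {
  set.seed(24)
  d0 <- 4; s0 <- 0.05; dg <- 8; n <- 5000
  s2 <- s0 * d0 / rchisq(n, df = d0) * rchisq(n, df = dg) / dg
  prior <- estimate_prior(s2, dg)
  expect_lt(abs(prior$d0 - d0) / d0, 0.20)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.10)

  doubled <- estimate_prior(2 * s2, dg)
  expect_equal(doubled$d0, prior$d0, tolerance = 1e-8)
  expect_equal(doubled$s0_sq, 2 * prior$s0_sq, tolerance = 1e-8)
})

test_that("identical variances at large df give an infinite-d0 prior", {
  prior <- estimate_prior(rep(0.3, 200), df = 50)
  expect_true(is.infinite(prior$d0))
  expect_equal(prior$s0_sq, 0.3, tolerance = 0.05)
  expect_error(estimate_prior(rep(0.3, 10), df = 50), "50 genes")
})

test_that("estimated prior agrees with limma's empirical Bayes on shared input", {
  set.seed(25)
  s2 <- 0.05 * 6 / rchisq(2000, df = 6) * rchisq(2000, df = 10) / 10
  ours <- estimate_prior(s2, 10)
  ref <- limma::fitFDist(s2, df1 = 10)
  expect_equal(ours$d0, ref$df2, tolerance = 0.02)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 0.02)
})

test_that("treat_pvalue matches its closed forms and monotonicities", {
  # tau = 0 reduces to the two-sided t p-value
  expect_equal(treat_pvalue(1.3, 0.4, 7, 0),
               2 * pt(1.3 / 0.4, df = 7, lower.tail = FALSE))
  # Normal-df closed form
  expect_equal(treat_pvalue(2, 0.5, Inf, 1),
               pnorm(2, lower.tail = FALSE) + pnorm(6, lower.tail = FALSE))
  # boundary: |logFC| = tau with small se approaches 0.5 from above
  p_b <- treat_pvalue(1, 0.25, 30, 1)
  expect_gt(p_b, 0.5)
  expect_lt(p_b, 0.5 + 1e-6)
  # monotone decreasing in |logFC|, increasing in tau
  lfc <- seq(0, 4, by = 0.25)
  p_lfc <- treat_pvalue(lfc, 0.5, 10, 1)
  expect_true(all(diff(p_lfc) <= 0))
  taus <- seq(0, 2, by = 0.25)
  p_tau <- vapply(taus, function(tt) treat_pvalue(2, 0.5, 10, tt), numeric(1))
  expect_true(all(diff(p_tau) >= 0))
})

test_that("bh_adjust reproduces the hand step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(26)
  p <- runif(200)
  adj <- bh_adjust(p)
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= 0))
  expect_true(all(adj >= p))
  # tied inputs are a fixed point of the step-up
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
})

test_that("signature derivation recovers planted subtype markers", {
  recs <- vapply(1:5, function(s) {
    sim <- suppressMessages(suppressWarnings(simulate_cohort(
      cohort_sim_config(n_per_subtype = 40, n_normals = 10, n_genes = 600,
                        n_signature_genes = 60, n_silenced = 5, seed = s))))
    b <- sim$bundle; truth <- sim$truth
    sig <- suppressMessages(derive_signatures(
      b$expression[, names(truth$subtype)], truth$subtype,
      logfc_threshold = 0.25))
    rec <- mean(unlist(lapply(c("1", "2", "3"), function(k)
      truth$signature_genes[[k]] %in% sig[[k]]$up)))
    fp <- sum(vapply(c("1", "2", "3"), function(k)
      length(setdiff(sig[[k]]$up, truth$signature_genes[[k]])), numeric(1)))
    c(rec, fp / 600)
  }, numeric(2))
  expect_gte(median(recs[1, ]), 0.90)
  expect_lte(median(recs[2, ]), 0.01)
})

test_that("permuted labels yield essentially empty signatures", {
  sim <- suppressMessages(suppressWarnings(simulate_cohort(
    cohort_sim_config(n_per_subtype = 40, n_normals = 10, n_genes = 600,
                      n_signature_genes = 60, n_silenced = 5, seed = 31))))
  b <- sim$bundle; truth <- sim$truth
  set.seed(32)
  sizes <- vapply(1:10, function(i) {
    perm <- setNames(sample(truth$subtype), names(truth$subtype))
    sig <- suppressMessages(suppressWarnings(derive_signatures(
      b$expression[, names(perm)], perm, logfc_threshold = 0.25)))
    sum(vapply(sig, function(s) length(s$up) + length(s$down), numeric(1)))
  }, numeric(1))
  expect_lte(mean(sizes), 0.05 * 600)
})

test_that("signature derivation is a pure function of expression and labels", {
  sim <- tiny_bundle(seed = 8)
  truth <- sim$truth
  e <- sim$bundle$expression[, names(truth$subtype)]
  s1 <- suppressMessages(suppressWarnings(
    derive_signatures(e, truth$subtype, logfc_threshold = 0.25)))
  s2 <- suppressMessages(suppressWarnings(
    derive_signatures(e, truth$subtype, logfc_threshold = 0.25)))
  for (k in names(s1)) {
    expect_identical(s1[[k]]$up, s2[[k]]$up)
    expect_identical(s1[[k]]$down, s2[[k]]$down)
  }
})
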