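test_that("promoter summary collapses probes by mean or max with pairwise NA", {
  meth <- matrix(c(0.2, 0.4, 0.6, NA), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  pm <- tibble::tibble(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
  expect_equal(unname(promoter_summary(meth, pm)["gA", ]), c(0.3, 0.6))
  expect_equal(unname(promoter_summary(meth, pm, method = "max")["gA", ]),
               c(0.4, 0.6))
  # single-probe gene: summary equals the probe
  pm1 <- tibble::tibble(probe_id = "p1", gene_id = "gB")
  expect_equal(unname(promoter_summary(meth, pm1)["gB", ]),
               unname(meth["p1", ]))
  # all probes missing in a sample -> NA
  meth2 <- meth; meth2[, 2] <- NA
  expect_true(is.na(promoter_summary(meth2, pm)["gA", "s2"]))
})

test_that("perfect monotone anticorrelation yields rho exactly -1", {
  e <- matrix(rep(c(4, 3, 2, 1), each = 1), 1, 4,
              dimnames = list("g1", paste0("t", 1:4)))
  e <- rbind(e, g2 = rnorm(4))
  b <- matrix(c(0.1, 0.2, 0.3, 0.4, runif(4)), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("t", 1:4)))
  ann <- tibble::tibble(
    sample_id = c(paste0("t", 1:4), paste0("n", 1:3)),
    tissue = c(rep("tumor", 4), rep("normal", 3))
  )
  # pad to satisfy the >= 10 tumors precondition
  extra_t <- paste0("t", 5:12)
  e <- cbind(e, matrix(rnorm(2 * 8), 2, 8, dimnames = list(NULL, extra_t)))
  b <- cbind(b, matrix(runif(2 * 8), 2, 8, dimnames = list(NULL, extra_t)))
  e <- cbind(e, matrix(rnorm(2 * 3), 2, 3, dimnames = list(NULL, paste0("n", 1:3))))
  ann <- tibble::tibble(
    sample_id = c(paste0("t", 1:12), paste0("n", 1:3)),
    tissue = c(rep("tumor", 12), rep("normal", 3))
  )
  # rebuild g1 as a perfect monotone decreasing relation over all 12 tumors
  e["g1", paste0("t", 1:12)] <- 12:1
  b["g1", paste0("t", 1:12)] <- seq(0.05, 0.6, length.out = 12)
  scr <- anticorrelation_screen(e, b, ann)
  expect_equal(scr$rho[scr$gene_id == "g1"], -1)
})

test_that("screen p-values are uniform under the null", {
  set.seed(61)
  genes <- sprintf("g%04d", 1:2000)
  tumors <- paste0("t", 1:60); normals <- paste0("n", 1:6)
  e <- matrix(rnorm(2000 * 66), 2000,
              dimnames = list(genes, c(tumors, normals)))
  b <- matrix(runif(2000 * 66), 2000,
              dimnames = list(genes, c(tumors, normals)))
  ann <- tibble::tibble(sample_id = c(tumors, normals),
                        tissue = c(rep("tumor", 60), rep("normal", 6)))
  scr <- anticorrelation_screen(e, b, ann)
  # rank-based rho gives occasional tied p-values; ties only make the KS
  # statistic conservative here
  expect_gt(suppressWarnings(ks.test(scr$p, "punif"))$p.value, 0.01)
})

test_that("constant-beta genes are excluded with a flag", {
  sim <- tiny_bundle(seed = 13)
  b <- sim$bundle
  bs <- promoter_summary(b$methylation, b$promoter_map)
  bs[1, ] <- 0.5
  scr <- anticorrelation_screen(b$expression, bs, b$annotation)
  expect_true(rownames(bs)[1] %in% attr(scr, "excluded"))
  expect_false(rownames(bs)[1] %in% scr$gene_id)
})

test_that("hypermethylation calls use a strict per-probe normal maximum", {
  meth <- matrix(c(0.8, 0.3,   # tumor t1
                   0.6, 0.3,   # tumor t2 (equal to normal max -> FALSE)
                   0.6, 0.25,  # normal n1
                   0.5, 0.3),  # normal n2
                 2, 4, dimnames = list(c("p1", "p2"),
                                       c("t1", "t2", "n1", "n2")))
  pm <- tibble::tibble(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
  hm <- call_hypermethylation(meth, pm, c("n1", "n2"))
  expect_true(hm["gA", "t1"])     # 0.8 > 0.6
  expect_false(hm["gA", "t2"])    # 0.6 is not strictly greater
  # two probes, one exceeding: true under any-probe, false under summary
  meth2 <- matrix(c(0.65, 0.10, 0.6, 0.25, 0.5, 0.3), 2, 3,
                  dimnames = list(c("p1", "p2"), c("t1", "n1", "n2")))
  expect_true(call_hypermethylation(meth2, pm, c("n1", "n2"))["gA", "t1"])
  expect_false(call_hypermethylation(meth2, pm, c("n1", "n2"),
                                     rule = "summary")["gA", "t1"])
})

test_that("no normal sample is hypermethylated against the full normal set", {
  sim <- tiny_bundle(seed = 14)
  b <- sim$bundle
  normals <- b$annotation$sample_id[b$annotation$tissue == "normal"]
  hm <- call_hypermethylation(b$methylation, b$promoter_map, normals,
                              tumor_samples = normals)
  expect_false(any(hm, na.rm = TRUE))
})

test_that("targetability is the conjunction of hypermethylation and no-loss", {
  hm <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
               dimnames = list(c("g1", "g2"), c("t1", "t2")))
  cnv <- matrix(c(-1L, 1L, 0L, NA), 2, 2,
                dimnames = list(c("g1", "g2"), c("t1", "t2")))
  tgt <- targetable_matrix(hm, cnv)
  expect_false(tgt$targetable["g1", "t1"])  # hypermethylated but lost
  expect_true(tgt$targetable["g2", "t1"])   # hypermethylated, gain
  expect_false(tgt$targetable["g1", "t2"])  # not hypermethylated
  expect_true(tgt$targetable["g2", "t2"])   # missing CNV treated as no-loss
  expect_true(tgt$cnv_missing["g2", "t2"])
  expect_true(all(tgt$targetable == (tgt$hypermethylated & tgt$no_loss)))
})

test_that("panel coverage matches hand enumeration and exhaustive oracle", {
  tgt <- matrix(FALSE, 3, 4, dimnames = list(c("g1", "g2", "g3"),
                                             c("s1", "s2", "s3", "s4")))
  tgt["g1", "s1"] <- TRUE
  tgt["g2", c("s2", "s3")] <- TRUE
  cov <- panel_coverage(tgt, panel = c("g1", "g2"))
  expect_equal(cov$coverage$coverage_pct[cov$coverage$group == "overall"], 75)
  # empty panel covers nothing
  cov0 <- panel_coverage(tgt, panel = character(0))
  expect_equal(cov0$coverage$coverage_pct[cov0$coverage$group == "overall"], 0)
  # full panel equals any-targetable fraction
  covf <- panel_coverage(tgt, panel = rownames(tgt))
  expect_equal(covf$coverage$coverage_pct[covf$coverage$group == "overall"],
               100 * mean(colSums(tgt) > 0))

  set.seed(62)
  for (i in 1:100) {
    m <- matrix(runif(5 * 8) < 0.3, 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    panel <- sample(rownames(m), sample(0:5, 1))
    got <- panel_coverage(m, panel = panel)
    expect_equal(got$coverage$coverage_pct[got$coverage$group == "overall"],
                 oracle_coverage_pct(m, panel))
  }
})

test_that("empty groups are flagged as undefined coverage, not zero", {
  tgt <- matrix(TRUE, 1, 2, dimnames = list("g1", c("s1", "s2")))
  groups <- setNames(c("A", "A"), c("s1", "s2"))
  cov <- panel_coverage(tgt, groups, panel = "g1")
  expect_false("B" %in% cov$coverage$group)
  # a declared-but-empty group arises when groups carry unused levels
  groups2 <- factor(c("A", "A"), levels = c("A", "B"))
  names(groups2) <- c("s1", "s2")
  cov2 <- panel_coverage(tgt, setNames(as.character(groups2), names(groups2)),
                         panel = "g1")
  expect_equal(cov2$coverage$coverage_pct[cov2$coverage$group == "A"], 100)
})

test_that("coverage is monotone in the panel", {
  set.seed(63)
  for (i in 1:25) {
    m <- matrix(runif(6 * 10) < 0.25, 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    panel <- sample(rownames(m), 3)
    extra <- sample(setdiff(rownames(m), panel), 1)
    groups <- setNames(sample(c("A", "B"), 10, replace = TRUE), colnames(m))
    before <- panel_coverage(m, groups, panel)$coverage
    after <- panel_coverage(m, groups, c(panel, extra))$coverage
    expect_true(all(after$coverage_pct >= before$coverage_pct, na.rm = TRUE))
  }
})

test_that("greedy panel selection is near-optimal and exact on disjoint instances", {
  # disjoint blocks: greedy is exactly optimal
  tgt <- matrix(FALSE, 3, 9, dimnames = list(paste0("g", 1:3), paste0("s", 1:9)))
  tgt["g1", 1:4] <- TRUE; tgt["g2", 5:7] <- TRUE; tgt["g3", 8:9] <- TRUE
  gp <- greedy_panel(tgt, max_size = 3)
  expect_equal(gp$panel, c("g1", "g2", "g3"))
  expect_equal(max(gp$trajectory$coverage_pct), 100)
  # one gene covering everything -> panel of size 1
  tgt2 <- tgt; tgt2["g2", ] <- TRUE
  gp2 <- greedy_panel(tgt2, max_size = 3)
  expect_equal(gp2$panel[1], "g2")
  expect_equal(gp2$trajectory$coverage_pct[1], 100)

  set.seed(64)
  for (i in 1:15) {
    m <- matrix(runif(8 * 15) < 0.2, 8, 15,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:15)))
    k <- sample(2:4, 1)
    gp <- greedy_panel(m, max_size = k)
    greedy_cov <- max(gp$trajectory$coverage_pct)
    best <- oracle_best_coverage(m, k)
    expect_gte(greedy_cov + 1e-9, (1 - 1 / exp(1)) * best)
  }
})

test_that("screen recovers planted silenced genes with few false candidates", {
  stats <- vapply(1:10, function(s) {
    sim <- suppressMessages(suppressWarnings(simulate_cohort(
      cohort_sim_config(n_per_subtype = 30, n_normals = 12, n_genes = 500,
                        n_signature_genes = 40, n_silenced = 12, seed = s))))
    b <- sim$bundle
    bs <- promoter_summary(b$methylation, b$promoter_map)
    scr <- anticorrelation_screen(b$expression, bs, b$annotation)
    cand <- scr$gene_id[scr$candidate]
    c(rec = sum(sim$truth$silenced_genes %in% cand),
      fp = length(setdiff(cand, sim$truth$silenced_genes)))
  }, numeric(2))
  expect_gte(median(stats["rec", ]), 11)
  expect_lte(median(stats["fp", ]), 2)
})
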