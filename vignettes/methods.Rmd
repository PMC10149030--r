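---
title: "Methods: from multi-omic cohort to patient-covering gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-omic cohort to patient-covering gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(epitarget)
```

## The analysis problem

Tumor-suppressor genes are frequently inactivated not by mutation but by
promoter DNA hypermethylation. Unlike a deleted gene, an epigenetically
silenced gene retains an intact coding sequence and can in principle be
reactivated, for example by CRISPR activation. This package implements the
computational side of finding such genes in a multi-omic tumor cohort and
deciding which small set of them would benefit the largest fraction of
patients:

1. **Subtype label transfer.** Molecular subtype labels are typically
   available only for samples profiled on every platform. Signatures derived
   from the labeled samples are used to transfer labels to the rest.
2. **Silencing screen.** Genes whose promoter methylation anticorrelates
   with their expression across tumors, and whose expression is higher in
   normal tissue, are candidate silenced tumor suppressors.
3. **Targetability and panel selection.** A (gene, tumor) pair is worth
   targeting only if the gene is hypermethylated in that tumor and not
   deleted. A greedy set cover picks the panel that covers the most
   patients.
4. **Experiment support.** Off-target enumeration for guide RNAs and
   ΔΔCt quantification for validation qPCR.

Everything runs against a synthetic cohort generator with full ground
truth, so each stage is testable without external data.

## Cohort model and simulator

A cohort bundle holds five aligned pieces: a genes × samples log-scale
expression matrix, a probes × samples methylation β-value matrix
(β ∈ [0, 1]), a probe→gene promoter map, a genes × samples copy-number
call matrix in {−2, …, 2}, and a sample annotation table (tissue, subtype
label or `NA`). `cohort_bundle()` aligns everything to the intersection of
sample ids and reports drops.

`simulate_cohort()` plants: three tumor subtypes, each with its own
marker genes shifted by `effect_size` standard deviations (markers of
other subtypes are shifted half as much in the opposite direction, so
signatures are genuinely bidirectional); a set of silenced genes driven by
a latent per-tumor severity variable that raises promoter β and pushes
expression *down* from the shared tumor/normal baseline (a pure downshift,
so normal tissue remains the higher-expressing group, as in real silencing);
matched normals sharing per-gene baselines; and independent copy-number
calls with a configurable loss probability. The expression downshift
coefficient is solved from a target correlation so that the realized
tumor-wise Spearman correlation between promoter β and expression is
strongly negative (about −0.75 to −0.9 at the default
`anticor_strength = 0.8`). Ground truth (subtype, silenced genes, marker
sets, realized correlations) is returned alongside the bundle.

Limits worth keeping in mind: noise is Gaussian and homoscedastic, probes
within a promoter are exchangeable, and copy number is independent of
methylation — the generator is built to make every downstream claim
checkable, not to mimic platform artifacts.

## Rank-based signature scoring and label transfer

A sample is scored against a signature by ranking all `n` genes
(ascending, average ties) and measuring the normalized displacement of the
up-set's mean rank from its minimum attainable value:

score_up = (mean rank(up) − (m+1)/2) / (n − m) − 0.5.

The down-component applies the same formula to the reversed ranks, and
the score is the sum of whichever components exist (either set may be
empty, not both). Scores lie in [−1, 1] for bidirectional signatures and
are invariant to any strictly monotone transform of expression — the
property that makes single-sample scoring robust to normalization
differences between labeled and unlabeled samples.

```{r}
rank_score(c(g1 = 10, g2 = 2, g3 = 7, g4 = 1, g5 = 9), up = c("g1", "g5"))
```

Label transfer standardizes each score dimension by the training mean and
sd and assigns each unlabeled sample the majority label of its `k = 30`
nearest training samples (Euclidean distance). Probabilities are exact
multiples of 1/k; equal distances are ordered deterministically by
(distance, training sample id), and subtype ties fall to the nearest
neighbor among the tied subtypes, so results are reproducible to the byte.

## Moderated t, TREAT, and FDR control

Signatures come from one-vs-rest differential expression with an
empirical-Bayes moderated t: per-gene pooled variances are shrunk toward a
prior, s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g), with the prior (d₀, s₀²)
estimated by matching moments of the log sample variances (Newton
inversion of the trigamma function; d₀ = ∞ when the variances show no
excess spread, reducing the test to a z-test; d₀ = 0 recovers the ordinary
pooled t-test exactly). Rather than testing against zero, the TREAT-style
p-value tests whether |logFC| exceeds a threshold τ:

p = P(T ≥ (|logFC| − τ)/se) + P(T ≥ (|logFC| + τ)/se),

which approaches 0.5 from above at |logFC| = τ. Multiplicity is handled by
Benjamini–Hochberg; the two-stage Benjamini–Krieger–Yekutieli procedure
(`bky_two_stage()`) is provided for the qPCR module, where its adaptive
stage-2 level q·m/(m − r₁)/(1 + q) buys power at small m.

**Choice of τ.** `derive_signatures()` defaults to the conventional
τ = 1.5 appropriate for cohorts with large subtype separation. The
pipeline default is τ = 0.25, matched to the synthetic cohort's planted
1-sd subtype effect: a threshold above the true effect provably yields
empty signatures, while a quarter of the effect leaves a wide rejection
margin for true markers (measured marker recovery ≈ 100% with a
false-marker fraction below 0.1%). Both are plain config fields.

## The silencing screen

For every gene, `anticorrelation_screen()` computes the Spearman
correlation between its promoter β summary and expression across tumors
(vectorized rank transform; p-value from the t approximation on n − 2 df),
plus a one-sided Mann–Whitney test that normal tissue expresses the gene
more highly than tumors. A candidate must satisfy all three: ρ ≤ −0.3,
BH-adjusted correlation p < 0.05, and normal-higher p < 0.05. The ρ and α
cutoffs are declared defaults, exposed as arguments, since "strong inverse
correlation" has no canonical numeric value.

Hypermethylation is called per (gene, tumor) when a tumor promoter probe
β **strictly exceeds** the maximum β of that probe across *all* normal
samples — the strict inequality means a tumor tied with the most
methylated normal is not called, which keeps the call conservative and the
boundary exactly testable. The default `any-probe` rule calls a gene on
any exceeding probe; a `summary` rule on the promoter mean is available.
Targetability additionally requires copy-number ≥ 0; missing copy number
is treated as no-loss but flagged.

## Greedy patient-covering panels

`greedy_panel()` repeatedly adds the gene with the greatest marginal
overall coverage (fraction of tumors with ≥ 1 targetable panel gene),
breaking ties by the higher minimum per-subtype coverage and then
lexicographically — every run is deterministic. Greedy set cover carries
the classical guarantee of at least (1 − 1/e) ≈ 63% of the optimal
coverage at any panel size, which the test suite verifies against
exhaustive enumeration on small instances.

## Off-target enumeration

`find_offtargets()` scans both strands of a genome exhaustively: at every
position, the 20-nt protospacer is compared base-by-base (Hamming
distance, default budget 3 mismatches) and the adjacent PAM is matched
against an IUPAC pattern (default `NGG`; PAM degeneracy is membership, not
mismatch). Ambiguous (`N`) genome bases never match. Coordinates are
0-based, half-open, on the forward strand for both orientations, sorted by
(contig, start, strand) — so reverse-complementing the genome mirrors the
hit set exactly. Hits can be annotated with windowed BED-interval overlaps
(`annotate_hits()`), using the same half-open convention.

## qPCR quantification

`delta_delta_ct()` normalizes each replicate's target Ct by the arithmetic
mean of the housekeeping Cts (equivalent to the geometric mean of
abundances), takes ΔΔCt against the control condition, and reports
fold = 2^(−ΔΔCt) with replicate-level folds for downstream testing.
Wells at the 40-cycle cap are censored: a condition whose target wells are
all undetected gets its fold flagged as an upper bound rather than a
point estimate.

```{r}
ct <- tibble::tibble(condition = rep(c("control", "treated"), each = 2),
                     target = rep(c("T1", "HK"), 2),
                     replicate = 1L, ct = c(30, 20, 27, 20))
delta_delta_ct(ct, housekeeping = "HK")
```

## Reproducibility

`run_pipeline()` executes simulate → signatures → transfer → screen →
targetability → panel end-to-end, writing every stage as TSV plus a
`summary.json` and the realized config, so each artifact is re-derivable
from config + seed alone; reruns are byte-identical on all stage outputs.
Cohort TSVs round-trip doubles bit-identically (`%.17g` serialization,
strtod parsing). All statistical primitives are validated against
independent oracles (brute-force rank scoring, naive per-position genome
scans, exhaustive coverage enumeration) and on planted ground truth in the
test suite.
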