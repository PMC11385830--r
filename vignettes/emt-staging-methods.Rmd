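---
title: "Methods: marker-anchored EMT staging and its synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-anchored EMT staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emtstage)
```

# The model

`emtstage` treats epithelial–mesenchymal transition (EMT) progression as an
ordinal pseudo-staging problem anchored to a single marker gene rather than
to an inferred trajectory. The working assumptions are:

1. **Marker monotonicity.** Vimentin (*VIM*) expression increases
   monotonically with mesenchymal commitment, so its log2-normalized value
   is usable as an ordinal stage coordinate. Unit-width half-open bins
   `(i-1, i]` over the 0–6 range partition cells into six stages. This is an
   assumption, not an inference: the package never checks that VIM *should*
   order the cells, it only makes all downstream statistics conditional on
   that ordering.
2. **Persistent activation.** EMT transcription factors are modeled (and
   classified) as switch-like: once significantly upregulated relative to
   the most epithelial stratum, they are expected to remain upregulated in
   all later stages. The onset classifier reports exactly this: the earliest
   significant stage, and a persistence flag over all stages at or above it.
3. **Distributional pragmatism.** All single-cell tests are rank-based
   (Wilcoxon), all enrichment scores are rank-based running sums, and the
   bulk moderated-t assumes approximate log-normality — standard choices for
   the respective data types, none specific to EMT biology.

# Tunable parameters and their defaults

| parameter | default | units / meaning |
|---|---|---|
| QC MAD multipliers | 5 / 5 / 3 | log1p library size and detection (lower tail), mito % (upper tail) |
| gene filter `min_cells` | 6 | "expressed in more than five cells" |
| normalization | log2 CP10K | target sum 1e4, pseudocount 1 |
| HVG count | 3000 | top standardized variances |
| PCs | 13 | embedding dimensionality |
| staging bins | 6 x width 1 | log2 marker scale, `(a, b]`, zero to bin 1, top clamp |
| DE gates | p < 0.05, log2FC >= 1 | BH-adjusted p by default |
| rank-sum exact cutoff | both groups <= 8 | exact enumeration below, tie/continuity-corrected normal above |
| log2FC pseudocount | 1e-9 | on the de-logged (CP10K) scale |
| enrichment exponent | 0.25 | rank-weight tau in the running sum |
| GSEA permutations | 1000 | gene-label permutations |
| Cox | Breslow ties, tol 1e-8 | damped Newton, max 100 iterations |

The MAD cut directions and the log1p scale are choices this package makes
explicitly (robust one-sided QC semantics; count totals are heavily
right-skewed); the MAD uses the 1.4826 normal-consistency constant. The
variance-stabilizing transform is deliberately *not* a regression-based
method: staging needs a fixed, reproducible log2 scale for the unit-width
bins, so log2 CP10K is the default and is what the 0–6 bin range is defined
against.

# The synthetic world

`simulate_emt_continuum()` states the world the tests live in:

- latent coordinate `u ~ Uniform(0, 1)` per cell (uniform so all six strata
  are populated; a two-component Beta mixture is available for
  epithelial- or mesenchymal-enriched populations);
- marker means `E[log2 VIM] = 6u`, `E[log2 CDH1] = E[log2 EPCAM] = 6(1-u)`;
- TF activation `b_g + a_g * 1[u >= o_g]` — a step, not a sigmoid, because
  the phenomenon being modeled is persistent switch-like activation
  (a logistic option exists for sensitivity);
- counts `NB(mean, theta)` with `Var = mu + mu^2/theta` (the (mean,
  dispersion) convention is stated here precisely to avoid the size/prob
  convention drift between tools), `theta = 10` by default;
- lognormal size factors (`sdlog = 0.3`), a 5% mitochondrial gene block
  scaled to a 5% count share, and optional injected QC-failure cells (2%
  size factors; half mito-inflated 40x);
- background gene abundances scaled so a typical cell totals ~1e4 counts,
  which makes the log2 CP10K value of the marker track its configured mean —
  this is what anchors latent onsets `o_g` to observable stages via
  `stage = ceiling(6 * o_g)`.

The bulk, survival and DSP generators follow the same pattern: NB counts
with planted log2 shifts; exponential event times with hazard
`lambda_0 * exp(beta_true * z)` and an exponential censoring rate solved
numerically so the realized censoring fraction matches the request; paired
segments sharing a lognormal ROI effect with the EMT program elevated in the
Vim-positive segment.

**What the generator does not emulate** — and therefore what a green test
does *not* establish: gene–gene correlation beyond the single latent axis,
batch effects, ambient RNA, doublets, zero-inflation beyond NB sampling,
non-proportional hazards, and spatial autocorrelation within segments.
Recovery results on this world demonstrate that the *procedures* are
implemented correctly and are well-calibrated under their own assumptions,
not that VIM staging is biologically valid in any particular tumor.

# Numerical and design choices

- **Rank-sum p-values.** Exact enumeration of all `C(nA+nB, nA)` assignments
  (two-sided as twice the smaller tail, clipped at 1) when both groups have
  at most 8 members; otherwise the normal approximation with tie correction
  and continuity correction. The two agree with the reference implementation
  to machine precision in the tests.
- **Adjusted vs raw p in the onset gate.** The published gate "p < 0.05"
  is ambiguous between raw and BH-adjusted values; the package defaults to
  the adjusted value (the conservative reading, matching the DE tool it
  emulates) and exposes `use_adjusted = FALSE` for the permissive one.
- **Zero-marker cells.** A strict reading of the "0 < x <= 1" bin would
  discard zero-VIM cells; they are kept in the lowest stratum by default
  (the epithelial reference must contain fully epithelial cells), with
  `drop_zero = TRUE` for the strict behavior.
- **Enrichment normalization.** "Normalized enrichment score" is undefined
  for a per-cell score matrix, so the package states its own: ES divided by
  the global maximum |ES| across all sets and cells, mapping into [-1, 1]
  and preserving signs. Comparisons are therefore meaningful within one
  score matrix, not across matrices.
- **Stage trend.** Spearman correlation is computed per cell against the
  ordinal stage index by default (`by_stage_median = TRUE` computes it on
  the six medians instead — the other defensible reading).
- **76-gene score.** Missing signature genes are imputed at zero expression
  with a coverage warning rather than renormalizing weights, so scores stay
  comparable across matrices with different coverage. Centering subtracts
  the grand mean exactly. The packaged weight table is synthetic (the
  published weights are not public domain data in this repository) and is
  labelled `_synthetic` in its filename.
- **Survival.** KM, log-rank and Cox are implemented directly (product-limit
  form; O-E chi-square with the hypergeometric variance; Breslow partial
  likelihood with damped Newton and step-halving). With tie-free data the
  log-rank statistic equals the Cox score test, which the tests verify
  numerically. Ties use Breslow's method — the simplest consistent choice.
  The High/Low split is at the mean score with ties-at-mean assigned Low
  (deterministic).
  A note on degenerate designs: with two subjects and one event the partial
  likelihood is monotone in beta (complete separation), so the smallest
  closed-form Cox toy has no finite optimum; the implementation reports
  this as an explicit error and correctness is instead established against
  the reference implementation on richer examples.
- **Moderated t.** The prior `(d0, s0^2)` is moment-matched on
  `log s^2_g` via the digamma/trigamma identities of the scaled-F model,
  with a Newton inversion of the trigamma function; `d0 = 0` reproduces the
  ordinary t and `d0 = Inf` the pooled-variance z-like statistic, both
  verified as limits. Agreement with the reference empirical-Bayes
  implementation is tested to 1e-8.
- **Preranked GSEA.** Weighted KS running sum (exponent 1). The null is
  gene-label permutation: with only nine ROI pairs, phenotype permutation
  has far too coarse a resolution, so the preranked form is the honest
  option; this is a documented divergence from phenotype-permutation GSEA.
  NES normalizes by the same-sign mean |permuted ES|; FDR q compares the
  pooled permuted NES distribution with the observed NES distribution.
  The DSP ranking metric is `-log10(p) * sign(mean difference)` from the
  paired t; zero-variance genes are excluded with a report.
- **Q3 normalization.** Each AOI is scaled so its 75th percentile equals the
  geometric mean of all AOI 75th percentiles — scale-free, and a no-op when
  AOIs are already comparable.
- **Graph clustering.** SNN-Jaccard weights on a kNN graph, Louvain
  modularity. Modularity optimization has a resolution limit: at resolution
  1 it splits large homogeneous blobs into pure fragments, so
  planted-partition recovery is exercised at low resolution in the tests and
  `resolution` is a first-class parameter, matching common practice of
  scanning it.
- **Determinism.** Every stochastic step takes a seed and restores the
  caller's RNG state; HVG and enrichment ties break lexicographically by
  gene identifier; reruns with an identical manifest are byte-identical for
  deterministic stages.

# Limitations

- Staging by one marker is a modeling commitment; no attempt is made to
  infer trajectories, branching, or velocity.
- The per-cell enrichment score is a rank-based stand-in for kernel-CDF
  GSVA; absolute values differ from GSVA's, though stage trends and
  orderings are the quantities used downstream.
- The Cox module is single-covariate by design (group or score); no
  multivariable adjustment or proportionality diagnostics beyond the
  monotone-likelihood error.
- Real-data headline results (cell counts, cluster counts, specific TF
  onsets, cohort survival curves) require the deposited accessions and are
  documented as qualitative anchors only; nothing in the test suite claims
  to reproduce them.
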