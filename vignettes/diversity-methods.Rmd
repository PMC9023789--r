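---
title: "Methods: the adjusted-entropy cell type diversity statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adjusted-entropy cell type diversity statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldiv)
```

## The statistic and its assumptions

A sample *s* in annotated single-cell data is a vector of cell counts
$n_{1s}, \dots, n_{ks}$ over a panel of $k$ cell types, with total
$n_s = \sum_i n_{is}$. `celldiv` summarizes the whole composition by the
adjusted entropy of the proportions $p_{is} = n_{is}/n_s$:

$$E_s \;=\; \frac{-\sum_{i=1}^{k} p_{is}\,\log p_{is}}{\log k} \;-\; 1 .$$

Three assumptions motivate the construction:

1. **Normalization by depth.** Total cell counts differ arbitrarily
   between samples (sequencing depth, capture efficiency), so only the
   proportions $p_{is}$ are comparable, never the raw counts.
2. **Compositionality.** Conditioning on $n_s$ puts the proportions on
   the simplex: they sum to 1, and a rise in one type forces falls in
   others. A per-sample summary of the whole vector respects this
   dependence, where per-type tests do not.
3. **Normalization by resolution.** Dividing the Shannon entropy by its
   maximum $\log k$ makes values comparable across panels of different
   size, so the same quantity can be reported at, say, a 2-lineage and a
   12-subtype resolution.

$E_s$ ranges over $[-1, 0]$: $0$ exactly when all proportions equal
$1/k$, $-1$ exactly when one type holds every cell. Higher values mean a
more even composition. We keep this $[-1,0]$ sign convention throughout;
the familiar Pielou-evenness scale $[0,1]$ is just $E_s + 1$ and is not
produced by any function to avoid two conventions circulating in output
files.

The statistic is a *global* summary: it says compositions became more or
less even, not which cell type moved. It is also only meaningful over a
fixed panel — see Limitations.

## Panel semantics: what k means

`k` is the number of columns of the composition matrix — the declared
analysis panel — not the number of types observed in a particular
sample. Types with zero counts stay in the panel (and contribute nothing
to the entropy via the $0 \log 0 = 0$ convention). The alternative,
letting `k` shrink per sample, would silently change the normalizing
constant between samples and destroy comparability, which is the
statistic's purpose. `count_composition()` therefore accepts an explicit
`panel` argument, and `k = 1` is an error rather than a `NaN`: the
normalization divides by $\log k$, which vanishes at $k = 1$.

## Group comparison

`compare_groups()` runs a fixed-effects one-way ANOVA of the per-sample
$E_s$ against group labels, followed by two-sided two-sample t-tests for
every group pair (or a reference group against the rest). Choices a user
can change, with the defaults and why:

* `variance_mode = "pooled"` (default) versus `"welch"`. With groups of
  a few dozen samples and similar spreads the classic pooled test is the
  conventional default of pairwise-t workflows; Welch is available for
  visibly unequal spreads. Each pair is tested with its own two-sample
  test (no variance pooling across non-compared groups).
* `adjust = "none"` (default), `"holm"`, `"bh"`. Raw p-values are always
  reported; with only a handful of groups, readers often prefer to see
  them and apply their own correction. Holm (family-wise) and
  Benjamini–Hochberg (FDR) are one flag away and are appended as an
  extra column, never replacing the raw values.
* `alpha = 0.05` is recorded with the result for reporting; it never
  censors output.

Preconditions are enforced loudly: at least two groups, at least two
samples per compared group (a variance is undefined below that), and an
error — not an `Inf` — when every group's within-variance is zero, since
the F statistic is then meaningless.

No covariate adjustment or per-type differential abundance is offered;
those need regression-style models and are outside this package's scope.

## The synthetic cohort generator

Real annotated cohorts of the shape this package targets are access
restricted, so testing and calibration run on simulated data. The
generative model is Dirichlet-multinomial: for each sample of a group,

$$p \sim \mathrm{Dirichlet}(\alpha_{\text{group}}), \qquad
  (n_{1s},\dots,n_{ks}) \sim \mathrm{Multinomial}(n_s, p).$$

This is the standard model for overdispersed compositional counts: the
multinomial induces the negative dependence among type counts that a
fixed cell total forces, and the Dirichlet adds between-sample
variability. $\alpha/\sum\alpha$ is the expected composition;
$\sum\alpha$ tunes how tightly samples cluster around it (the presets
use $\sum\alpha = 30$, giving sample-to-sample proportion scatter of a
few percentage points on the dominant types, which looks like real PBMC
cohorts).

Two presets ship with the package:

* `aging_preset()`: four groups of 12/26/14/14 samples over a 12-type
  PBMC panel (7 lymphoid, 5 myeloid), 300–1200 cells per sample drawn
  uniformly. The three younger groups' concentrations are skewed toward
  the dominant lymphoid types; the fourth group's concentration is
  distinctly more even with a larger myeloid share, so its expected
  $E_s$ is the highest. The $\alpha$ values are artifact choices made
  once to look like plausible PBMC compositions — no per-group
  proportion tables exist to calibrate them against, so the preset
  targets the qualitative direction only.
* `aging_null_preset()`: the same sizes and panel with one shared
  $\alpha$ (fixed 500 cells/sample), used for type-I-error calibration
  of the ANOVA pipeline via `calibration_experiment()`.

What the generator deliberately does **not** emulate: expression counts,
annotation error, doublets, batch or dataset-of-origin effects, and
covariate structure (age within group, sex). A green simulation test
therefore establishes that the pipeline's statistics behave correctly
under a clean compositional model — not that any biological claim about
a real cohort would replicate.

Reproducibility: every sample has its own random substream derived from
the root seed and the sample's global index, so the same config always
yields the same matrices, appending groups or samples never perturbs
earlier samples' draws, and the caller's RNG state is restored on exit.

## Numerical choices

* **Zero proportions** use the entropy limit $0\log 0 = 0$; real panels
  routinely contain types absent from a sample.
* **Natural log** internally. $E_s$ is invariant to the log base
  (numerator and denominator rescale together — the test suite checks
  agreement with a base-2 implementation to 1e-12); fixing one base
  keeps intermediate values reproducible.
* **Boundary clamping.** Floating-point summation can overshoot the
  analytic range by an ulp (e.g. `rep(1/3, 3)` does not sum its logs to
  exactly `log(3)`). Values within 1e-12 of a boundary are clamped to
  exactly 0 or −1, so range checks and the boundary identities are
  exact. 1e-12 is far above accumulated rounding error at any realistic
  `k` and far below any meaningful difference in the statistic.
* **Simplex tolerance.** Proportion rows must sum to 1 within 1e-9 —
  loose enough for values that round-tripped through text files, tight
  enough to catch genuinely unnormalized input.
* **Zero-cell samples** have no defined composition. They are dropped
  with a warning (logged, never silent, by the CLI) rather than
  erroring, so a batch run survives an empty sample; a matrix that is
  *all* zeros errors. No minimum-cells-per-sample filter is applied
  beyond that: there is no principled universal cutoff, and the
  `n_cells` column in every diversity table lets users apply their own.
* **Deterministic ordering.** Columns follow the panel order (or
  lexicographic order when no panel is given), rows are sorted by sample
  id, and coarse labels keep their order of first appearance in the
  hierarchy, so all output tables are byte-stable across runs. Plot
  images are a convenience surface and excluded from byte-exactness.
* **Unmapped fine labels** during aggregation are an error naming the
  label; an opt-in `other_bucket` collects them into a literal `"Other"`
  instead. Silent catch-all buckets hide annotation mismatches, so the
  default is strict.

## Limitations

* $E_s$ compares samples only over a common panel; a cell type that is
  undetectable in some condition either stays in the panel with zero
  counts (depressing those samples' $E_s$) or forces a different panel,
  changing the normalization. Different metrics are needed when the
  detectable panel itself varies across conditions.
* The statistic is symmetric in the types: compositions that are
  permutations of each other get the same value, so a lymphoid-to-myeloid
  shift and its mirror image are indistinguishable by $E_s$ alone —
  pair it with the stacked-bar view of the proportions.
* ANOVA and t-tests treat $E_s$ as approximately normal within groups;
  with very few cells per sample or $E_s$ pinned near a boundary the
  approximation degrades. The bundled calibration experiment checks the
  type-I error rate under the preset's regime (hundreds of cells,
  moderate evenness), not in those corners.
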