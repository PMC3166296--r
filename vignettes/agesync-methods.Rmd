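---
title: "Methods: detecting and testing spatio-temporal association of age-related expression change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and testing spatio-temporal association of age-related expression change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agesync)
```

## The question and the model

Tissues of a multicellular organism do not age in lockstep. Given expression
profiles of several tissues measured at an ordered ladder of ages, agesync
asks, for every *age phase* (a window between two consecutive ages) and every
pair of tissues: do the genes that changed in one tissue overlap the genes
that changed in the other far more than chance? Same-direction overlap
(up–up or down–down) is *synchronous* behaviour, opposite-direction overlap
is *asynchronous*, and a changed gene set that overlaps nothing significantly
is *stochastic* at that phase.

The unit of analysis is the directional change set, written
`<Tissue>_<to><unit>v<from><unit>_<direction>` (e.g. `A_10Mv4M_up`: genes
up-regulated in adrenal gland between 4 and 10 months). For two sets of sizes
$M$ and $K$ drawn from a universe of $N$ genes and sharing $x$ genes, the
association statistic is the hypergeometric tail

$$
p \;=\; P(X \ge x) \;=\; \sum_{i=x}^{\min(M,K)}
\frac{\binom{M}{i}\binom{N-M}{K-i}}{\binom{N}{K}},
\qquad X \sim \mathrm{Hypergeometric}(N, M, K),
$$

i.e. the chance that a random $K$-subset of the universe hits the first set
at least $x$ times. Pairs with $p$ strictly below a configured threshold
become network edges, typed synchronous or asynchronous by direction
equality. Repeating the test across *all* tissue–phase combinations (not
just within one phase) yields the four-dimensional map, whose edges are
additionally classed `same-tissue` (temporal persistence within a tissue),
`cross-tissue same-phase`, or `cross-tissue cross-phase`.

### Assumptions

* Conditional on the set sizes, under the null the two sets are independent
  uniform draws from the shared universe. This is what the planted-structure
  simulator reproduces and what the calibration tests verify.
* The universe $N$ must be the set of genes *eligible* to appear in any
  change set. The package defaults to the post-filter universe (genes
  surviving the missingness filter), because a gene removed before detection
  can never be drawn; the pre-filter count remains available
  (`universe = "input"`) for sensitivity checks, since "all genes on the
  chip" is also a defensible reading.
* No multiple-testing correction is applied across pairs: the method reports
  raw per-figure thresholds (conventionally 0.001–0.005 for per-phase
  networks, 1e-4–5e-4 for the much larger four-dimensional family, which is
  why the 4D default is stricter).

## Change criteria

Four criteria produce the directional sets; exactly one is active per run.

| kind | rule | intended design |
|---|---|---|
| `fold_change` | mean-aggregated per-condition values; called up when the ratio `to/from` ≥ `fc_threshold` (log2 difference ≥ `log2(fc_threshold)`), down for the reciprocal; **inclusive** boundary ("at least") | pooled-RNA designs, one array per condition |
| `z_test` | one-sided two-sample Z with unpooled per-group variances ($n-1$ denominators); up when the upper normal tail < `z_alpha`, down for the lower tail | ≥ 2 (ideally ≥ 3) replicate arrays per condition |
| `mas5_composite` | change p < 0.0025 (increase; $1-p$ < 0.0025 for decrease) **and** fold-change ≥ 2 **and** both conditions detected Present | Affymetrix MAS5-style outputs; change p-values and P/A/M calls are consumed as inputs, never computed |
| `consensus` | fold-change passed in the same direction in each of two datasets measuring the same process | duplicated array designs |

Parameter notes:

* `fc_threshold` (ratio, default 2) is interpreted on the linear scale;
  on log2 data it is applied as `|Δlog2| ≥ log2(threshold)`. The loader never
  transforms values — a `scale` flag travels with the dataset, because mixed
  inputs (MAS5 signals, Z-scored matrices) must not be silently re-scaled.
  Fold-change thresholds are meaningless for Z-scored (scale-free) data;
  use the `z_test` criterion there.
* `z_alpha` (per tail, default 0.01): the Z statistic uses estimated
  variances, so with few replicates it is anticonservative — at $n = 5$ per
  condition the statistic is approximately $t_8$ and the realized per-tail
  rate at the normal 0.01 cutoff is ≈ 0.024, converging to 0.01 only as
  replicates grow (the test suite measures both ends). With pooled designs
  there are no replicates at all and the fold-change criterion is the only
  option. This is a real limitation of the Z-test criterion at small $n$,
  not an implementation artifact.
* Genes with a missing value in either compared condition are in neither
  set; the Z test additionally skips (and counts) genes with fewer than two
  replicates or zero standard error.

## Numerical choices

* The tail probability is computed as a survival summation in log space over
  `dhyper(·, log = TRUE)` terms. The naive $1-\sum_{i<x}\mathrm{pmf}$ form
  cancels catastrophically when the tail is small; it is used only as an
  independent cross-check at universe sizes ≤ 25, where enumeration is exact
  in double precision. A second independent route (`phyper`'s survival
  function) is cross-checked in the tests up to $N = 10^5$; the
  implementation itself never calls it.
* All significance comparisons are strict (`p < threshold`), and the probe
  filter removes only probes whose missing fraction is *strictly greater*
  than the cutoff — a probe missing in exactly 80% of samples survives the
  default filter.
* Duplicate-probe collapse keeps the probe measured in the most samples;
  ties break deterministically to the lowest input row index, so a re-run on
  a re-ordered file is the only way to change the outcome.
* The up and down sets of the same tissue-phase are disjoint by construction
  and are never tested against each other: the forced $x = 0,\ p = 1$
  outcome would only add noise edges to degree counts. Pairs involving an
  empty set are untested rather than reported at $p = 1$, and empty sets
  therefore surface as stochastic (isolated) nodes.
* Pair order does not matter (the statistic is symmetric in $M, K$), so the
  networks test unordered pairs; up–down and down–up combinations of two
  tissues are distinct unordered pairs and are both tested.

## Node categories on the four-dimensional map

The four descriptive outcomes of a 4D analysis overlap (a node can
simultaneously persist in its own tissue and recur elsewhere), so
`classify_4d_nodes()` uses a mutually exclusive precedence, from the classes
of a node's incident edges:

1. no edges → `specific`;
2. edges only within its own tissue → `tissue-specific-temporal`;
3. same-tissue edges plus cross-tissue edges confined to the node's own
   phase → `temporal-associated` (temporally persistent, only
   contemporaneous spatial partners);
4. anything with a cross-tissue cross-phase edge, or cross-tissue edges
   without same-tissue persistence → `spatio-temporal-associated`.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates log2 expression with a per-gene baseline
$\mathcal{N}(8, 1)$ shared across tissues (the magnitude of typical
MAS5-style log2 signals; the overlap statistics are location/scale-free
after calling, so this choice is cosmetic realism), replicate noise
$\mathcal{N}(0, \sigma)$ i.i.d. per measurement, uniform (MCAR) missingness,
and planted modules: a block plants, within one phase, a gene module of a
given size per tissue, a fraction `overlap` of which is shared by all
tissues of the block. Directions per tissue make the shared genes a true
synchronous (same direction) or asynchronous (opposite direction) pair.
Shifts are steps of `effect_size` (default 1.5 log2 units) at the phase
boundary that persist afterwards, so a block is detectable only in its own
phase. A single seed governs everything; identical seeds give bit-identical
datasets and truth records.

Defaults: `noise_sd = 0.2` and `effect_size = 1.5` — a clearly-detectable
planted change against modest replicate noise, the regime the
planted-recovery tests exercise (200-gene modules, overlap 0.5).

The simulator does **not** emulate probe-level array structure, batch
effects, correlated (non-MCAR) missingness, gene–gene correlation outside
planted modules, or heavy-tailed noise. Passing calibration and recovery
tests therefore certifies the statistical machinery under its own null and
alternative — it does not certify robustness to those real-data features.

### Study conditions used by the test suite

* *Null calibration*: 200 structureless simulations of 10,000 genes ×
  5 tissues × 4 ages, pooled (1 replicate) with `noise_sd = 1.0`, fold-change
  detection, threshold 0.005; the fraction of tested pairs below threshold is
  compared with the nominal level within 3 binomial standard deviations. The
  high noise is deliberate: it makes the null change sets large (~20% of the
  universe per direction), so the attained level of the *discrete* test sits
  close to nominal. With realistic small sets the test is strongly
  conservative (the attained level of a discrete tail test is bounded above
  by, and can sit far below, the nominal one) and a calibration measurement
  would measure discreteness, not correctness.
* *Planted recovery*: 100 replicates, 10,000 genes, effect 1.5, 200-gene
  modules, overlap 0.5, noise 0.2; mean recall of planted synchronous and
  asynchronous edges must reach 0.95.
* *Trajectory*: 100 runs of a three-phase plan (sync-rich, async-rich,
  empty) at 4,000 genes with 3 replicates per condition — the replicated
  design keeps null fold-change calls numerically negligible, so the final
  phase's emptiness reflects the plan, not luck; ≥ 95 runs must show
  sync > async, then async > sync, then zero edges.

These sizes keep the whole suite within a few minutes on one CPU while
leaving the binomial error bands meaningfully narrow.

## Known limitations

* The Z-test criterion is anticonservative below ~20 replicates (see above);
  with 3–5 replicates, realized per-tail rates run 2–2.5× nominal.
* Raw (uncorrected) thresholds mean edge counts grow with the number of
  tested pairs; compare networks only at matched thresholds and universes.
* Tests within a phase share node sets, so edge indicators are dependent;
  calibration statements hold at the per-test marginal level only.
* The fold-change rule on linear-scale data requires strictly positive
  values; non-positive entries are treated as missing for that comparison.
* With pooled designs nothing estimates within-condition variance, so
  fold-change calls carry no per-gene error control at all — threshold
  choice is the only knob, as in the original pooled-array analyses.
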