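---
title: "Methods: composite-index DNB detection on stage-ordered expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite-index DNB detection on stage-ordered expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `dnbr`, the design
choices made where the methodology is genuinely open, the synthetic data
the package validates itself against, and the limits of what those
validations show.

## The model

Dynamic network biomarker (DNB) theory describes a system approaching a
critical transition: a small dominant module of variables begins to
fluctuate strongly and coherently while decoupling from the rest of the
system. For a gene module $M$ of size $m$, a stage $s$ with case samples
$d = 1 \dots n_s$, and a pool of reference samples, the package computes

$$\mathrm{SD}_{in}(M,s) = \frac{1}{m\,n_s}\sum_{g \in M}\sum_{d}
  \lvert x_{gd} - \bar x_g \rvert,$$

where $\bar x_g$ is gene $g$'s mean over the reference samples;

$$\mathrm{PCC}_{in}(M,s) = \binom{m}{2}^{-1}
  \sum_{\{g,h\} \subset M} \lvert r_{gh} \rvert, \qquad
  \mathrm{PCC}_{out}(M,s) = \frac{1}{m\,b}\sum_{g \in M}\sum_{h \notin M}
  \lvert r_{gh} \rvert,$$

with $r_{gh}$ the Pearson correlation over the stage's case samples and
$b$ the number of background genes; and the composite index

$$\mathrm{CI}(M,s) = \frac{\mathrm{SD}_{in} \cdot \mathrm{PCC}_{in}}
  {\mathrm{PCC}_{out}}.$$

Assumptions worth making explicit: expression is on the log2 scale;
the reference pool defines the baseline for every stage (deviations are
not stage-matched); the module is a single coherent unit (no substructure
is modelled); and correlations are estimated from the stage's case
samples alone, because the rising-correlation and decoupling conditions
describe the perturbed system, not the baseline.

Three points were open in the underlying methodology and were decided
here:

* **Reference samples** are the non-case (normal) pool, the natural
  reading of "average expression in the reference samples".
* **Aggregation of SD_in**: the printed deviation statistic scores a
  single sample; the package averages $\lvert x_{gd} - \bar x_g\rvert$
  over both module genes and the stage's case samples. An optional
  `sd_normalize` flag divides by the per-gene reference standard
  deviation (the classical differential-SD form); default off, honoring
  the plain absolute-deviation definition.
* **Degenerate correlations**: a zero-variance profile has undefined
  correlation; it is defined as 0 with a warning. A vanishing
  $\mathrm{PCC}_{out}$ is floored at $\varepsilon = 10^{-6}$ (with a
  warning) rather than raising a division error; the floor only binds on
  pathological fixtures.

## Critical-stage detection

The critical (pre-transition) stage is the stage $s^\*$ maximizing the
forward difference $\mathrm{CI}(s+1) - \mathrm{CI}(s)$, ties resolved to
the earliest stage — i.e. the stage at which the sharp rise of the score
*begins*, not the stage holding the peak. On the canonical four-stage
colorectal trajectory (0.4238, 0.1477, 0.0923, 0.6479) this designates
stage III as critical with the peak at stage IV, matching the published
designation of stage III as the pre-transition state even though stage IV
holds the maximum. When every forward difference is negative the
trajectory never rises; the result is flagged `no_transition` and the
least-negative stage is returned. Both the critical and the peak stage
are reported in the fitted object.

## Module search

The search procedure (the least-specified part of the methodology) is
deliberately simple and fully deterministic given the data:

1. per stage, genes are ranked by mean absolute deviation from their
   reference means and the top `top_k` (default 200) retained;
2. average-linkage hierarchical clustering on $1 - \lvert r \rvert$ over
   the stage's case samples; every internal dendrogram node with size in
   `[min_size, max_size]` (defaults 10–50) is a candidate module;
3. every candidate is scored by CI at its stage; the winner's full
   trajectory is rescored and the critical stage detected.

Two robustness choices matter and are exposed as parameters:

* **Near-tie resolution (`ci_tol`, default 0.05).** Nested candidates
  from one dendrogram branch score within sampling noise of each other: a
  small subcluster trades a slightly higher within-module correlation
  against a slightly higher out-correlation, and with ~20 case samples
  per stage these differences are a few percent — pure estimation noise.
  A strict argmax therefore often returns an arbitrary fragment of the
  true module. Instead, among all candidates within `ci_tol` of the
  maximal CI the *largest* wins (then higher CI, then lexicographic gene
  order), generalizing the natural "ties go to the larger module" rule to
  the noise scale of the statistic. Setting `ci_tol = 0` restores the
  strict argmax.
* **Minimum size (default 10).** The CI of a module selected by
  clustering is upward-biased, and the bias grows as modules shrink
  (fewer averaged correlation pairs, selected for tightness). Very small
  high-variance clusters can outscore genuine modules; a floor of 10
  genes removes that degenerate family while staying well below the size
  of modules of practical interest (tens of genes).

## Differential expression

Per stage, each gene's case samples are tested against the reference pool
with a Welch unequal-variance $t$ (Satterthwaite degrees of freedom),
written in closed form so the degenerate cases have fixed conventions:
two constant equal groups give $p = 1$; constant unequal groups give an
infinite statistic with $p$ guarded at $10^{-300}$. This is a deliberate,
documented departure from the moderated linear-model fit often used at
this step: with ~20 samples per group the moderation gain is modest, and
the Welch test makes no shared-variance assumption. False discovery rate is
controlled by Benjamini–Hochberg across genes within a stage (the
procedure is not named in the underlying methodology; BH is the standard
choice). Calls use the two thresholds FDR < 0.05 and |log2FC| > 2.0
(4-fold), with log2FC the difference of group means on the log2 scale.
Counts of up/down calls are reported per stage; they are schema, not
calibrated quantities, because the test statistic differs from the
original moderated fit.

## Co-expression stage

The unsigned weighted network is $a_{gh} = \lvert r_{gh}\rvert^\beta$.
The soft power is scanned (default 1–12) and chosen as the smallest
$\beta$ whose signed scale-free fit index reaches 0.90; the fit index
bins connectivities into 10 equal-width bins and regresses log10 mean
frequency on log10 bin-mean connectivity, returning
$-\mathrm{sign}(\mathrm{slope}) \cdot R^2$. If no power reaches the
target the best-fitting power is used with a warning. Topological overlap
follows the standard form
$\omega_{gh} = (\sum_u a_{gu}a_{uh} + a_{gh}) / (\min(k_g,k_h) + 1 - a_{gh})$.

Modules come from average-linkage clustering of $1-\omega$ with a
**static cut**, replacing dynamic tree cutting (whose parameters are not
published for the workflow this package implements). The default cut
height is 99% of the maximal merge height — just below the top of the
dendrogram. The rationale: unrelated genes merge only near dissimilarity
1, while genes sharing a factor merge far lower, so a cut just under the
top separates every coherent branch without fragmenting it *regardless of
the proportion of module genes in the matrix*. Quantile-based cuts (e.g.
the lower quartile of merge heights) behave well only when module genes
are rare; when they dominate, the quantile falls inside the within-module
merge range and shatters the modules. Clusters below `min_module_size`
are labelled `grey`; module names follow the conventional color sequence
by decreasing size. Eigengenes are the unit-variance first principal
component of the gene-standardized module submatrix, oriented to correlate
positively with the member profiles on average; module–trait correlations
use the ordinal stage code 1…4 (the coding is a choice; any strictly
increasing coding gives the same ranking up to monotone effects) with the
usual $t$-transform $p$-value on $n-2$ degrees of freedom.

In the recovery experiments the network is built at the canonical
unsigned power $\beta = 6$. On mostly-independent synthetic matrices no
power reaches the scale-free target, and the fallback (argmax of a noisy
fit index) drifts to extreme powers that erase weak modules;
`pick_power()` is therefore validated on scans where the target is
attainable, and module recovery is assessed at the standard power.

## Hub centralities

Twelve node scores in the cytoHubba tradition, with the conventions
pinned down so rankings are reproducible: distance-based metrics
(closeness, eccentricity, radiality, stress, betweenness) are computed
within connected components, excluding cross-component pairs; MNC is the
order of the largest connected component of the open neighborhood and
DMNC divides its edge count by that order to the power 1.7 (the exponent
is the convention of the original tool, not re-derived here); MCC sums
$(|C|-1)!$ over maximal cliques containing the node, which reduces to the
degree when the node lies only in 2-cliques; bottleneck builds one
shortest-path tree per root — parents resolved deterministically to the
smallest-id neighbor one level up — and counts roots for which the node's
subtree holds at least a quarter of the component; EPC is Monte-Carlo
edge-percolation connectivity (default 1000 trials, edge retention 0.5,
fixed seed), the only stochastic metric, reproducible given its seed.
Every ranking breaks score ties by ascending node id, making top-$k$
consensus sets deterministic.

## The synthetic generator

`simulate_dnb_data()` draws $x_{gd} = \mu_g + \sigma\varepsilon_{gd}$
with $\mu_g \sim U(5, 10)$, $\sigma = 1$, independent Gaussian noise —
log2-scale-like backgrounds — and plants three structures in the case
samples only:

* **DNB module** (default 20 genes): $x = \mu_g + \lambda(s) f_d +
  \tau(s)\sigma\varepsilon$, one shared standard-normal factor $f_d$ per
  sample (rank-1 correlation), so within-module correlation is
  $\lambda^2 / (\lambda^2 + \tau^2\sigma^2)$ and rises with the loading
  while correlation to the background stays 0 in expectation. The default
  schedule $\lambda = (0.3, 0.5, 0.7, 2.5)$ with tipping stage $t^* = 3$
  and $\tau \equiv 1$ keeps the module quiet through stage III and lets it
  explode between III and IV — the canonical pre-transition picture (low
  scores early, sharp rise beginning at the critical stage, peak at the
  final stage), and the configuration the forward-difference detector is
  designed for. A schedule that jumps *at* $t^*$ instead would shift the
  detected onset one stage earlier, which is the detector working as
  specified, not failing.
* **DE genes** (default 40, half up / half down at $|\Delta| = 3$ log2
  units): constant mean shift in all case samples.
* **Trait module** (default 15 genes, $\gamma = 1$): loading on the
  centered ordinal stage code, giving an eigengene correlated with stage
  but, within any single stage, no extra correlation.

Defaults are desk-scale study conditions: 500 genes, 4 stages × 20 case
samples, 20 reference samples. All draws derive from one seed, and the
draw order is independent of the parameter *values*, so two specs
differing only in $\lambda$, $\tau$, $\Delta$ or $\gamma$ share noise
realizations — which is what makes the per-seed monotonicity experiment
(CI at $t^*$ as a function of $\lambda(t^*)$) clean.

What the generator does **not** emulate: probe-level microarray noise,
batch effects, count-distributed sequencing data, correlated backgrounds,
multi-factor module structure, or missingness. Passing the recovery
suites therefore shows the estimators work under the theory's own
generative assumptions at realistic sample sizes — not that they are
robust to the artifacts of any particular platform.

## Validation problem sizes

The test suite checks every closed-form statistic against independent
brute-force enumeration (exact for integer-valued graph metrics, 1e−12 /
1e−9 otherwise, on fixtures of ≤ 10 genes and ≤ 8 nodes), and runs the
recovery experiments at the default study conditions: 50 seeds for module
and critical-stage recovery (criterion: Jaccard ≥ 0.7 and detected stage
= $t^*$ in ≥ 90% of seeds), 20 seeds × a 5-point loading grid for
monotonicity, 50 seeds each for the differential-expression power/null
characteristics and for trait-module ranking, and full pipeline reruns
for byte-identical manifests. These sizes keep the whole suite in the
tens of seconds while leaving the pass thresholds far from the observed
operating points.

## Known limitations

* The module search scans one dendrogram per stage; modules that never
  cohere at any single stage are invisible to it.
* CI values are comparable across stages of one fit, not across datasets;
  no null distribution is attached to the reported maximum (a label
  permutation, as used in the test suite, is the recommended ad-hoc
  check).
* The co-expression stage implements a deliberately small subset of the
  full weighted-network toolbox (no module merging, no signed networks,
  no blockwise decomposition).
* With an even number of stages and a trajectory that rises twice, the
  forward-difference rule reports only the steepest onset.
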