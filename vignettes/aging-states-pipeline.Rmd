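---
title: "Methods: four-state aging trajectories from single-cell counts"
author: "scAgeStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-state aging trajectories from single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scAgeStates)
```

This vignette explains the models behind each stage of the package, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design choices made where the methodology was genuinely
open. Everything quantitative shown here is computed by the package's own
test suite or by `scripts/acceptance.R`; the vignette states no empirical
result beyond those.

## The model

Cells of a stem-cell-enriched epithelial population are assumed to occupy
positions on a one-dimensional latent aging axis $t \in [0,1]$. Four
discrete states partition the axis at three boundaries
$b_1 < b_2 < b_3$: active young (a-Young), quiescent young (q-Young),
early senescence (e-Sen) and late senescence (l-Sen). Chronological age
does not determine a cell's state; it shifts the *mixture*: the a-Young
share falls and the l-Sen share rises with age. Gene programs respond to
$t$ in six characteristic dynamic patterns — (1) gradual decline across
the whole course, (2) a peak in state 2, (3) a peak in state 3 with a
sharp drop in state 4, (4) a rise into state 3 that plateaus through
state 4, (5) a continuous rise through states 3 and 4, and (6) late
activation confined to state 4.

The analysis recovers this structure from a UMI count matrix: order the
cells (pseudotime), find the genes that move along the ordering, cluster
their standardized curves into four groups, and cut the axis where the
cluster-average curves intersect — each state is the interval where one
gene program dominates.

## Quality control and normalization

Four cell-level rules run in one pass (a cell must pass all): per-batch
barcode whitelist (top `barcode_top_n = 100` barcodes by total reads,
standing in for read-level whitelisting), ERCC fraction ≤ 0.10,
mitochondrial fraction ≤ 0.05, detected genes in [200, 6000], and all
four stromal markers (*Pecam1*, *Ptprc*, *Lyve1*, *Col1a1*) at most 0.1.
The stromal cutoff is interpreted on the log-normalized scale
(`ln(1 + count/total × 10^4)`), since 0.1 is not meaningful for integer
counts. Genes must be detected in ≥ 10 of the *surviving* cells (the gene
filter runs after the cell filters; the reverse order is a one-flag
change away since detection counts are recomputed from whatever matrix is
passed). Normalization is natural-log with scale factor 10,000.

Covariate regression replaces each gene with its OLS residuals against a
per-cell design (intercept included, factors one-hot encoded,
rank-deficient columns dropped with a warning). Residuals are returned
centered, so a constant covariate reduces regression to centering.

Two regression choices differ from common habit and deserve their
rationale:

* **Cell cycle is regressed as the *called phase*, a factor, not as phase
  scores.** Phase effects on expression are close to on/off. A linear
  regression on two continuous scores leaves most of that discrete
  structure in the residuals, and the trajectory step then latches onto
  it; the factor design removes it cleanly. Phases are called on
  unregressed data first (a fixed two-pass order breaks the circularity
  between cycle scoring and regression).
* **ERCC fraction, mitochondrial fraction, detected-gene count and batch
  are *not* regressed by default** (flags exist). In a population whose
  transcriptome composition changes along the axis of interest, these
  quantities are partly biological: when late programs switch on, totals
  rise and the spike-in *fraction* falls, so "removing the ERCC effect"
  removes aging signal. Batch is additionally nested within age group in
  the designs this package targets, where a batch factor would absorb the
  age contrast itself.

## Pseudotime

PCA (10 components by default) on the 500 most variable genes, then a
density-normalized Gaussian-kernel diffusion map on the embedding, then
projection onto a principal curve (iteratively smoothing each embedding
coordinate against the current ordering and re-projecting onto the
fitted curve's arc length). Two choices here are deliberate:

* **The diffusion component is selected by age separation, not by rank.**
  The leading diffusion component is whatever structured variation is
  largest — before regression that is routinely the cell cycle. Among the
  top five components the package takes the one with the largest $R^2$
  against chronological age group, which is observed metadata and is what
  an *aging* trajectory must separate. With cycle structure regressed out
  the choice almost always coincides with the first component.
* **Pseudotime is reported as the normalized rank along the curve.** A
  1-D latent coordinate is identified only up to monotone transforms;
  arc-length units depend on expression geometry. The quantile convention
  makes $t$ comparable across runs and maps a uniform latent population
  onto a uniform $[0,1]$.

Orientation follows the rooting rule: the configured root age group (the
youngest, by default) must have lower mean $t$ than the oldest group.
Fewer than 50 cells, or a disconnected k-nearest-neighbor graph, is an
error, not a silent answer.

## Pseudotime-dependent genes, curves, clusters, states

The gene test is a Gaussian likelihood-ratio test of a natural cubic
spline in $t$ (3 df) against an intercept, $\chi^2(3)$, BH-corrected,
selection at $q < 0.05$. Constant genes get $p = 1$ by definition. Its
type-I error is verified by simulation in the test suite (fraction of
null genes with $p < 0.05$ within $0.05 \pm 0.02$).

Selected genes are smoothed on a 100-point grid, clamped at zero,
transformed with $\log_{10}(x+1)$, standardized per gene across the grid,
and truncated to $[-3, 3]$. The smoothing spline uses 6 df: the curve
families this stage must track (logistic ramps, peaked bumps) are
systematically distorted by a 3-df natural spline, which shifts the
cluster-curve crossing points — and therefore the state boundaries —
about 0.03 low even on noise-free input. The standardization step exists
because a ±3 clamp is only meaningful on a standardized scale
($\log_{10}(x+1)$ is non-negative).

Gene curves are clustered with Ward linkage (Euclidean distance,
`ward.D2`, cut at $k = 4$); the merge sequence is verified against a
naive $O(n^3)$ Lance-Williams oracle in the tests. State segmentation
labels every grid point with the argmax cluster-average curve, smooths
the label sequence with a 5-point majority filter (widened automatically
up to 21 if micro-runs persist; runs shorter than 3 points merge into
their larger neighbor), and requires exactly four runs with distinct
clusters — otherwise it errors and suggests re-clustering. "Intersecting
point" is implemented as the argmax changeover; when each cluster
dominates one interval this coincides with the pairwise crossing of
consecutive cluster curves.

## Scoring

**Module scores.** Genes are ranked by mean expression and split into
24 equal-frequency bins; for each set gene, 100 control genes are drawn
without replacement from its bin; the score is mean(set) − mean(pooled
unique controls) per cell. The draw is seeded and the CLI-style surface
requires the seed, because a stochastic score that cannot be reproduced
is not a score. The tests check the score against a direct two-mean
recomputation at $10^{-12}$ and verify shift invariance.

**Cell cycle.** Expression is converted to $\log_2(\mathrm{TPM}+1)$
(equal effective lengths for UMI data, so TPM is counts-per-million).
Per phase, genes correlated at $\rho \ge 0.25$ with the phase-average
profile are retained, with two refinement rounds (average → filter →
re-average); the round count is a fixed convention since a single
sentence "filter by correlation with the average" does not pin down
iteration. Phase scores are z-scored across cells; cells with
z(G1/S) < 0 and z(G2/M) < 0 are G0, all others take the argmax phase.

**Pathway dynamics.** Module score per cell → spline smoothing over $t$
→ means within the four state intervals → range normalization to [0,1]
→ classification with tolerance $\varepsilon = 0.1$. The six pattern
rules (precedence 6, 4, 5, 3, 2, 1; flat profiles unclassified) are an
operationalization of qualitative descriptions: e.g. pattern 4 requires
both late states high with $|a_3 - a_4| \le \varepsilon$ (plateau);
pattern 5 requires $a_4 > a_3 > a_2$ with a ≥ 3ε climb. The classifier
is total: every 4-tuple maps to exactly one label or "unclassified".

**Paired comparison.** Pathway score = mean expression of set genes per
sample; two-sided paired t-test. All-zero differences give $t = 0,
p = 1$; constant non-zero differences trip a zero-variance guard that
reports $p$ below machine epsilon with a flag instead of an undefined
statistic.

## TF regulons

Enrichment of a TF's target set in a state's gene cluster is an
upper-tail hypergeometric test (`phyper`), BH-adjusted within source
across TFs, with a TF "reliable" when supported at $q < 0.05$ by at
least two sources. The default universe is the expression-matrix gene
list supplied with the database; intersecting the universe with each
source's own target coverage is available as `universe_mode =
"per_source"` for sparse curated sources. TF activity over pseudotime is
the module score of the union of the TF's targets across sources.

For a repressor with measured binding targets, WT and KO cells give a
per-gene two-sided rank-sum test; significant genes split into
positively regulated (KO < WT) and negatively regulated (KO > WT),
intersected with the binding targets. Repressor activity is the weighted
average expression of the negatively regulated targets, sign-flipped so
that strong repression reads as high activity. Weights are either
uniform or the absolute standardized rank-sum statistics ("weighted
average" admits both; both are shipped, neither asserted as canonical).

## Signaling entropy

An unweighted co-expression network connects genes with Pearson
$r \ge 0.3$ (threshold exposed; absolute-vs-positive correlation is a
convention, positive here), restricted to the largest connected
component. For a cell with expression $x$ on the network genes, the
random walk $P_{ij} = A_{ij} x_j / (Ax)_i$ has stationary distribution
$\pi_i \propto x_i (Ax)_i$ (exact for this reversible chain — no
iterative solver), local entropies $S_i = -\sum_j P_{ij} \ln P_{ij}$,
entropy rate $SR = \sum_i \pi_i S_i$, and normalization by
$\ln \lambda_{\max}(A)$ bounds the result at 1. Exact zeros are replaced
by $10^{-3}$ times the smallest positive entry, since the walk is
undefined at zeros. The closed form on a 3-node path with uniform
expression ($SR = \tfrac12\ln 2$, normalized 1) and the $\pi P = \pi$
identity on random graphs anchor the tests. The network is fit on a
reference (wild-type aging) dataset and frozen before application to
perturbed cells.

## Limiting dilution

Under the single-hit model a well at dose $d$ is positive with
probability $1 - e^{-fd}$. The MLE of $\log f$ comes from a binomial GLM
with complementary log-log link, offset $\log d$ and slope fixed at 1;
the 95% CI is Wald on the log scale (the field's reporting convention,
"1 in N (lower–upper)"). All-negative or all-positive tables sit on the
likelihood boundary: the package flags them and reports an exact
one-sided 95% bound from the binomial likelihood rather than a silent
infinite N. Group comparison is a likelihood-ratio $\chi^2$ with
(groups − 1) df; if any group is on the boundary the GLM is replaced by
direct profile maximization with a warning. Wald-CI coverage at
$f = 1/500$ is measured over 1000 simulations in the acceptance run and
lands in the nominal band.

## The synthetic generator

The generator is the package's test bed and defines its study
conditions: 4 age groups (3, 12, 17, 25 months), 200 cells each, 1500
genes, negative-binomial counts with dispersion $\theta = 10$ and
log-normal library factors (sd 0.3), 3% spike-in and 2% mitochondrial
count shares, 5 stromal contaminants, 360 pattern genes (60 per
pattern), cell-cycle programs sized like the retained phase-gene lists
(14/13/21/19/13), and a phase mixture with 30% G0.

Choices worth recording:

* **State boundaries** sit at $t = 0.25/0.55/0.85$ — a convention, since
  a latent scale has no observable geometry; it makes state 3 widest, in
  line with it holding the most cells. The default age mixtures drift as
  the data demand (a-Young falls, l-Sen rises) and *pool* to the interval
  widths, so the pooled population is uniform on the axis and the
  normalized-rank pseudotime is directly comparable to the truth scale.
* **Pattern curves** are logistic ramps (patterns 1, 4, 5) and Gaussian
  bumps (2, 3, 6) whose centers and widths are calibrated, noise-free,
  so the standardized cluster-average programs change dominance exactly
  at the configured boundaries. Without that calibration the generator's
  own `state_true` contradicts the "intersecting curves" definition of a
  state that the inference implements.
* **Cell cycle** is modeled as a cycle: a phase's program activates fully
  in its own phase, at 0.45 of the log-effect in the two adjacent phases,
  and is *repressed* (−0.3) in G0 cells — quiescent cells shut cycling
  programs down rather than idling at baseline. The repression is what
  makes the two-negative-score G0 rule well-posed.
* **Confounds are real**: spike-ins have constant means (so their
  *fraction* anti-correlates with latent age), contaminants express the
  stromal markers, KO cells de-repress a planted target set and sit late
  on the axis.

What the generator does **not** emulate: batch effects on expression
(batch labels exist but are clean), doublets, ambient RNA, dropout
beyond NB sampling, branching trajectories, read-level artifacts.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under honest noise — not robustness to every artifact of
real droplet data.

## Problem sizes and runtime choices

The suite runs the full default simulation (800 cells + contaminants,
1500 genes) once in the acceptance tests and smaller instances (400
cells, 1000 genes) in unit tests; the limiting-dilution coverage study
uses 1000 replicates; the TF consensus property runs 50 database seeds.
These sizes were chosen so the complete suite finishes in about a
minute on a laptop-class single core while keeping every statistical
check adequately powered.

## Known limitations

* The trajectory is strictly linear; populations with genuine branching
  need a tree method upstream, after which the state segmentation can be
  applied per path.
* The pattern classifier inherits its tolerance $\varepsilon$; profiles
  near rule borders are sensitive to it (it is a config argument).
* The diffusion map is dense ($O(n^2)$ memory in cells); tens of
  thousands of cells would need a sparse-kernel variant.
* Boundary recovery assumes the pooled population covers the whole axis
  reasonably evenly; a cohort missing an entire state can only return
  three dominated intervals, which the segmentation reports as an error
  rather than inventing a boundary.
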