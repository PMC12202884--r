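---
title: "Cell-specific causal network inference: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-specific causal network inference: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicnet)
```

## The problem

Gene regulatory network (GRN) inference from single-cell RNA-seq usually
produces one network per dataset or per cluster, discarding the
cell-to-cell variation that is the whole point of single-cell assays. The
estimator in this package produces a **directed network for every
individual cell**, and then turns those networks into a matrix
representation (the network outdegree matrix, ODM) that any standard
scRNA-seq pipeline can consume in place of the expression matrix.

## The model

### Reference causal network

Candidate regulatory relationships are restricted to a score-filtered
protein--protein interaction (PPI) background (by default edges with
STRING combined score below 700 are removed; 700 itself is kept). For a
target gene $g$ with background neighbours $g_1, \dots, g_n$, two linear
models are compared for every candidate cause $g_i$:

$$g = \sum_{j=1}^{n} \alpha_j g_j + \varepsilon_1
\qquad\text{and}\qquad
g = \sum_{j \ne i} \beta_j g_j + \varepsilon_2,$$

where $\varepsilon_1$ and $\varepsilon_2$ are cross-validated
root-mean-square prediction errors: cells are split into 5 nearly equal
random folds, each model is fit on 4 folds and evaluated on the held-out
fold, and the per-fold RMSEs are averaged. The **causal strength index**

$$\omega(g_i \to g) = \ln \frac{\varepsilon_2}{\varepsilon_1}$$

is positive exactly when removing $g_i$ worsens held-out prediction of
$g$, which is read as evidence for the edge $g_i \to g$. Every gene takes
its turn as target, so both orientations of each PPI pair are evaluated
independently. Positive-$\omega$ edges form the *reference causal
network*.

Cross-validation is what makes the sign of $\omega$ meaningful: on
training error, dropping any regressor can only increase the residual, so
$\omega$ would never be negative. On held-out error an uninformative
regressor *inflates* the expected loss, so useless candidates come out
with $\omega < 0$ most of the time. The package's null-calibration checks
confirm this: with all true coefficients zero, the mean $\omega$ across
candidates is negative and no candidate direction fires in as many as
half of repeated draws.

### Cell-specific networks

The reference network fixes, for each target, its parent set. The full
and leave-one-parent-out models are then refit once on **all** reference
cells (the CV folds above exist only to estimate the errors robustly, not
to produce the predictors), and those frozen predictors are applied to
each individual cell of the objective dataset. With a single observation
the RMSE degenerates to the absolute residual, so for cell $k$:
$\varepsilon_1^c = |g^c - \hat g_{\text{full}}|$,
$\varepsilon_2^c = |g^c - \hat g_{\text{reduced}}|$, and the edge is
present in cell $k$ iff $\ln(\varepsilon_2^c / \varepsilon_1^c) > 0$.
Cell networks are therefore always edge-subsets of the reference network.

### Binarization and the ODM

Networks are binarized (edge weight 1 iff $\omega > 0$) and each cell's
network is collapsed to a column of outdegrees: entry $(g, k)$ of the ODM
is the number of targets gene $g$ regulates in cell $k$'s network. The
ODM has exactly the shape of the expression matrix, so clustering,
embedding, and trajectory tools can run on it unchanged. ODMs from
different conditions can be concatenated along the cell dimension when
their gene lists agree.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_score` | 700 | STRING combined-score cutoff (0--1000 scale) for the background. |
| `folds` | 5 | CV folds for the reference-error estimates. Fewer folds → noisier errors; more folds → smaller validation sets. |
| `intercept` | `TRUE` | Fit regressions with an intercept. The literal model equations carry no intercept term; since expression is not mean-centered, fitting one is the safer default, and `intercept = FALSE` reproduces the intercept-free form. |
| `omega_max` | 50 | Cap on $|\omega|$ when one error is exactly zero (a log-ratio singularity). Any value far above observed $\omega$ magnitudes (typically $< 5$) behaves identically. |
| `scale_factor` | $10^4$ | Per-cell library-size target before `log1p`. The regressions assume roughly homoskedastic, continuous expression; library-size scaling plus `log1p` is the standard way to get there from counts. Pre-normalized matrices can skip this step. |
| `prevalence_cutoff` | 0.70 | Consensus networks keep edges present in at least this fraction of a cluster's cells; the boundary value is kept. |
| `alpha` | 0.05 | FDR threshold for the differential-regulator and edge-activity tests. |

## Numerical choices

- **Solver.** All regressions use least squares with a tiny trace-scaled
  ridge term ($\lambda = 10^{-6}\,\mathrm{tr}(X^\top X)/p$). This keeps
  rank-deficient designs — duplicated or collinear regulators, hub genes
  with more neighbours than training cells — solvable and deterministic
  while being numerically invisible for well-conditioned problems.
- **Log-ratio singularities.** $\varepsilon_1 = 0,\ \varepsilon_2 > 0$
  gives $\omega = +50$ (edge present); both zero gives $\omega = 0$ (no
  evidence, edge absent); $\varepsilon_2 = 0,\ \varepsilon_1 > 0$ gives
  $-50$, keeping $\omega$ antisymmetric in its arguments.
- **Fold assignment.** One seeded shuffle of the cells is shared by all
  targets, so the whole reference network is reproducible from a single
  integer seed, and $\varepsilon_1$ is computed once per target and
  reused across its candidate causes (the full model does not depend on
  which candidate is excluded).
- **Tie-breaks.** Neighbour lists and regulator rankings break ties
  lexicographically; gene identifiers in the simulator are zero-padded so
  lexicographic and numeric order coincide.

## Downstream statistics

- *Differential regulators*: per-gene two-sided Student's (pooled
  variance) $t$ test on ODM rows between two groups, Benjamini--Hochberg
  FDR across genes. Genes constant in both groups are recorded with
  $p = 1$, never dropped.
- *Edge activity tests*: per reference edge, a 2×2 chi-square test
  (active/inactive × group) with Yates continuity correction — the
  standard default for 2×2 tables — and BH-FDR across edges. An
  "up-regulated link" is a significant edge whose active rate is higher
  in the target condition; directionality is a post-hoc filter on a
  two-sided test, not a one-sided test.
- *Consensus networks*: per cluster, edges kept at prevalence ≥ cutoff.
- *Activity curves*: a regulator's outdegree along an externally supplied
  cell ordering (e.g. a pseudotime rank), smoothed by a centered moving
  average with shrunken windows at the ends. The moving average was
  chosen as the assumption-light, dependency-free smoother; anything
  fancier can consume the raw series. Orderings are inputs — the package
  never infers trajectories.
- *Clustering agreement*: ARI, AMI, NMI and FMI implemented directly from
  their contingency-table definitions, with natural logarithms, the exact
  hypergeometric expected mutual information, and — deliberately — the
  **maximum** of the two entropies as the AMI normalizer (several
  libraries default to the arithmetic mean; the max form is what this
  package implements and tests). Degenerate conventions: two trivial
  partitions compare as 1; pair-based indices return 0 when no pair is
  clustered together.

## What the simulator emulates, and what it does not

`simulate_grn()` + `simulate_expression()` generate a random DAG with
coefficients of magnitude in $[0.8, 1.5]$ and random sign, embedded in a
background of the true skeleton plus distractor pairs, and draw cells
from the linear--Gaussian structural equation model: root genes are
standard normal, every other gene is its coefficient-weighted parent sum
plus $\mathcal N(0, 0.2^2)$ noise. Group-wise knockouts zero chosen edge
coefficients for the cells of one group. These defaults — 50 genes, 30
edges, 60 distractors, 300 reference cells in the headline recovery
experiment; 100 cells per condition in the knockout experiments — are the
problem sizes the test-suite and the acceptance script use.

The simulator deliberately matches the estimator's model class, so
recovery results measure the implementation, not model mismatch. It does
**not** emulate count noise, dropout, library-size variation, cyclic
regulation, or time dynamics; passing tests on it therefore show the
machinery is correct, not that the linear, steady-state assumption holds
for any particular real dataset.

## Known limitations

- **Orientation.** $\omega$ is a conditional-dependence statistic. In a
  linear--Gaussian system a child gene genuinely improves prediction of
  its parent, so the reversed orientation of a true edge also tends to
  receive $\omega > 0$; with strong signal the inferred network contains
  most true edges *and* many of their reversals. Directed recall is
  excellent (measured 1.0 on the headline scenario) while directed
  precision sits near 0.35 — close to the ceiling implied by symmetric
  detection plus the null firing rate of distractors. Users should read
  edge direction as "regulatory association anchored at the target's
  neighbourhood", not as a resolved causal arrow; orientation competition
  between the two directions of a pair is a possible extension, not
  implemented because it changes the published decision rule.
- The linear models are steady-state: feedback loops and time-lagged
  regulation are out of scope.
- The per-cell decision is a single-observation comparison and is
  correspondingly noisy at the individual-edge level (per-cell agreement
  with a known generating condition measures ≈ 0.85–0.89 at noise SD 0.2);
  aggregation — the ODM, prevalence consensus, activity tests — is where
  the signal is.

## Worked example

```{r}
scn <- simulate_grn(12, 8, n_distractors = 6, seed = 3)
expr <- simulate_expression(scn, 200, seed = 4)
fit <- sicnet(expr, scn$background, folds = 5, seed = 1)
summary(fit)
recovery_report(scn, fit$network)

obj <- simulate_expression(scn, 40, seed = 5, cell_prefix = "obj")
odm <- predict(fit, obj, type = "odm")
odm[1:5, 1:6]
```
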