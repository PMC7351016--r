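---
title: "Comparing correlation-based and sparse-regression brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing correlation-based and sparse-regression brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roinet)
```

## The problem

Resting-state functional connectivity studies summarize each brain region
of interest (ROI) by one mean time series and ask how the network built on
those series differs between groups — for example between healthy
controls, people with mild cognitive impairment, and people with
Alzheimer's disease. Two construction routes are compared throughout this
package:

* **Pearson correlation.** The edge weight between regions $i$ and $j$ is
  the product-moment correlation
  $r(x_i, x_j) = \frac{\sum_t (x_i(t) - \bar x_i)(x_j(t) - \bar x_j)}
  {\sqrt{\sum_t (x_i(t) - \bar x_i)^2 \sum_t (x_j(t) - \bar x_j)^2}}$.
  Every pair gets a weight; the matrix is dense.

* **L1-regularized regression (lasso).** Region $p$'s series $\gamma_p$
  is modeled as a sparse linear combination of all other regions'
  series, $\gamma_p = A_p \alpha_p + e_p$, by minimizing
  $f(\alpha_p) = \tfrac12 \lVert \gamma_p - A_p \alpha_p \rVert_2^2 +
  \lambda \lVert \alpha_p \rVert_1$.
  The L1 penalty drives coefficients exactly to zero, so the assembled
  coefficient matrix is sparse: an edge survives only if one region
  carries information about another *beyond* what the remaining regions
  already explain. This is why a shared global signal — which inflates
  every pairwise correlation — affects the two constructions very
  differently.

Both weighted matrices are thresholded into binary undirected graphs at a
grid of edge densities, characterized by small-world metrics, and compared
between groups density by density.

## The pipeline, stage by stage

### Temporal preprocessing

`nuisance_regress()` removes an intercept, a linear trend and any
user-supplied covariates by ordinary least squares; residuals are exactly
orthogonal to the design. `bandpass()` then applies a Butterworth
band-pass (default 0.03–0.06 Hz at TR = 2 s, order 4) forward and
backward (`signal::filtfilt`), so the filter is zero-phase and introduces
no temporal shift. The narrow default band is the range in which
resting-state small-world topology is most pronounced. The filter family
and order are not uniquely determined by common practice, so both are
exposed in `prep_config()`; order 4 forward–backward is a conventional
resting-state default. Regression runs before filtering so that filter
edge effects cannot leak trend variance back into the series. Series
shorter than three filter lengths are rejected with the minimum usable
length in the message.

### Connectivity

`pearson_connectivity()` wraps the product-moment formula (via
`stats::cor`), forces the diagonal to zero (graphs exclude self-loops)
and converts zero-variance regions into zero rows with a warning rather
than an error, so degenerate inputs flow through.

`l1_connectivity()` solves one lasso problem per region with the
package's own cyclic coordinate-descent solver (`lasso_regress()`):
coordinate updates are soft-thresholding steps on the Gram formulation,
and iteration stops only when the subgradient optimality conditions hold
to `tol` (default 1e-8, relative to the data scale). Columns are
mean-centered first — the model has no intercept — but deliberately not
variance-rescaled, since the objective is stated on the raw series.

The penalty is chosen by `select_lambda()`. The default
`fraction_of_max` policy sets $\lambda$ to 10% of the largest per-region
shrink-to-zero threshold $\max_j |a_j^\top \gamma_p|$: above that
threshold the solution is identically zero, so the fraction directly
positions the fit between "empty" and "least squares" on a scale that
transfers across subjects with different signal amplitudes. A fixed
$\lambda$ is available when comparability with an external choice
matters.

The per-region fits produce a directed matrix; the undirected graph
analysis needs a symmetric one. The default `max_abs` rule keeps, for
each pair, whichever directed coefficient has the larger magnitude —
preserving the strongest evidence for an edge — with `mean` as the
alternative; ties keep the upper-triangle entry so results are
deterministic.

### Binary graphs and small-world metrics

`binarize_at_density()` ranks off-diagonal entries by absolute weight and
keeps the top $K = \operatorname{round}(d \cdot M(M-1)/2)$ as edges
(round half away from zero; ties at the cutoff break lexicographically,
so binarization is bit-reproducible). Absolute values are ranked for both
methods: after symmetrization the sign of a lasso coefficient is not
interpretable, and using $|r|$ keeps the treatment uniform. If a sparse
matrix has fewer nonzero weights than the target — common for lasso
matrices at high densities — all nonzero edges are kept and the shortfall
is recorded.

The four metrics follow the standard binary-graph definitions: mean
clustering coefficient $C_p$ (nodes of degree < 2 contribute 0),
characteristic path length $L_p$, global efficiency $E_g$
(mean inverse distance, 0 for unreachable pairs) and local efficiency
$E_{loc}$ (mean global efficiency of each node's neighbor subgraph).
Distances and triangle counts are computed through igraph; the test
suite pins every metric to brute-force enumeration oracles (triangle
triples, Floyd–Warshall, exhaustive neighbor subgraphs) on hundreds of
small random graphs.

**Disconnected graphs.** At densities as low as 0.10 the thresholded
graph can fragment. $L_p$ is averaged over *reachable* pairs only, with
the unreachable-pair count attached as an attribute; the alternative
(infinite distances) would poison group means at exactly the densities
where fragmentation is informative. $E_g$ needs no convention — inverse
distance is zero for unreachable pairs.

**Null model.** `small_world_indices()` compares the real graph with
degree-preserving random networks obtained by double-edge swaps
(igraph's `keeping_degseq`; 10 attempted swaps per edge, 100 nulls by
default, all seeded). $\gamma = C_p/\bar C_p^{null}$,
$\lambda = L_p/\bar L_p^{null}$, $\sigma = \gamma/\lambda$; a network is
called small-world when $\gamma > 1$ with $\lambda \approx 1$,
equivalently $\sigma > 1$. Nulls on which $L_p$ is undefined are dropped
and counted; more than 20% dropped is an error rather than a silently
biased ratio. Indices are computed per subject, not on group-mean
networks.

### Group statistics

`compare_groups()` runs a pooled-variance (Student) two-tailed t test per
(density, metric) cell. Pooled rather than Welch because that is the
textbook default reading of "two-sample t-test"; the choice is recorded
in the table's metadata. The Bonferroni family defaults to the 41
densities within one metric — the tests are "one per density" — with a
whole-table family available; raw P values are always reported alongside
adjusted ones, and the significance flag uses adjusted P < 0.05.
`effect_size_curve()` emits pooled-SD Cohen's d per density, the paired
output used to compare how strongly the two construction methods separate
the same groups.

Two worked demographic examples complete the statistics module:
`chi_square_independence()` (Pearson chi-squared without continuity
correction) and `anova_oneway_summary()`, which reconstructs a one-way
ANOVA from per-group means, SDs and sizes when only a published summary
table is available. On the reference sex-by-group table (11/16, 22/11,
13/11) the chi-squared P is 0.133. On the companion age summaries
(63.74 ± 7.80 n=27, 68.00 ± 9.89 n=33, 67.54 ± 10.48 n=24) the
reconstruction gives F(2, 81) = 1.71, P = 0.187; a published P of 0.166
for those same summaries is not recoverable from the rounded values — an
ANOVA on unrounded raw data need not match one rebuilt from a rounded
table, which is why the package tests the reconstruction against its own
sum-of-squares identity rather than against that printed value.

## The synthetic cohort generator

No raw fMRI ships with the package, and the group-level findings of any
particular study cannot be regenerated from synthetic data. What the
generator provides is a cohort with *known* structure so that every
pipeline property — type-I error control, power against a known effect,
the sparsity contrast between methods — can be checked against ground
truth.

Each subject is drawn as correlated Gaussian innovations with a block
(modular) spatial correlation matrix — `r_within` inside a module,
`r_between` elsewhere, unit diagonal — passed through a lag-1
autoregressive filter and augmented with a shared global time course.
Group membership shifts `r_within` by a per-group delta: degraded or
enhanced local connectivity, precisely the effect the clustering
coefficient and local efficiency should detect downstream.

Defaults, chosen once as a realistic region-level emulation and not
revisited:

| parameter | default | why |
|---|---|---|
| groups | 27 / 33 / 24 | the emulated three-group design (HC/MCI/AD) |
| `n_regions` | 90 | standard whole-brain anatomical parcellation size |
| `n_timepoints`, `tr` | 155, 2 s | a typical usable resting-state run |
| modules | 6 contiguous, equal | coarse large-scale systems |
| `r_within`, `r_between` | 0.5, 0.1 | strong intra-system, weak inter-system coupling |
| `group_deltas` | 0, +0.05, −0.15 | mild compensatory increase, clear deficit |
| `ar_coef` | 0.3 | BOLD-like temporal smoothness at TR = 2 s |
| `global_amp` | 0.2 | mild residual global signal after preprocessing |
| seed derivation | `(48271·seed + 104729·i) mod (2³¹−1)` | reproducible, independently regenerable subjects |

Innovations are rescaled by $\sqrt{1 - \phi^2}$ before the AR recursion
so the stationary marginal variance stays at the covariance diagonal,
which keeps the *cross-region correlation* at its target regardless of
`ar_coef` (two AR(1) processes with a common coefficient inherit their
innovations' correlation). A 50-sample burn-in removes the recursion
transient. If a parameter combination ever leaves the block matrix
indefinite, negative eigenvalues are clipped and the diagonal
renormalized to 1, with a warning (the default blocks are always valid).

What the generator deliberately does **not** emulate: hemodynamic
response convolution, scanner drift and motion artifacts, spatially
heterogeneous module sizes, negative correlations, non-Gaussian noise.
Passing tests therefore demonstrate that the pipeline's statistics behave
correctly on data whose dependence structure is known — not that any
particular clinical finding generalizes.

## Verification strategy and problem sizes

The test suite works at three scales, chosen to keep a full run in a few
minutes on one core:

* **Exact oracles.** Metrics vs brute-force enumeration on 200 random
  graphs of up to 12 nodes; the lasso vs its subgradient conditions and
  vs a high-precision convex solve (glmnet with matched
  parameterization) on 50 random instances of up to 50 × 10; the
  chi-squared and ANOVA examples vs closed forms.
* **Distributional properties.** A null cohort (two arms of 20 subjects,
  30 regions, 155 time points, identical parameters) must give a
  fraction of raw P < 0.05 cells inside the binomial 95% band around
  0.05 across the 164 (density, metric) cells; metric curves at
  neighboring densities from the same subjects are correlated, which in
  practice makes the observed fraction mildly conservative, and the band
  check is the agreed criterion.
* **Power and qualitative contrasts.** Lowering `r_within` by 0.3 in one
  arm must yield Bonferroni-significant clustering-coefficient
  differences at ≥ 80% of the 41 grid densities for **both**
  construction methods; ring lattices with 5% shortcuts (90 nodes,
  degree 10) must be classified small-world ($\gamma > 1$,
  $\lambda \in [0.8, 1.3]$, $\sigma > 1$) in ≥ 95% of seeded
  repetitions with 50 nulls; and the lasso matrix must have strictly
  more exactly-zero off-diagonal entries than the correlation matrix on
  every subject. The sensitivity comparison between the two methods is
  *reported* as paired effect-size curves, not asserted directionally —
  which method separates groups more strongly depends on the generating
  model, and a synthetic cohort cannot settle what only real data can.

`scripts/acceptance.R` re-runs all of this from scratch under a single
command-line seed and writes the resulting numbers as JSON.

## Numerical choices and degenerate inputs

* Lasso convergence is declared on the KKT violation, not on coefficient
  movement, so "converged" means "optimal to tolerance"; non-convergence
  raises an error carrying the final violation.
* A lambda at or above the shrink-to-zero threshold returns exact zeros
  (no 1e-17 residue), and zero-variance predictors stay at coefficient
  zero.
* Binarization, rewiring, subject simulation and null ensembles are all
  pure functions of their seeds; pipeline runs reproduce byte-identical
  TSV artifacts (MD5s recorded in the run manifest).
* Degenerate statistics follow explicit conventions: zero pooled
  variance with equal means gives t = 0, P = 1 (unequal means is an
  error); an edgeless graph has $C_p = E_g = E_{loc} = 0$ and an
  undefined $L_p$ (error), while a disconnected graph keeps a finite
  reachable-pair $L_p$.

## Known limitations

* The regularization value of the reference analyses is unknown
  ("preselected"); the `fraction_of_max` default makes sparsity
  comparable across subjects but is a package choice, not a
  reconstruction.
* Whether the original directed coefficient matrices were symmetrized —
  and how — is unknown; both rules are exposed and `max_abs` is the
  documented default.
* The exact null-model and disconnected-graph conventions of the
  toolboxes used in the literature vary; the conventions above are
  documented choices.
* Group-level P-value tables from real cohorts are not reproducible from
  synthetic data; the package reproduces their structure (41 densities ×
  4 metrics per contrast) and verifies the statistical machinery instead.
* Weighted-graph metric variants and nodal (region-wise) statistics are
  out of scope.
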