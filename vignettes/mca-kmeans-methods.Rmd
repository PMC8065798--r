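---
title: "Methods: MCA--k-means risk-factor clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MCA--k-means risk-factor clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the model, the parameter conventions and the
numerical choices behind `mca_kmeans()` and its building blocks, in
enough detail to re-derive or independently re-implement the results.

## 1. Setting and assumptions

The data are an $I \times K$ table of categorical variables (patients
by risk factors and outcomes) with $J$ category levels in total. The
method assumes:

- every cell is observed (no missing data; `encode_indicator()` refuses
  `NA`s rather than imputing);
- every variable has at least two observed levels (a constant column
  has zero variance and no mass-centered representation; see
  `drop_constant` below);
- outcomes participate as *active* variables, on the same footing as
  the comorbidities: the goal is to detect co-occurrence, not to model
  the outcome conditionally.

## 2. Multiple correspondence analysis

One-hot expansion maps each variable to one 0/1 column per level —
*both* levels of a binary variable are expanded, so every category
level becomes a point. This yields the indicator matrix
$\mathbf{X}$ ($I \times J$, row sums all equal to $K$) and the Burt
matrix $\mathbf{B} = \mathbf{X}'\mathbf{X}$.

For an analysed matrix $\mathbf{A}$ (either basis), let
$N = \sum_{ij} A_{ij}$, $\mathbf{P} = \mathbf{A}/N$, and
$\mathbf{r}, \mathbf{c}$ the margins of $\mathbf{P}$. The core
decomposition is the SVD of the standardized residuals

$$
\mathbf{S} = \mathbf{D}_r^{-1/2}(\mathbf{P} - \mathbf{r}\mathbf{c}')
\mathbf{D}_c^{-1/2} = \mathbf{U}\,\boldsymbol{\Delta}\,\mathbf{Q}',
$$

with principal coordinates
$\mathbf{F} = \mathbf{D}_r^{-1/2}\mathbf{U}\boldsymbol{\Delta}$ (rows)
and $\mathbf{G} = \mathbf{D}_c^{-1/2}\mathbf{Q}\boldsymbol{\Delta}$
(columns). Eigenvalues are $\lambda_s = \delta_s^2$; their sum is the
total inertia, i.e. Pearson's $\chi^2/N$ of $\mathbf{A}$. Useful
identities, all enforced by the test suite:

- indicator basis: total inertia $= J/K - 1$ for any table (for the
  reference cohort, $33/16 - 1 = 1.0625$);
- Burt basis: eigenvalues are the squares of the indicator-basis
  eigenvalues;
- transition relation: $\mathbf{G} = \mathbf{D}_c^{-1}\mathbf{P}'
  \mathbf{F}\boldsymbol{\Delta}^{-1}$;
- $\mathbf{r}'\mathbf{F} = \mathbf{c}'\mathbf{G} = \mathbf{0}$
  (mass centering).

Numerical conventions:

- **Null dimensions.** Singular values $\le$ `tol` (default `1e-12`)
  are dropped; an exactly independent matrix therefore has zero
  retained dimensions and zero inertia.
- **Axis orientation.** An SVD axis is determined only up to sign. Each
  axis is oriented so its largest-magnitude *category* coordinate is
  positive. This makes repeated fits comparable, but note that when two
  symmetric categories tie for the largest magnitude, the orientation
  can still flip under row permutation; comparisons across fits should
  align signs per axis.
- **Degenerate masses.** Zero row or column mass is an error naming the
  offending index, not a silent drop.

**Dimension retention.** The default rule keeps the smallest leading
axis count whose cumulative share of inertia reaches
`dim_threshold = 0.80`. On the indicator basis the inertia spectrum is
flat (a known property of indicator-basis MCA), so this typically keeps
many axes; the threshold trades geometric fidelity of the embedding
against the dimensionality seen by k-means.

## 3. K-means with cross-validated cluster count

The retained category coordinates (rows of $\mathbf{G}$) are clustered
by Lloyd's algorithm: random distinct points as initial centers,
alternate assignment/update until assignments are stable or `max_iter`
(default 100) is reached, best of `n_restarts` (default 10) restarts.
Conventions:

- **Cost.** The reported clustering cost is the *mean unsquared*
  Euclidean distance of points to their assigned centers
  (`metric = "distance"`); `metric = "squared"` gives the classical
  within-cluster sum-of-squares convention. The Lloyd *update* step
  always minimizes the squared objective (the mean is the squared-loss
  minimizer); the unsquared cost is used for reporting and model
  selection.
- **Ties.** A point equidistant to several centers goes to the
  lowest-numbered one; labels are renumbered by first appearance so
  results are permutation-stable.
- **Empty clusters.** An emptied cluster is re-seeded with the point
  farthest from its current center.

**Cluster-count selection** (`select_k()`): for each $k$ in
`k_min..k_max` (default 2..10), a `v`-fold (default 5) cross-validation
is run — centers fitted on $v-1$ folds, the held-out fold scored by its
mean distance to the nearest center. The *same* seeded fold shuffle is
reused across all $k$, so per-fold costs are paired across $k$.
Selection rules:

- `cost_plateau` (default): the first $k$ with
  $|\bar D(k+1) - \bar D(k)| <$ `cost_tolerance` (default 0.01).
  This threshold is *scale-dependent*: costs are mean distances in the
  embedding, so rescaling the data rescales the decrements. The default
  is calibrated to MCA principal coordinates, whose scale is bounded by
  the singular values ($\le 1$).
- `fold_significance`: the first $k$ whose paired two-sided $t$-test of
  per-fold costs against $k+1$ is non-significant at $\alpha = 0.05$.

If no $k$ satisfies the rule in range, the cross-validated cost minimum
is returned with `flagged = TRUE`. On the full 33-category reference
cohort the plateau rule often does not trigger within $k \le 10$
(successive decrements stay above 0.01), which the fit reports
explicitly rather than hiding.

All stochastic stages derive their seeds deterministically from the
single user seed, so a fit is exactly reproducible; `.Random.seed` of
the calling session is saved and restored.

## 4. The synthetic cohort generator

`table1_spec()` encodes the marginal level counts of the reference
cohort (1022 patients; 15 binary variables plus a 3-level comorbidity
index; outcome prevalences 25/1022 and 15/1022). `generate_cohort()`
draws each free variable independently from its marginals.

**Planted blocks.** A block is a set of `"Variable=Level"` members plus
a strength $s \in [0,1]$. Dependence is induced by one shared latent
Bernoulli per block: with $q$ the smallest member marginal, each row is
*activated* with probability $q$, and an activated row switches each
member level on with probability $s$ (so the forced-on rate is $qs$);
otherwise the member's variable is drawn from a residual distribution
with the member level's probability reduced to $(p - qs)/(1 - qs)$,
which preserves every marginal exactly in expectation at every
strength. $s = 0$ gives mutual independence; $s = 1$ with equal member
marginals gives deterministic co-occurrence. Blocks must be disjoint in
variables, and a member whose marginal falls below the activation rate
is rejected as infeasible.

What the generator does and does not emulate: it reproduces the
marginal composition of the study cohort and lets association structure
be planted with known truth, which is exactly what is needed to
evaluate cluster recovery; it does **not** model age/sex-specific
comorbidity correlation, calendar time, or any causal structure.
Claims-level fixtures (`generate_claims()`) are deliberately toy-sized,
built for exercising the cohort-construction rules (index window, age
filter, baseline exclusions, 3-visit confirmation), not for realism.

`generate_blobs()` provides the complementary geometric fixture:
isotropic Gaussian blobs with centers on a circle. The defaults
(`sd = 0.05`, `separation = 5`) put the within-blob spread far below
and the between-blob gaps far above the 0.01 plateau tolerance, so the
planted blob count is identifiable by the selection rule.

## 5. The logistic control arm

`fit_logistic()` is a plain maximum-likelihood fit via IRLS
(`stats::glm`, binomial family, iteration cap 100, deviance tolerance
`1e-8`), with *no* variable selection and *no* penalization — the point
of this arm is to exhibit, not repair, the rare-event pathology. A term
is flagged for quasi-separation when its standard error exceeds 50 or
its absolute coefficient exceeds 10; `rare_event_diagnostics()` traces
flags to the zero cells of the covariate-by-outcome tables.
Rank-deficient designs are an error listing the aliased terms, never a
silent `NA`. The per-covariate Rao score test (`score_test()`) is
computed in closed form from the intercept-only null,
$U'V^{-1}U \sim \chi^2_{J-1}$ with $U = X'(y - \bar y)$ and
$V = \bar y(1-\bar y)\,(X'X - X'\mathbf{1}\mathbf{1}'X/n)$; it reduces
to the (uncorrected) Pearson $\chi^2$ for a binary covariate and
remains well defined even where the full regression diverges.

## 6. Problem sizes and verification

The package is exercised at the scales its guarantees are stated for:
MCA against an independent eigendecomposition oracle on random tables
up to $50 \times 5$ (coordinates to $10^{-6}$, eigenvalues to
$10^{-8}$); k-means against exhaustive partition enumeration on point
sets of size 8; cluster-count recovery on blob fixtures with
$k \in \{2,3,5\}$; block recovery and separation-flag behaviour on full
$1022 \times 16$ generated cohorts. A single `mca_kmeans()` fit at that
size takes well under a second.

## 7. Limitations

- Constant columns cannot be embedded. By default `mca_kmeans()` treats
  them as an error; `drop_constant = TRUE` (the pipeline default) drops
  them with a warning, because a sampled cohort can legitimately miss
  the rarest level of a very rare comorbidity (e.g. a 2/1022
  prevalence).
- The plateau tolerance is an absolute number on the cost scale; it is
  not invariant to rescaling the embedding and was chosen for MCA
  principal coordinates.
- Cluster membership is descriptive co-occurrence, not a causal or even
  conditional-association statement; categories of the *same* variable
  are mechanically negatively associated and their placement should not
  be over-read.
- The cross-validation selects a cluster count, not a clustering
  "significance"; with diffuse structure it can fail to plateau and
  fall back (flagged) to the in-range cost minimum.
- The generator preserves marginals in expectation, not exactly per
  draw; finite-sample marginal fluctuation is intended and is what
  makes the constant-column case reachable.
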