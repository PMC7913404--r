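---
title: "Spatial propensity score matching: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial propensity score matching: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Observational comparisons of a binary exposure (for example, membership in a
racial group as perceived by care providers) on a binary health outcome are
confounded at two levels when patients are clustered in areal units such as
counties: by patient-level covariates, and by *geographic confounding* —
county-level factors, observed or not, that are associated with both exposure
prevalence and outcome rates and that vary smoothly over the map. Classical
propensity score matching balances the patient-level covariates but leaves
the geographic component untouched; when the unmeasured county factors are
spatially structured, estimates of the average treatment effect on the
treated (ATT), $\Delta_{ATT} = E(Y_1 - Y_0 \mid Z = 1)$, are biased and
interval coverage collapses.

`spatialpsm` implements a two-stage remedy: augment both the propensity
score model and the post-matching outcome model with county-level random
intercepts carrying a scaled Besag–York–Mollié (BYM2) prior, so that
counties borrow strength from their neighbours, and carry the resulting
posterior through matching and standardization to an ATT risk difference
with a credible interval.

## Models

**Propensity model.** For patient $j$ in county $i$ with covariates
$x_{ij}$ and exposure $Z_{ij}$,
$$\mathrm{logit}\,\Pr(Z_{ij} = 1) = x_{ij}^T\beta + \phi_{1i}.$$

**Outcome model** (fitted on the matched sample only, separately from the
propensity model so that the outcome never feeds back into the propensity
posterior):
$$\mathrm{logit}\,\Pr(Y_{ij} = 1) = x_{ij}^T\gamma + z_{ij}\alpha + \phi_{2i}.$$

**Spatial prior.** Each $\phi_k = (\phi_{k1}, \dots, \phi_{kn})^T$ follows
the scaled BYM (BYM2) decomposition
$$\phi_k = \sigma_k\left(\sqrt{1 - \lambda_k}\, v_k +
  \sqrt{\lambda_k}\, u_{\star k}\right), \qquad
  \mathrm{Var}(\phi_k) = \sigma_k^2\left[(1 - \lambda_k) I +
  \lambda_k Q_\star^-\right],$$
where $v_k$ is iid standard normal, $u_{\star k}$ is an intrinsic CAR
(ICAR) field with scaled structure matrix $Q_\star$, and
$\lambda_k \in [0, 1]$ is the share of marginal variance carried by the
structured component. $Q = M - A$ is built from the county adjacency graph
($M$ = diagonal neighbour counts, $A$ = 0/1 adjacency); $Q_\star = s\,Q$
with $s$ chosen so the geometric mean of
$\mathrm{diag}(Q_\star^-)$ — the marginal variances of the sum-to-zero
constrained ICAR field — equals one. Scaling makes $\sigma_k^2$ comparable
across neighbourhood graphs and hence gives the precision prior a stable
meaning. One well-known subtlety: the two standard write-ups of the BYM2
decomposition disagree on whether the multiplier is $\sigma$ or $\sigma^2$;
we use $\sigma$, the form whose variance reproduces the covariance displayed
above.

**Priors.** Fixed effects: independent $N(0, 10^5)$. Total spatial
precision $\tau_k = 1/\sigma_k^2$: Gamma(shape 1, rate $5\times 10^{-5}$).
Mixing weight $\lambda_k$: Uniform(0, 1) — the source material is silent on
this prior and on which precision the gamma prior targets under the
re-parameterization; we place it on the total BYM2 precision and document
the choice here rather than claiming it reconstructs anyone's intent.

## Inference: Laplace approximation with hyperparameter grid

The latent vector $\theta = (\beta, \phi)$ given hyperparameters
$\psi = (\log\tau, \mathrm{logit}\,\lambda)$ has a log-concave posterior;
an inner Newton iteration (analytic gradient and Hessian, step-halving,
gradient max-norm tolerance $10^{-8}$, at most 100 iterations) finds the
conditional mode, and the Gaussian (Laplace) approximation at that mode
supplies both the latent posterior and the marginal likelihood of $\psi$.
Because the prior precision of the spatial block can be enormous at grid
extremes (large $\tau$, $\lambda \to 1$), an absolute gradient criterion
can sit below double precision; the iteration therefore also stops when the
Newton decrement falls below $2\times10^{-9}(1 + |f|)$, which bounds the
attainable objective improvement.

The outer integration over $\psi$ uses a deterministic grid: a coarse scan
over $\log\tau$ at $\lambda = 1/2$, Nelder–Mead refinement to the joint
mode, a numeric 2×2 curvature estimate, and a centred 5×5 grid spaced by
0.9 posterior standard deviations per dimension, pruned at relative weight
$10^{-5}$ and renormalized. Twenty-five curvature-spaced points cover this
two-dimensional, close-to-Gaussian hyperposterior well at the problem sizes
the package targets; the accuracy class is the plain Gaussian-at-the-mode
Laplace approximation (no skewness correction). The grid size is a
`model_spec()` parameter for users who want a denser rule.

The structured component never has mass on the constant direction: sampling
and precision construction work in the eigenbasis of $Q_\star$, whose null
space (one constant vector per graph component) is excluded, which enforces
the per-component sum-to-zero constraint exactly. Eigenvalues are truncated
at a relative tolerance of $10^{-10}$ when the generalized inverse is
formed.

Posterior functionals are Monte Carlo averages over the grid mixture: a
grid point is drawn by weight, then a Gaussian latent vector at its
mode/curvature. Posterior-mean propensity scores integrate
$\mathrm{expit}(\eta_{ij})$ over 400 such draws by default (the method and
draw count are recorded on the result); ATT standardization uses 1000
draws.

## Matching

Matching is greedy 1:1 nearest-neighbour without replacement on
$\mathrm{logit}(\hat e_{ij})$ with caliper $0.2 \times$ the pooled sample
SD of the logit scores. Treated subjects are processed in a seeded random
permutation by default — the processing order is not pinned down by the
method's sources, so it is exposed as a parameter (`"random"`,
`"descending"`, `"data"`) for sensitivity analysis. Ties between
equally-near available controls break toward the smallest control index,
for determinism. The matcher runs in $O((n_t + n_c)\log n_c)$ via bisection
in a sorted control array with path-compressed deletion pointers; a
brute-force quadratic implementation serves as its oracle in the test
suite. Balance is reported as absolute standardized differences (pooled
two-group variance denominator, proportion form for binary covariates).

## ATT estimation

On the matched sample, the outcome model (exposure-only, or
covariate-adjusted, with or without its own spatial intercept) is fitted
and 1000 posterior draws taken. For each draw every matched subject is
standardized to both exposure arms — the subject's own covariates and
county effect appear in both arms, so the spatial term is shared rather
than cancelled through the nonlinear link — and the within-draw mean of
$\mathrm{expit}(\eta \mid z{=}1) - \mathrm{expit}(\eta \mid z{=}0)$ is the
draw's risk difference. The reported ATT is the across-draw mean; the 95%
credible interval is the 2.5/97.5 percentile range. Matched-pair dependence
is deliberately ignored in the outcome model, mirroring standard practice
for this estimator. The crude (unadjusted) estimate is the observed
difference in outcome proportions; in the five-model stepwise analysis its
interval comes from an intercept-plus-exposure outcome model on the full
sample, so that all five rows carry credible intervals while the point
estimate remains the crude difference.

## The synthetic-data generator

The generator emulates a three-state county system: 272 regions with 1528
ordered pairwise adjacencies (764 undirected edges; census adjacency files
count ordered pairs, and both readings are supported via an argument).
Because polygon geometry is out of scope, the graph itself is synthesized:
Delaunay triangulation of uniform random points, then uniformly random edge
pruning to the target count under a connectivity guard. This yields
planar, county-like degree distributions (mean ≈ 5.6) but not the actual
census topology; the patient-covariates-only scenario is insensitive to
the graph by construction, which is why the acceptance checks use it.

Per-county cohort sizes are drawn by picking one of the four
inter-quartile intervals of (2, 21, 36, 78, 800) with probability 1/4 and
then a uniform integer inside it — the most direct reading of "uniform
within quartile-defined intervals" — giving a long-tailed size distribution
with mean ≈ 134 and totals near 36,000 patients.

Patient covariates are $x_1 \sim N(5, 2)$ (second parameter read as a
variance, consistent with the $N(0,1)$ notation used alongside it),
$x_2 \sim N(0,1)$, $x_3 \sim \mathrm{Bern}(0.4)$,
$x_4 \sim \mathrm{Bern}(0.2)$. Exposure and outcome follow the logistic
models above with $\beta_0 = 0.10$, $\beta = (-0.15, 0.1, 0.1, -0.5)$,
$\gamma_0 = -1.0$, $\gamma = (0.10, -0.3, 0.1, -0.4)$, treatment effect
$\alpha = -0.50$; county terms $v_i\eta$ and $f_1(u_i)$ (propensity),
$v_i\psi$ and $f_2(u_i)$ (outcome) with $\eta = -0.3$, $\psi = 0.5$,
$V_i \sim \mathrm{Bern}(0.3)$, and $U_i$ a proper CAR field (smoothing
0.5, variance $\sigma^2_u$). Both potential outcomes are retained, and the
observed outcome obeys consistency. The implied true ATT, recomputed by
Rao–Blackwellised Monte Carlo (averaging
$\mathrm{expit}(\eta_0 + \alpha) - \mathrm{expit}(\eta_0)$ over simulated
treated patients, so the closed-form corner cases hold exactly), is
≈ −0.104 in the patient-covariates-only scenario.

The smooth county effects are $f_k(u) = \sum_{l=1}^{6}\nu_{kl} B_l(u)$:
cubic B-splines with interior knots at the empirical quartiles of the
realized $U$ and the intercept column dropped (six basis columns; the model
intercepts live in $\beta_0, \gamma_0$). The coefficients $\nu_k$ are not
identifiable from any published source, so the package ships defaults —
$\nu_1 = (0.4, 0.8, 1.2, 1.2, 0.8, 0.4)$,
$\nu_2 = (-0.6, -0.3, 0.3, 0.6, 0.9, 1.2)$ — chosen once to be smooth,
non-linear, and same-signed in both models (genuine geographic
confounding); they are config-overridable.

**A scale-invariance property worth knowing.** With quantile-anchored
knots, $f_k(U)$ is exactly invariant to rescaling $U$: multiplying
$\sigma^2_u$ by any positive constant rescales the field and its knots
together and leaves every $f_k(u_i)$ unchanged. Scenarios
$\sigma^2_u = 2$ and $\sigma^2_u = 4$ are therefore *identical in
distribution*; only $\sigma^2_u = 0$ (county terms off) versus
$\sigma^2_u > 0$ (geographic confounding on) changes the generative law.
The package keeps the quantile-knot definition because it is the stated
design, and treats "performance degrades as spatial variance grows" as the
on/off contrast; differences between the positive-variance scenarios are
replication noise. Users who want genuinely scale-sensitive confounding
can pass fixed `knots`/`boundary` to `spline_basis()` or scale $\nu_k$.

What passing simulations do **not** show about real data: the generator
draws covariates independently, uses one smooth confounder and one binary
county covariate, and has no measurement error, missingness, within-county
correlation beyond the shared county terms, or realistic covariate sets;
results on it validate the machinery, not any particular application.

## Simulation study driver

`run_study()` crosses scenarios ($\sigma^2_u$ values) with the four
estimation strategies (non-spatial/spatial propensity model ×
exposure-only/covariate-adjusted outcome model; the spatial-adjusted
variant also puts the spatial intercept in the outcome model, and fitted
models never see $V_i$ or $U_i$ — those are the unmeasured confounders).
Per-scenario truth is recomputed by Monte Carlo over at least $10^6$
patients. Metrics: relative bias $|\bar{\hat\Delta} - \Delta|/|\Delta|$,
RMSE, and 95% interval coverage in percent. Replicate seeds derive
deterministically from the base seed; failed replicates are recorded and
excluded rather than imputed, because silent imputation would bias
coverage. Propensity fits and matched samples are shared between variants
with identical propensity specifications within a replicate — they are the
same computation.

The test suite runs the null-spatial scenario at 100 replicates and the
confounded scenarios at 25 replicates each. The confounded-scenario
assertions are directional only (spatial coverage above non-spatial,
spatial RMSE no worse, non-spatial coverage below its null-scenario
level); with the package's default spline coefficients the geographic
confounding is milder than in studies that tuned it to be severe, so the
coverage deficits are single-digit percentage points and the replicate
seeds are fixed to make the contrast a deterministic regression check
rather than a power claim. The five-model null-calibration check runs 40
small cohorts (40 counties, quartiles (2, 8, 14, 24, 60)) — calibration
under a null effect is a property of the procedure, not of the cohort
size.

## Numerical choices

- Inner Newton: gradient max-norm $10^{-8}$, decrement fallback as above,
  step-halving, latent ordering (fixed effects, then county effects) in
  graph region order.
- Generalized inverses by symmetric eigendecomposition with relative
  zero-eigenvalue tolerance $10^{-10}$; per-component scaling; an isolated
  (degree-0) region is an error because its structured variance is
  undefined.
- Proper CAR sampling by sparse Cholesky of $(M - \alpha A)/\sigma^2$;
  $\sigma^2 = 0$ returns the degenerate zero field.
- The draw-by-subject reductions (posterior-mean propensities, per-draw
  standardized risk differences) and the matching scan run in compiled
  code; `exp` there uses range reduction with a degree-10 polynomial
  kernel (relative error ≈ $3\times10^{-13}$), because the reductions are
  otherwise bound by the platform's libm.
- Degenerate inputs: constant logit scores give a zero caliper with a
  warning (exact matches only); zero pooled variance with unequal means
  reports an infinite standardized difference with a warning; constant
  responses and perfectly separating covariates are errors naming the
  covariate.

## Limitations

- The Laplace-plus-grid posterior is an approximation; heavy-tailed or
  strongly skewed hyperposteriors are summarized by a Gaussian-at-the-mode
  rule and a 5×5 grid. No MCMC backend is provided.
- Credible intervals for the ATT condition on the matched sample and the
  outcome model; uncertainty from propensity estimation and matching is
  not propagated, mirroring the two-stage procedure the package
  implements.
- 1:1 greedy matching without replacement only; no optimal or variable
  ratio matching, no weighting or stratification estimators, no ATE.
- Areal data only (edge-list adjacency); no shapefile parsing, no
  geostatistical fields, no choropleth plotting.
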