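# spatialpsm

Propensity score matching for patients clustered in areal units (counties),
with spatial random effects that account for **geographic confounding** —
county-level confounders, observed or unobserved, that vary smoothly over
the map. The package is aimed at health-disparities and health-services
researchers estimating the average treatment effect on the treated (ATT)
from observational multilevel data.

## The method

For patient *j* in county *i*, a Bayesian logistic **propensity model** and
post-matching **outcome model**

```
logit Pr(Z_ij = 1) = x_ij' β + φ_1i
logit Pr(Y_ij = 1) = x_ij' γ + z_ij α + φ_2i
```

carry county random intercepts φ_k with a **scaled Besag–York–Mollié
(BYM2)** prior: φ_k = σ_k(√(1−λ_k) v_k + √λ_k u*_k), an iid component plus
an intrinsic CAR (ICAR) component on the county adjacency graph, with the
ICAR structure matrix Q = M − A scaled so that σ_k² is the (geometric-mean)
marginal variance and λ_k ∈ [0,1] is the share explained by spatial
structure. Models are fitted by a Laplace approximation with deterministic
hyperparameter-grid integration; the propensity and outcome stages are fit
separately to avoid feedback. Matching is greedy 1:1 nearest-neighbour
without replacement on the logit propensity with a caliper of 0.2 pooled
SDs; the ATT is the standardized risk difference — each matched patient
standardized to both exposure arms — averaged over 1000 posterior draws,
with a 95% percentile credible interval.

A full simulation driver reproduces the method's operating characteristics
(relative bias, RMSE, 95% coverage) under a synthetic 272-county system
with and without an unmeasured, spatially structured county confounder.

## Worked example

```r
library(spatialpsm)

graph  <- synthetic_county_graph(272, 1528, seed = 1)  # county-like adjacency
design <- simulation_design(sigma2_u = 2)              # geographic confounding on
cohort <- simulate_cohort(design, graph, seed = 12)
cohort
#> simulated_cohort: 40461 patients in 272 counties; P(z=1) = 0.561, P(y=1) = 0.406

# spatial propensity model, scores, caliper matching
spec   <- model_spec(c("x1", "x2", "x3", "x4"), include_spatial = TRUE, graph = graph)
psfit  <- fit_bayes_logistic(spec, cohort$data, "z")
scores <- posterior_mean_propensity(psfit, cohort$data, seed = 1)
idx    <- seq_len(nrow(cohort$data))
z      <- cohort$data$z
m      <- greedy_match(list(id = idx[z == 1], logit = scores$logit_e[z == 1]),
                       list(id = idx[z == 0], logit = scores$logit_e[z == 0]),
                       caliper = compute_caliper(scores$logit_e), seed = 2)
m
#> matched_sample: 16358 pairs, 6343 unmatched treated (caliper 0.0762, order random)
estimate_lambda(psfit)
#> [1] 0.1864482

# covariate-adjusted spatial outcome model on the matched sample
md    <- cohort$data[c(m$pairs$treated_id, m$pairs$control_id), ]
ofit  <- fit_bayes_logistic(model_spec(c("z", "x1", "x2", "x3", "x4"),
                                       include_spatial = TRUE, graph = graph),
                            md, "y")
draws <- sample_posterior(ofit, 1000, seed = 3)
standardized_risk_difference(ofit, md, draws)
#> att_estimate [adjusted]: risk difference -0.1140 (95% CrI -0.1242, -0.1041), n = 32716
```

The risk difference says matched treated patients have an outcome
probability about 11.4 percentage points lower than they would have had
under the control condition. In this cohort the exposure is the majority
group (P(z=1) = 0.56), so the control pool is exhausted and 6343 treated
patients go unmatched — the matched-sample diagnostics make that visible.
`estimate_lambda` reports the posterior share of county-level variance
attributed to spatial structure in the propensity model.

The same pipeline is available as commands (`cmd_simulate`, `cmd_analyze`,
`cmd_simstudy`, `cmd_graph`) and as a shell wrapper:

```sh
Rscript inst/cli/spsm.R analyze --seed 3 --out results/ --sigma2-u 2
```

which writes a five-row stepwise estimates table (unadjusted, patient-level
matching with/without outcome adjustment, spatial matching with/without
spatial outcome adjustment), balance diagnostics, and a manifest for exact
re-runs.

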