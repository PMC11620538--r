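---
title: "Multi-omic mediation: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic mediation: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediomics)
```

`mediomics` implements a framework for asking how an environmental
exposure affects a health outcome through molecular intermediates, when
several omics layers are measured on the same samples. This vignette is
the package's own account of the models it fits, the knobs that matter,
and the places where the design was genuinely open and a choice had to be
made.

## The setting

Per sample we observe an exposure $X$ (e.g. prenatal blood mercury), an
outcome $Y$ (e.g. the liver-injury biomarker CK-18), covariates $C$, a
cohort label, and $L$ omics matrices $M^{(1)}, \dots, M^{(L)}$ of very
different widths. Three questions structure the analysis, and each gets
its own mediation strategy:

1. *Which individual features carry the effect?* High-dimensional
   penalized mediation (surrogate-biomarker discovery).
2. *Which shared axes of molecular variation carry it?* Mediation with
   latent factors (pathway-level mechanism).
3. *Which subgroups of people carry the risk?* Latent-cluster
   quasi-mediation (risk stratification). "Quasi" because this model does
   not separate direct from indirect effects: it assumes the exposure's
   entire effect flows through the latent clusters.

Each strategy is crossed with an integration stage: **early**
(concatenate layers before modeling), **intermediate** (model layers
jointly but layer-aware), **late** (model each layer separately). The
stages trade statistical assumptions: early ignores differences in
dimensionality and correlation structure between layers; intermediate
models them explicitly; late forfeits cross-layer conditioning, which is
why correlated proxies in different layers can all be selected there
while a joint model would keep one.

## Preprocessing

All stages assume one canonical representation, produced by
`preprocess_study()`:

- **Exposure harmonization.** Cord-blood total mercury is divided by 1.7
  to place it on the maternal whole-blood scale
  (`harmonize_cord_mercury()`); the factor is the established
  cord-to-maternal concentration ratio for total mercury.
- **Within-cohort scaling.** Exposure and continuous outcome are scaled
  to mean 0, SD 1 *within each cohort* (`scale_within_groups()`), so
  cohort-level location and scale differences cannot masquerade as
  exposure effects. SDs use the $n-1$ denominator throughout the package.
- **Feature residualization.** Every feature is replaced by the residual
  of feature ~ covariates (+ cohort), studentized and rescaled to mean 0,
  SD 1 (`residualize_features()`). The studentization uses a *constant*
  leverage factor (the average hat value) rather than the per-row
  $\sqrt{1-h_{ii}}$: a row-varying factor would leave the output slightly
  correlated with the covariates and make the operation
  non-idempotent, and the contract downstream models rely on is exact
  orthogonality to the adjustment set. After the final rescaling the two
  versions differ only by that row weighting. Residualization is
  idempotent and output columns satisfy $|\mathrm{cor}(\cdot, C)| <
  10^{-8}$ by construction.
- **Missing data.** Complete-case on exposure/outcome/covariates;
  features with under 5% missingness are mean-imputed before
  residualization, wider gaps drop the feature. Omics matrices are
  assumed QC'd upstream (probe-level normalization and batch handling are
  out of scope).
- The exposure may optionally be log-transformed before scaling
  (`log_exposure = TRUE`): biomonitoring concentrations are typically
  right-skewed, but because the choice changes the estimand's scale it is
  exposed as a flag rather than imposed.

## Exposure–outcome analysis

`total_effect()` fits $Y \sim X + C$ by OLS and reports
$\gamma$ with a $t$-based Wald CI (small-sample-correct and consistent
with standard regression output; a normal-quantile CI would differ only
in the third decimal at the package's typical $n$).

`forward_select_covariates()` implements change-in-estimate selection:
starting from the minimal adjustment set, the candidate that moves
$\gamma$ most is added if the relative change exceeds 10%. The rule
leaves iteration order and ties unspecified, so the package fixes them:
largest change first, ties broken by name, giving a deterministic
selection path. If $\gamma$ is numerically zero the relative criterion
switches to an absolute one (logged).

Two sensitivity analyses accompany the estimate. Fixed-effects
meta-analysis across cohorts (`fixed_effects_meta()`) pools per-cohort
estimates by inverse variance and tests heterogeneity with Cochran's
$Q \sim \chi^2_{k-1}$. The robustness value (`robustness_value()`)
converts the $t$ statistic into the minimum partial $R^2$ an unmeasured
confounder would need with both exposure and outcome to explain the
estimate away; it is reported for full nullification ($q = 1$).

## Feature screening

The meet-in-the-middle screen ranks features by $|\alpha_j \beta_j|$
within each layer. The absolute value matters: mediated paths can be
negative on both legs, and ranking on the signed product would bury
them. The budget is the sure-independence-screening rule $2n/\log n$
(natural log), rounded *up* to the nearest multiple of five and divided
across layers with a per-layer ceiling, so every layer gets the same
integer share even when the division is uneven. With $n = 420$ and five
layers the budget is `r sis_feature_budget(420, 5)$total` features,
`r sis_feature_budget(420, 5)$per_layer` per layer. Screening is a
pre-filter, not inference: no multiplicity control is applied at this
stage, deliberately.

## High-dimensional mediation

The product-of-coefficients estimand is $\alpha_j\beta_j$ with
$\%TE_j = 100\,\alpha_j\beta_j/\gamma$.

**Early/late** (`mediate_early()`, `mediate_late()`): one lasso of $Y$ on
all retained features with $X$ and $C$ unpenalized; 10-fold CV with the
one-standard-error rule and seeded folds; features surviving the penalty
are refit jointly by OLS for debiased $\beta_j$ and SEs. The classic
recipe this follows uses MCP; lasso with an OLS refit preserves the same
select-then-debias contract on a simpler, extensively tested optimizer,
and is the package's default penalty family. Inference is
joint-significance — $p_j = \max(p_{\alpha_j}, p_{\beta_j})$ — with
Benjamini–Hochberg correction across the selected set at FDR 0.05.

**Intermediate** (`mediate_intermediate()`): the penalty multiplier is
allowed to differ per layer (group-lasso-type shrinkage per layer). The
reference workflow tunes such multipliers by empirical Bayes; the package
instead searches a 5-point log-grid (0.25–4) by coordinate descent
against the cross-validated error — transparent and directly testable.
Because glmnet rescales penalty factors internally, only *relative*
multipliers matter, and forcing them equal reproduces the early
integration fit exactly (a reduction the tests assert). Following the
two-step description of the method, the reported $\beta_j$ are the
penalized coefficients themselves, with standard errors from a
case-resampling bootstrap (default $B = 200$; below 50 a warning flags
unstable SEs) at the tuned penalty; bootstrap resampling is unstratified
by default with cohort stratification available upstream of the call.

**Confidence intervals for $\alpha_j\beta_j$** use the distribution of
the product of two independent normals (`prodclin_ci()`): the CDF
$P(AB \le q) = E_A[P(B \le q/A)\,\mathbb{1}_{A>0} + P(B \ge
q/A)\,\mathbb{1}_{A<0}]$ is evaluated by adaptive quadrature (split at
$A = 0$, relative tolerance $10^{-10}$) and inverted by root-finding over
a bracket of $\pm 15$ product-SDs. The independence assumption mirrors
the method this implements — $\hat\alpha$ and $\hat\beta$ come from
different regressions on the same data; their finite-sample correlation
is ignored. Tests hold the endpoints to within
$0.005(\mathrm{se}_a|b| + \mathrm{se}_b|a| + \mathrm{se}_a\mathrm{se}_b)$
of a $10^7$-draw Monte-Carlo oracle over a 27-point grid.

Per-feature $\%TE$ values are reported as-is and their sum is *not*
constrained to 100%: with correlated mediators and finite samples the
individual shares need not add up.

## Mediation with latent factors

`pca_factors()` keeps the smallest leading set of principal components
whose cumulative explained variance reaches the threshold (default 80%).
Component signs are arbitrary, so each component is anchored by making
its largest-magnitude loading positive — required for reproducible
output.

`jive_decompose()` splits the layers into joint, individual and residual
parts, $X_i = J_i + A_i + E_i$, with the individual sample-space
components constrained orthogonal to the joint ones. Each layer is first
scaled to unit Frobenius norm so a 500-feature methylome cannot drown a
36-protein panel in the joint fit. Estimation alternates truncated SVDs
(joint from the concatenation of $X_i - A_i$; individual from the
joint-orthogonalized residual of each layer) until the total residual sum
of squares changes by less than $10^{-6}$ relative (at most 500
alternations; the objective trace is stored and is non-increasing —
convergence can be slow near flat optima, hence the generous cap, and a
non-converged fit returns its best iterate with a warning).

Rank selection by permutation: sample order is permuted independently
within each layer, which destroys cross-layer alignment while leaving
each layer's covariance intact; the observed singular values of the
concatenation are compared against the 95th percentile of the permuted
leading singular value over 100 permutations (seeded), and the joint rank
is the count that exceed it. For individual ranks — where no alignment
exists to destroy — the analogous null permutes each column of the
joint-residual layer independently, breaking the sample coupling that
low-rank structure requires while preserving marginals.

`mediate_components()` treats standardized factor scores as candidate
mediators and reuses the penalized-joint-fit machinery, i.e. components
are selected and conditioned on *jointly* rather than tested one at a
time — consistent with how the feature-level analysis conditions its
mediators, and the path chosen where a per-component marginal analysis
was the plausible alternative. Two percent-mediated summaries appear:
`pct_te` $= 100\,\alpha\beta/\gamma$ per component, and `pct_mediated`,
each significant component's share of the summed significant indirect
effect (which is what "explains X% of the mediation" means for a
component; the two coincide only when exactly one component is
significant and it mediates everything). `component_feature_correlations()`
exports the Pearson $r$ and $p$ of every feature against every
applicable component — layer-individual components are not applicable to
other layers' features — as the ranked input for external
pathway-enrichment tools (proprietary enrichment engines are out of
scope).

## Latent-cluster quasi-mediation

The generative model: cluster $L \mid X$ is multinomial-logistic;
features $Z \mid L = k$ are independent normals with cluster means
$\mu_k$ and a per-feature variance shared across clusters; the outcome
$Y \mid L = k$ is normal with mean $\eta_k$ (supervised variant only).
The diagonal within-cluster covariance is the only tractable choice at
omics dimensionality and matches the no-variable-selection, $K = 2$
configuration the framework fixes a priori for interpretability.

The EM details that matter:

- **Initialization** is seeded k-means with 5 restarts, keeping the best
  final log-likelihood; mixture likelihoods are multimodal and a single
  start is not trustworthy.
- **M-step exactness**: the logistic step is solved to IRLS convergence
  (for $K = 2$ a weighted quasibinomial fit; beyond that a
  multinomial fit on the posterior matrix), so the observed-data
  log-likelihood is non-decreasing at every iteration — asserted in the
  tests at tolerance $10^{-8}$ — and EM stops at a relative change of
  $10^{-6}$ (at most 500 iterations).
- **Label anchoring**: mixture labels are arbitrary, so clusters are
  relabeled with the reference (cluster 1) having the lowest outcome mean
  (supervised) or lowest first-feature mean (unsupervised); $\delta$ and
  $\eta$ are expressed against that reference, which is fixed at 0.
- **Degenerate $K = 1$** returns all-ones PIPs, an empty $\delta$, and
  the outcome grand mean as the single cluster effect.
- **Empty clusters** trigger re-initialization; five failures abort with
  diagnostics rather than returning a silently degenerate fit.

`lucid_parallel()` fits one cluster variable per layer in a single EM,
assuming no residual cross-layer correlation given the clusters and an
*additive* outcome model in the layers' cluster indicators (cross-layer
interactions are not modeled; per-layer effects are what the analysis
reports). The E-step enumerates all $\prod_l K_l$ configurations —
$2^3 = 8$ subgroups for three layers, $2^5 = 32$ for five — which is
also why more than 10 binary layers are refused with a pointer to serial
mode. With a single layer the model *is* the early model, and the
implementation delegates accordingly, making the reduction exact by
construction. `cluster_omics_profile()` reports each cluster's expected
omics profile as the PIP-weighted mean, recomputed from the data for
auditability (at convergence it equals $\mu$ up to the final E-step
half-step).

`lucid_serial()` chains single-layer models along a user-supplied,
biologically motivated layer order: the first model is unsupervised with
the study exposure; each later model takes the previous model's
non-reference-cluster PIPs as its exposure (a single column at $K = 2$);
only the final model sees the outcome. Covariates enter the cluster
models only through the upstream residualization — the cluster model
itself takes none.

## The synthetic generators

The generators define the study conditions under which the framework's
guarantees are demonstrated; they are first-class, tested code.

- `simulate_mediation_study()`: cohort-shifted normal exposure; active
  features $M_j = \alpha X + $ block-correlated noise; outcome
  $Y = \gamma_{direct} X + \sum_j \beta M_j + \varepsilon$.
- `simulate_factor_study()`: joint factors loading on every layer,
  optional layer-individual factors, exposure and outcome loading on
  joint factor 1.
- `simulate_cluster_study()`: per-layer binary clusters with
  exposure-dependent log-odds (default slope 0.8), features at
  cluster means $\pm\,\mu_{sep}/2$ (default separation 2 SD), additive
  cluster effects on the outcome.

Default dimensions (500/300/100/36/177 over five layers) preserve the
relative ordering of real methylome/transcriptome/miRNA/protein/
metabolite panel widths at desk scale; within-layer correlation is
block-exchangeable (a single $\rho$ per block, default 0.3), the
simplest structure that reproduces within-layer correlation alongside
cross-layer independence of the noise. What the generators do *not*
emulate: array-specific marginals (beta-value distributions, intensity
artifacts), probe-level QC noise, and real between-layer biological
coupling beyond the planted factors. Tests passing on these generators
therefore demonstrate correctness of the estimators under their stated
models, not robustness to everything real data does.

Problem sizes used in the heavier checks — planted-mediator recovery at
$n = 500$ with 140 features over 50 seeds, rank recovery on
$60 \times (30+25+20)$ three-layer studies over 100 replicates,
log-odds recovery at $n = 2000$ over 50 seeds — were chosen so each
statistical claim is tested at the scale it is about while the suite
stays desk-sized.

## Known limitations

- Binary outcomes are carried through the data model but the cluster
  model's supervised variant is only exercised against continuous
  outcomes.
- Random-effects meta-analysis and benchmark-based confounder bounding
  are not implemented (the robustness value is the supported sensitivity
  summary).
- The product-of-coefficients CI ignores the finite-sample correlation
  of $\hat\alpha$ and $\hat\beta$.
- Penalized selection is a discovery tool: shrinkage biases effect sizes
  toward zero, correlated features within a layer are thinned to single
  representatives (except under late integration), and selected features
  warrant experimental validation, not causal interpretation.
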