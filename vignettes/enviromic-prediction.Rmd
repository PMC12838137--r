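---
title: "Enviromic genomic prediction: models, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enviromic genomic prediction: models, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model stack, the priors and numerical choices, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the methodology left room. Nothing stated here goes beyond what the test
suite and `scripts/acceptance.R` actually compute.

## 1. The data and the model stack

The unit of analysis is a within-environment genotype mean of grain yield
(Q/ha), where an *environment* is a site × harvest-year combination. Two
families of models are supported.

**Across environments.** Genotype means are first condensed to best linear
unbiased estimates (BLUEs) with genotype fixed and environment random
(`estimate_blues()`); genomic duplicates — pairs closer than Rogers
distance 0.03, the expected distance of F6-derived sister lines — are
collapsed to a canonical id before fitting and the estimate is copied back
to every member. The BLUEs are then predicted with `GBLUP_D`
(`y = mu + G_a + G_d + e`) or `E_GBLUP_D` (adding `G_aa`).

**Within environments.** The baseline M_1 uses identity covariances for
genotype and environment main effects; M_2 substitutes the genomic kernels;
M_3/M_5 structure the environment effect with the linear/Gaussian
environment kernel; M_4/M_6 add a multiplicative G×E term whose covariance
is the Hadamard product of the row-expanded environment and additive
genomic kernels; M_7/M_8 decompose G×E into site, year, genotype-year
(`YRM ⊙ GRM_a`) and genotype-site parts. The Hadamard expansion is always
done on the rows present in the data (training and prediction rows), never
on level-space matrices, so unbalanced designs and whole-kernel
conditioning for prediction come for free. By the Schur product theorem the
expanded kernels remain positive semi-definite; this is also checked
numerically in the tests.

Genomic kernels follow the standard constructions: VanRaden method 1 for
`GRM_a` (`W W' / 2Σp(1−p)`, `W = codes − 2p`), the orthogonal dominance
coding `{0 → −2p², 1 → 2p(1−p), 2 → −2(1−p)²}` for `GRM_d`, and the
mean-diagonal-normalized Hadamard square of `GRM_a` for `GRM_aa`. Note that
for fully inbred material the diagonal of `GRM_a` is ≈ 2 (inbreeding), so a
variance parameter `σ²_a` contributes `σ²_a · d̄` to the phenotypic
variance; `component_shares()` and `genomic_repeatability()` report on that
phenotypic scale.

Environment kernels are built from 27 daily weather variables aggregated to
monthly means over the October–August season (27 × 11 = 297 environment
variables). The linear kernel is `EV EVᵀ` on column-standardized EVs,
normalized to mean diagonal 1. The distance kernel is `exp(−dist(EV)/θ)`:
the methodology's printed form has a positive exponent, which diverges with
distance, so the package implements the standard decaying kernel, in line
with its description as a Gaussian kernel for environmental effects. θ
defaults to the median off-diagonal Euclidean distance — a common bandwidth
heuristic — and is exposed as a parameter. Year and site kernels are built
the same way from year-mean and site-mean EV rows; with a single site the
year kernel provably reduces to the environment kernel (a unit test).

## 2. Bayesian machinery

`fit_gibbs()` re-implements the RKHS Gibbs sampler of the standard Bayesian
whole-genome regression frameworks. Each random term with kernel `K` is
reparameterized as `u = V D^{1/2} α` (eigendecomposition of `K`,
`α ~ N(0, I σ²_t)`), and `α` is rotated once more into the eigenbasis of
the cross-product of its row design, which makes the full-conditional
covariance diagonal: one joint Gaussian draw per term per iteration, at the
cost of two matrix-vector products. Identity-kernel terms use an exact
indicator fast path.

Two consequences are worth knowing:

* **Unobserved directions are sampled from their prior.** Levels carrying
  no data (e.g. a genotype only present in prediction rows under M_1) get
  fresh prior draws each iteration, so their posterior-mean effect is
  Monte-Carlo noise centered on zero. This is deliberate: it reproduces how
  the reference implementations behave, and it is what makes "prediction
  ability ≈ 0 for new genotypes under M_1" a measurable quantity rather
  than an undefined correlation against a constant.
* **Heterogeneous residuals** (one `σ²_e` per environment, used by the
  variance-decomposition model) are supported only when all random terms
  have identity kernels, because environment-specific weights would break
  the diagonal reparameterization; environments with fewer than 10 records
  share a pooled residual variance.

Priors are scaled-inverse-χ² with `df0 = 5`; scales are set so the prior
mode assigns half the phenotypic variance to the residual and splits the
other half equally among the random terms, mirroring the R²-based defaults
of the cited framework. Reference settings for the sampler are
`nIter = 15000, burnIn = 2000`; all analyses in the tests use desk-scale
settings (1200–6000 iterations, thin 5) after checking that posterior
means are stable at those lengths — effective sample sizes per variance
component are reported in every fit. `blup_oracle()` solves Henderson's
equations in observation space (`V = Σ σ²_t Z K Zᵀ + R`) and is used to
verify the sampler: with variances fixed, posterior-mean effects match the
closed form to RMS < 0.02·SD(y) on 45-row instances.

One prior-driven limit surfaced by the null simulations: with as many
genotypes as observations, the genomic share of a pure-noise trait does not
shrink to zero under this prior — the derived null level of
`genomic_repeatability()` is ≈ 0.3 at n = 200, versus 0.75–0.88 for a
kernel-drawn signal. The tests freeze those derived levels; users comparing
repeatabilities should read them relative to that floor, not to zero.

## 3. The synthetic-data generator

`sim_config()` + the four `simulate_*()` functions emulate the statistical
structure of an integrated line/hybrid trial network:

* **Population.** Fully homozygous lines drawn family-wise: lines within a
  breeding cross share a Beta-distributed family allele frequency
  (defaults: families of ~12 lines, within-family frequency correlation
  0.35), giving the within-family genomic relatedness elite material
  actually has. Without that structure genomic kernels are near-diagonal
  and *no* model could transfer G×E information to unseen genotypes — the
  family structure is what makes the cv3 benchmarks meaningful. A
  configurable divergent subpopulation (a gene-bank stand-in, concentrated
  in the last experimental series) reproduces the one strongly
  differentiated group; hybrids arise from an incomplete factorial of
  female × male parents with marker codes equal to the parental mean; exact
  duplicates are injected under new ids.
* **Weather.** Per site-year, 335 daily records (Oct 1–Aug 31, Feb 29
  dropped) of 27 variables on natural scales: variable mean + site +
  year + site×year effects + daily noise, with per-variable means/SDs from
  a packaged defaults table. No attempt is made at real meteorology
  (seasonality, autocorrelation, cross-variable physics); consequently the
  11 monthly columns of one variable are strongly correlated through the
  shared site/year components, and EV-importance statements are most
  meaningful at the per-variable level.
* **Phenotypes.** Every component is drawn from exactly the covariance the
  models assume (Cholesky with 1e-8 jitter; the G×E matrix uses the
  Kronecker identity `vec(L_G A L_Eᵀ)`), then rescaled so its realized
  variance equals its configured share of the total — recovery tests are
  therefore well-posed, at the price that the *parameter* and the
  *realized* variance coincide by construction. Default shares put G×E at
  one third of the genetic variance, the level reported for elite line
  material; the grand mean (85 Q/ha) and total variance (64) are on the
  winter-wheat yield scale. Environment-main-effect magnitude is not fixed
  by the methodology and is left configurable (default share 0.25).
* **Crop-growth parameters.** `simulate_gs_parameters()` stands in for
  crop-growth-model calibration output: k correlated genotype×site
  parameters with a configurable heritable fraction (default 0.15, the
  level typical of such parameters), genomically structured when a marker
  set is supplied.

What passing tests on these data do **not** show: robustness to real LD
patterns, selection, non-Gaussian G×E, spatial field trends, or weather
measurement error — none of which the generator emulates.

## 4. Validation geometries and benchmarks

`quadrant_plan()` reproduces the four-quadrant scheme: per run, 33% of
genotypes and 33% of environments (`round(frac·n)`) are flagged new;
training is 80% of the known×known quadrant; cv1 is the held-out 20%, and
cv2–cv4 are the complete known×new, new×known and new×new quadrants.
Five-fold plans stack fold predictions within a run before correlating
(10 runs × 5 folds = 50 evaluations); scenario plans hold out one
experimental series and train on 1–6 others; leave-one-environment-out
requires every test genotype to keep ≥ 3 training records. Prediction
ability is the per-test-environment Pearson correlation, averaged per run;
models are compared with paired t-tests on per-run means plus the mean
percent difference. Degenerate test groups (< 3 pairs or zero variance)
are skipped and logged, never zero-filled. Whether "new" genotypes should
be sampled stratified by series is left as a flag (`unstratified` default).

Problem sizes used by the acceptance-style tests (chosen once as
desk-scale study conditions): the M_1 null check runs 20 independent
simulations of 500 genotypes × 20 environments at sparsity 0.5; variance
recovery uses 800 genotypes (lines-only for the additive/error config,
400 lines + 400 hybrids for the six-component config — heterozygous hybrids
are required to separate additive from dominance shares in inbred-heavy
data); the M_6-versus-M_2 benchmark uses 160 genotypes × 10 environments,
20 runs, G×E at 50% of genetic variance with a G×E-free control.

## 5. G×E clustering, importance, and selection

G×E patterns are the residuals of `ŷ = mu + genotype + environment + e`
(all random) fitted to a complete predicted genotype×environment matrix.
Because random-effect estimates are shrunken, those residuals retain a
small remnant of the main effects; the pattern matrix removes the residual
row/column means exactly, making patterns orthogonal to both indicator
spaces — the property every downstream step relies on. Environments are
then clustered by K-means (50 restarts) on the first two principal
coordinates of their pattern distances; with `k = "auto"` the cluster
number maximizes mean silhouette subject to a minimum cluster size
(default 3, as the validation protocol requires; the main-text choice of
at least 6 per cluster is the same knob), with the SSE elbow reported
alongside. `ev_importance()` follows the published protocol (learning rate
0.1, 3000 trees, depth 30, multiclass log-loss early stopping after 100
rounds, repeated stratified 5×3-fold accuracy); tests run reduced tree
counts for runtime, which changes nothing structural.

Core sets are selected by greedy maximization of the average
entry-to-nearest-entry Rogers distance — a documented core-collection
objective family; the exact solver behind the original tool is out of
scope. Reference sets take the top 7% of genotypes by BLUE plus a random 3%
of the remainder (ceiling sizes, seeded sampling); the published absolute
yield thresholds are expressed as these quantile equivalents because
synthetic yields have arbitrary location. Enviromically adapted genotypes
are the per-environment top 10% (ceiling; ties broken by id). Selection
gain compares adapted sets against the top-50-by-BLUE overall performers,
both as deviations from the environment-wise reference mean; their
difference divided by 0.32 Q/ha/year converts the boost into
breeding-progress years. The inequality `gain_adapted ≥ gain_overall` holds
environment-wise by construction (a top-k mean maximizes the k-subset
mean); the scientifically informative statements are the *size* of the
boost under G×E and its collapse to zero without G×E — both tested.

## 6. Numerical conventions and degenerate inputs

* Kernels must be symmetric to 1e-10; eigenvalues in [−1e-8, 0) are
  tolerated as numerical noise, anything lower is lifted by jitter.
* Windowed F_st uses Weir–Cockerham ratio-of-sums in base-pair windows
  (299,999 bp, step 29,999, half-open, 1-based); bp units were chosen over
  marker-index units because the stated window size matches a physical
  scale. Average linkage is used wherever a linkage was unstated.
* Deduplication is single-linkage (transitive closure), canonical id =
  lexicographic minimum; missing marker calls fall back to rounded
  per-marker mean imputation.
* PCo axes carry a deterministic sign (largest-magnitude loading positive);
  K-means uses seeded k-means++-style restarts via `nstart`.
* Constant phenotypes drive all variance posteriors to ~0; non-finite
  phenotypes, empty marker sets after filtering, disconnected
  genotype-environment graphs, missing kernels/parents and too-small
  clusters all raise early, named errors.

## 7. Known limitations

The sampler covers the model families above but not multi-trait or spatial
extensions; REML is not provided (the Bayesian route is the package's
estimation path, the closed-form solver its check). The weather generator's
lack of within-season dynamics limits month-resolved importance claims.
Absolute prediction abilities on synthetic data depend on the configured
variance shares and relatedness and should not be read as forecasts for any
real breeding program — the package's claims are the *structural* ones its
tests assert: null behaviour of identity kernels, oracle equivalence,
variance recovery, model ordering under G×E, cluster and driver recovery,
and the selection-gain arithmetic.
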