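---
title: "Models and methods behind itemnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind itemnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`itemnr` studies item nonresponse ("Prefer not to answer", PNA, code -3;
"I don't know", IDK, code -1) as a heritable behavioural trait and as a
source of selection bias in GWAS. This vignette documents the generative
model, the estimation procedures, the numerical choices, and what the
synthetic data can and cannot establish.

## The generative model

The simulator realizes a causal diagram in which genotypes `G` influence
a target phenotype `Y` (paths `alpha`), a latent general nonresponse
liability `I` (paths `beta`), and a mediator `Z` (SNP-heritability
`delta_snp_mediator`); `Z` also influences `Y` (`eta`); and the
missingness of `Y` is a probit outcome of `Y` itself (`theta`), the
mediator (`gamma`) and the nonresponse factor (`selection_factor_weight`):

```
P(miss_i) = Phi(b0 + theta * Y_i + gamma * Z_i + w * I_i)
```

with `b0` found by bisection so the marginal missingness equals
`target_missing_frac`. This keeps scenarios with different path
strengths comparable at the same missing-data rate. Analyses of the
observed rows implicitly condition on `miss = 0`; when `theta != 0` and
a variant reaches the selection liability through `I` or `Z`, that
conditioning distorts the variant's observed association with `Y`
(collider bias); when all three selection paths are zero the data are
missing completely at random (MCAR) and the observed-data GWAS is
unbiased — both regimes are exercised by the test suite.

**Nonresponse factors.** The PNA general factor is
`sqrt(h2_factor) * std(G b) + sqrt(1 - h2_factor) * e`, with `b` drawn
i.i.d. normal (optionally restricted to a sparse causal set,
`n_causal_nonresponse`). The IDK factor is a `factor_cor`-weighted blend
of the PNA factor and an independently constructed one, so the realized
latent correlation tracks the preset. The default `factor_cor = 0.73` is
a preset taken from the genetic correlation reported between the two
nonresponse forms in observed biobank data; it is an input to the
simulator, never a quantity the package claims to estimate.

**Items.** Item `j` of response type `r` fires its nonresponse indicator
when `lambda_g[j] * I_r + lambda_d * D[dom(j), r] + unique noise`
exceeds a probit threshold `tau_j`. Thresholds are spaced over
`item_threshold_range` (default 1.2–2.2, nonresponse rates roughly
1–12%, PNA the rarer option); IDK thresholds sit `idk_threshold_shift`
lower, making IDK the commoner response, as in real questionnaires. PNA
takes precedence in a cell, so the two codes are mutually exclusive by
construction, mirroring single-choice touchscreen questionnaires. A
fraction `prop_items_idk` (default 0.76) of items offers IDK at all.

**What the generator does not emulate.** Real item content (domains are
exchangeable blocks, not food/health/psychiatric items), participant
drop-off mid-survey (the J-shaped all-PNA tail is only partly mimicked
by the ordinal 0/1/2/3 collapse), dosage uncertainty beyond a stored
INFO field, population structure (PCs are computed but carry no
confounding by default), X chromosome, and item-order effects. Passing
recovery tests on these cohorts shows the estimators are correct under
the stated model, not that real questionnaire data satisfy that model.

## Tetrachoric and polychoric correlation

Estimation is two-step ML: thresholds from the inverse-normal marginal
proportions (after adding 0.5 to zero cells — the standard continuity
correction that keeps estimates finite), then a 1-D profile likelihood
in `rho` over bivariate-normal rectangle probabilities, maximized by
`optimize` on `(-1 + 1e-6, 1 - 1e-6)`. Tables that are perfectly
concordant or discordant are clipped to `±(1 - 1e-6)` and flagged
unconverged. The bivariate normal CDF is an in-package vectorized
implementation of the Drezner–Wesolowsky/Genz quadrature (absolute error
near machine precision; verified against an independent implementation
in the tests). Matrices assembled from pairwise estimates need not be
positive semi-definite; they are repaired by eigenvalue clipping at
1e-8 followed by diagonal renormalization, and the Frobenius norm of the
adjustment is recorded so a user can see how much repair occurred.

## Factor construction

The pipeline follows the phenotype-construction recipe: (1) tetrachoric
matrix of the binary indicators on an 80% split; (2) single-factor
minres (OLS) EFA; (3) complete-linkage clustering of the residual
correlations at distance `1 - |r|`, cut at 0.500 (PNA) or 0.775 (IDK) —
the cut heights are interpreted on this correlation-distance scale,
which is the natural reading given that residual correlations live in
[-1, 1]; (4) collapsing each branch to one indicator (ordinal 0 = no
PNA, 1 = exactly one, 3 = all items, 2 = otherwise; IDK branches are
summed); (5) polychoric correlation of the collapsed indicators (ordinal
treatment preserved for the 4-level PNA scores; Pearson fallback for
long count scales); (6) bifactor EFA; (7) CFA on the 20% holdout; (8)
refit on the full sample and factor scores.

**Rotation.** "Biquartimin" is implemented as the bifactor rotation of
the quartimin family: the quartimin complexity criterion applied to all
factor columns except the first, optimized by gradient projection. The
rotation runs on the *orthogonal* manifold. The oblique variant was
implemented first and found to possess degenerate minima on
exactly-bifactor data in which one group factor is absorbed into the
factor correlations; with orthogonal factors (which is also how the
generative model is built, and how bifactor models are conventionally
identified) the criterion minimum recovers the generative pattern
exactly in the package's tests. Deterministic random restarts guard the
noisy-data case, and a candidate solution is only preferred if its
broadest column still loads on every item — a safeguard against
collapsed solutions.

**Pattern and CFA.** The zero-constraint pattern assigns each item to
the group factor with its largest rotated |loading| if that loading is
at least 0.30 (a conventional salience cutoff); group factors retaining
fewer than 3 items are dropped (identification). The CFA minimizes the
unweighted least-squares discrepancy between observed and model-implied
correlations with orthogonal general and group factors; uniquenesses
absorb the diagonal, and a soft penalty keeps communalities below 1
(Heywood protection). Fit indices are ULS analogues: with
`T = (n-1) * F` and the independence model as null, `RMSEA`, `TLI` and
`SRMR` are computed from the discrepancy and the degrees of freedom.
They are reported, not gated on: the paper-style workflow treats holdout
fit as a sanity check, and the package follows that. These are not
WLSMV statistics; the full asymptotic weight matrix of the polychoric
estimates was judged a large engineering cost with little effect at the
scales this package targets, and the deviation is deliberate.

**Scores.** The "empirical Bayes" factor scores are computed as the
regression-method posterior mean on the liability scale: each ordinal
indicator is replaced by the conditional mean of its latent liability
given the observed category (using the estimated thresholds), then
`E[f | x] = L' Sigma^{-1} x` with the fitted loadings. Uniquenesses are
floored at 0.02 when inverting `Sigma`. The scores are monotone in the
indicators, identical for identical response rows, and standardized
before any association analysis.

## GWAS engine

Per-variant OLS is computed by residualizing phenotype and genotype on
the covariate design (QR-based Frisch–Waugh–Lovell), which reproduces
full-design OLS exactly — including the residual degrees of freedom, so
p-values come from the t distribution, not a normal approximation.
Covariates follow the survey-GWAS convention (sex, age, age², sex×age²,
leading genotype PCs), with age centered before squaring. QC removes
variants at MAF ≤ 0.01, INFO ≤ 0.8, HWE chi-square (1 df) P ≤ 1e-10, or
monomorphic, each with a logged reason. Clumping is greedy on the
p-value ordering: members at `r² > 0.6` within 250 kb of the lead
(positions 1-based, windows inclusive), leads mutually independent at
`r² < 0.1`; LD is computed from the analysis sample's dosages since the
genotypes are simulated. Deming regression compares two sets of betas
with the error-variance ratio `mean(se_y²)/mean(se_x²)`, a jackknife
slope SE, and a two-sided test of slope = 1; the fully per-point ML
variant is out of scope.

## Heckman correction

Stage 1 is a Newton–Raphson probit (score-norm tolerance 1e-8, step
halving, explicit separation diagnostics) of the missingness indicator
on selection covariates — in practice the nonresponse factor scores,
mediator/SES-like variables and demographics. Stage 2 adds the inverse
Mills ratio of the predicted missingness liability,
`lambda = phi(eta)/Phi(-eta)` (asymptotic form `eta + 1/eta - 2/eta³`
beyond `eta = 30`), as a covariate to the GWAS regression. `lambda`'s
own coefficient is variant-independent and is reported once, from the
genotype-free response model; its sign is opposite to the direct
phenotype-to-missingness path `theta` (selection that removes
low-phenotype individuals yields a positive coefficient). Second-stage
standard errors are naive OLS, matching the covariate-in-GWAS
implementation the method mirrors; a nonparametric bootstrap over
individuals is available for the `lambda` coefficient. A collinearity
guard errors when the Mills ratio is linearly explained by the other
response covariates (R² above a threshold) *and* the selection stage
carries signal — with an uninformative probit the ratio is near-constant
and harmless, and flagging it would break the MCAR neutrality property.

**The MNAR demonstration preset.** The causal diagram fixes directions,
not magnitudes, so the preset path strengths were chosen once, by a
design analysis, to make the mechanism demonstrable at n = 20,000 with
200 variants and 40% missingness; they are presets, not estimates. Two
findings from that analysis shaped the preset. First, the per-variant
collider bias transmitted through a nonresponse factor scales inversely
with the square root of the number of variants carrying the factor's
heritability, so the preset concentrates the factor's genetic
architecture on the 20 phenotype-causal variants
(`n_causal_nonresponse = 20`); with a fully polygenic factor the
per-variant bias drowns in GWAS sampling noise. Second, when the SNP
effects on the phenotype and on the factor are correlated, the Mills
ratio doubles as a genetic proxy of the phenotype and the correction
*over*-attenuates true effects — the specification sensitivity that
two-step corrections are known for. The preset therefore draws the two
effect vectors uncorrelated (`alpha_beta_cor = 0`): the removable,
factor-mediated spurious component then dominates the uncorrected bias,
the corrected betas move toward the generative truth, and the Deming
slope of corrected on uncorrected falls below 1 because the corrected
betas shed the spurious dispersion. Users can set `alpha_beta_cor`
nonzero to study the over-correction regime deliberately.

The audit uses the *true* general factor and mediator as selection
covariates, isolating the correction from factor-estimation error
(scored-factor accuracy is tested separately); the mediator also enters
the response model, leaving the nonresponse factor as the exclusion
restriction — mirroring analyses where SES/health proxies enter the
selection stage only.

## Prediction metrics

Logistic models are fitted by IRLS (tolerance 1e-8) with Wald SEs.
Cox–Snell `1 - exp(2(ll0 - ll1)/n)`, Nagelkerke (Cox–Snell divided by
its maximum), and McKelvey–Zavoina `var(Xb)/(var(Xb) + pi²/3)` are all
provided because applied work mixes them; outputs are always labelled.
The McKelvey–Zavoina residual variance is `pi²/3` for the logit link,
with the probit variant (variance 1) available for selection models.
The follow-up participation preset is calibrated so the two general
factors jointly contribute an incremental Cox–Snell pseudo-R² of about
0.056 — the reference scenario for the prediction stage — and the
recovery test compares the estimate against the generative-likelihood
oracle rather than against that constant. Education recoding maps the
seven UKB qualification categories to ISCED-based years (20, 15, 13, 12,
19, 17, 6); nonresponse categories signal exclusion rather than a value.
The question-order trend test is a negative-binomial GLM (log link, ML
dispersion via `MASS::glm.nb`) of per-question nonresponse counts on
presentation order, reporting one- and two-sided p-values.

## Numerical choices and degenerate inputs

* Tetrachoric boundary tables (a zero diagonal or anti-diagonal) are
  clipped to `±(1 - 1e-6)`, not estimated.
* Items with constant indicators are dropped with a warning before
  matrix estimation; an all-degenerate input is an error naming the
  items.
* minres starts at 1 − SMC uniquenesses bounded to [0.001, 1]; an
  (effectively) diagonal input returns the null-loading solution rather
  than an arbitrary degenerate one.
* Dendrogram cuts below the first merge produce singleton branches with
  a warning; above the last merge, a single branch with a warning.
* The probit reports complete separation both when the linear predictor
  diverges and when, at convergence, every observation is classified
  essentially perfectly.
* All simulator stages derive their RNG streams from `seed` plus a small
  fixed offset per stage, so every output is bit-identical under a fixed
  seed and stages can be re-run independently.

## Problem sizes

The shipped tests and the acceptance script run the estimators at the
sizes the package's own recovery analysis uses: tetrachoric recovery at
n = 10⁶ pairs, the factor pipeline at n = 20,000 with 40 items and 4
domains, GWAS calibration over 10⁴ null variants, and the Heckman audit
over 50 replicates of n = 20,000 × 200 variants. These sizes give
Monte-Carlo error comfortably below the tolerances asserted while
keeping a full run in the minutes range on a single core.

## Known limitations

* The correction demonstrably depends on the selection model: omitting
  the nonresponse factor from the probit stage degrades recovery (this
  is itself a tested property), and a misspecified selection model can
  make the correction worse than none — particularly when selection
  covariates are genetically correlated with the outcome.
* WLSMV-style robust fit statistics and standard errors for the ordinal
  CFA are not provided; fit indices are ULS analogues.
* The simulator's LD is exchangeable within blocks; realized dosage
  correlation is attenuated relative to the copula parameter, so LD is
  tuned empirically where exact r² matters (clumping tests supply their
  own LD matrices).
* Polychoric estimation is two-step, not full ML over thresholds and
  correlation jointly; at the sample sizes used the difference is well
  below the asserted tolerances.
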