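---
title: "Bayesian counterfactual mediation for two-arm trials: models, generator and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian counterfactual mediation for two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmediate)
```

## The scientific problem

A two-arm randomised trial of a text-message smoking-cessation programme
measures three candidate mediators — how *important* quitting feels, how much
*know-how* the participant has, and how *confident* they are (each a single
1–10 item) — at baseline and at 1, 3 and 6 months, together with two binary
abstinence outcomes at 3 and 6 months (prolonged abstinence, i.e. at most 5
cigarettes over the window, and 4-week point-prevalence abstinence). The
question is *how* the intervention works: how much of the treatment effect
travels through each mediator?

`cfmediate` answers this with natural direct and indirect effects in the
counterfactual framework. Writing $Y(a, M(a'))$ for the outcome under direct
treatment assignment $a$ with the mediator set at the value it would take
under assignment $a'$, and $p(a, a') = \mathrm{E}[Y(a, M(a'))]$ for the
marginal counterfactual risk, the package reports odds ratios

$$
\mathrm{OR}_{\mathrm{NDE}} = \frac{\mathrm{odds}\, p(1, 0)}{\mathrm{odds}\, p(0, 0)},
\qquad
\mathrm{OR}_{\mathrm{NIE}} = \frac{\mathrm{odds}\, p(0, 1)}{\mathrm{odds}\, p(0, 0)},
\qquad
\mathrm{OR}_{\mathrm{TE}} = \frac{\mathrm{odds}\, p(1, 1)}{\mathrm{odds}\, p(0, 0)}.
$$

The direct effect moves the arm while holding each individual's mediator at
its control-arm value; the indirect effect stays in the control arm while the
mediator moves to its intervention-arm distribution.

### Pairing conventions

Four compositions $p(a, a')$ exist, so two "pairings" of direct and indirect
effects are possible. The definitions above (NDE evaluated at $M(0)$, NIE in
the control arm) are the *pure* natural effects (PNDE/PNIE) and the default
headline (`pairing = "pure"`). The complementary *total* pairing
(`pairing = "total"`, TNDE/TNIE) evaluates the NDE at $M(1)$ and the NIE in
the intervention arm; it is always computed alongside because only mixed
pairings multiply:
$\mathrm{OR}_{\mathrm{TE}} = \mathrm{OR}_{\mathrm{NDE}^*} \times
\mathrm{OR}_{\mathrm{NIE}}$ holds *exactly, per posterior draw* (it is an
algebraic identity of the three odds), and `natural_effects()` records the
maximal per-draw deviation so the identity is verified rather than assumed.
Which pairing a published analysis used is rarely stated; reporting both
makes the choice transparent.

## The two-model estimator

Estimation follows the standard two-regression construction:

1. **Mediator models** (`fit_mediator_model()`): Bayesian linear regression
   of each *standardised* mediator at the interval causally prior to the
   outcome (1 month for 3-month outcomes, 3 months for 6-month outcomes) on
   the arm indicator and the adjustment set — sex, age, intervention version,
   baseline nicotine dependence (FTND, 0–10) and the standardised baseline
   value of the same mediator. Standardisation uses the mean and sample sd
   (denominator $n-1$) of the available observations at that interval, pooled
   across arms; the transform is kept so counterfactual predictions stay on
   one scale.
2. **Outcome model** (`fit_outcome_model()`): Bayesian logistic regression of
   the outcome on arm, the standardised mediator value(s), and the same
   adjustment set (the baseline value of each mediator in the model).

Per posterior draw, the conditional law of the mediator vector under arm
$a'$ is a normal distribution (mean from the mediator model's coefficients,
spread from its residual sd). `counterfactual_risk()` integrates the
logistic outcome model against that law for every covariate row of the
shared analysis sample and averages — the marginalisation population is the
observed (complete-case) covariate sample, so the reported quantities are
adjusted *marginal* odds ratios without any model for the covariate
distribution.

### Integration

Because the mediators are modelled as conditionally independent normals
given covariates, the outcome's linear predictor depends on them only
through $\sum_m b_m M_m$, which is itself univariate normal. The integral is
therefore one-dimensional regardless of how many mediators enter, and
Gauss–Hermite quadrature (default 32 nodes) evaluates it to near machine
precision for both the single-mediator and the joint three-mediator model.
Monte Carlo integration with common random numbers across the four
compositions is retained as an independent second route; the test suite
checks the two agree to three decimals. An optional residual correlation
between mediators exists in the generator (default 0); were it used in
estimation, the same collapse would apply with the appropriate quadratic
form.

### Priors and sampling

Following the reporting conventions of the trial literature: standard normal
priors on every coefficient representing an effect (arm, mediator, and
covariate coefficients alike — continuous covariates are standardised first
so this scale is meaningful), a wide normal (sd 10) on intercepts, and a
half-normal (sd 5) on linear-model residual sds. Point estimates are
posterior medians; 95% compatibility intervals are the 2.5% and 97.5%
percentiles (linear interpolation); `prob_direction` is the posterior
probability that the effect exceeds its null (0 for differences and log
odds, 1 for odds ratios). Odds-ratio summaries take percentiles of the
per-draw OR values; the median is equivariant under monotone transforms, so
the headline estimate does not depend on that choice.

Sampling is by exact conjugate Gibbs rather than gradient-based MCMC: linear
models use the blocked normal/slice sweep, and logistic models use
Pólya-Gamma data augmentation (Devroye's exact alternating-series sampler,
compiled), under which the coefficient update is an exact multivariate
normal draw. The draws are effectively independent — effective sample sizes
near the nominal draw count and split-$\widehat R$ at 1.00 — and there are
no divergent transitions to monitor, because no discretised Hamiltonian is
involved. Defaults are 4 chains × 1000 post-warmup draws (500 warmup). The
diagnostics gate (`check_diagnostics()`) flags any fit with
$\widehat R > 1.01$; in the pipeline a flagged fit aborts the run unless
explicitly overridden. For very short exploratory chains the $\widehat R$
*estimate* itself carries Monte Carlo noise of a few thousandths, so
`run_mediation_pipeline()` exposes the gate threshold.

The attrition models ask a different question — which baseline covariates
predict response, separately by arm — and deliberately include many
covariates plus arm interactions. There the effect coefficients get
Cauchy$(0, \tau)$ priors with a common scale $\tau$ under a half-normal(0, 1)
hyperprior. The Cauchy is expressed as a normal scale mixture
($t_1$), which keeps the sweep conjugate; $\tau$ is updated from its
mixture-marginalised conditional (a partially collapsed step) because the
naive sweep couples $\tau$ to the mixing weights and mixes poorly.

## The synthetic trial generator

No participant-level data from the motivating trial are public, so the
package ships a generator (`simulate_trial()`) whose defaults are the
published study conditions, and every estimator claim is tested as *parameter
recovery* against those conditions:

* **Baseline** (`generate_baseline()`): n = 1012; 81% women; age from a
  normal truncated at the eligibility minimum of 18 whose *truncated*
  mean/sd match the published 45.4 (14) — the latent parameters are solved,
  not copied; FTND rounded and clipped to 0–10 with mean 5, sd 2.2;
  cigarettes per week truncated at 1 (eligibility: at least one per week),
  mean 101, sd 46.2; 6.2% surgery version. Mediator baselines: importance
  9.4 (1.3), know-how 5.5 (2.6), confidence 6.2 (2.5), clipped to the 1–10
  item range. For importance the clip is consequential: a third of the latent
  mass sits above 10, which is precisely the ceiling effect the trial
  reports — but it also means the *observed* moments of generated importance
  (≈ 9.1 (0.95)) sit below the configured latent ones, a deliberate
  trade-off documented here rather than hidden by re-solving latent
  parameters (for a ceiling this strong no normal latent reproduces the
  printed moments).
* **Randomisation** (`randomize()`): permuted blocks of length 2 or 4,
  chosen uniformly at random, stratified by intervention version, 1:1 within
  each block in random order. An incomplete final block is left as-is, so
  the within-stratum imbalance never exceeds max(block)/2 = 2 — exactly how
  block randomisation behaves in the field.
* **Mediator trajectories** (`generate_mediators()`): follow-up value =
  baseline item mean + configured drift + treatment effect + 0.5 × the
  centred baseline item + small centred covariate terms + Gaussian noise,
  clipped to 1–10 (optional rounding to integer scores). Treatment effects
  are *specified on the standardised scale* (defaults are the published
  adjusted estimates: know-how 0.55/0.47/0.47 at 1/3/6 months, confidence
  0.30/0.23/0.32, importance −0.04/0.13/0.10) and the generator solves the
  raw-scale coefficient so the *realised* standardised difference — after
  clipping — equals the configured value. Residual sds are solved so the
  marginal follow-up sd matches the baseline sd.
* **Outcomes** (`generate_outcomes()`): Bernoulli draws from logistic models
  combining a direct arm effect, the standardised mediators at the causally
  prior interval, baseline mediators and covariates. The trial never prints
  arm-specific abstinence proportions, so control-arm rates are free
  parameters, defaulting to ~25% (prolonged) and ~20% (point prevalence):
  deliberately non-rare, so that odds ratios and risk ratios differ and the
  integration machinery is genuinely exercised. Prolonged and
  point-prevalence outcomes use separate coefficient sets with independent
  noise; no nesting is enforced between the two definitions.
* **Attrition** (`apply_missingness()`): response indicators per interval
  from logistic models with a positive age slope everywhere (older
  participants respond more) and, at the 1-month mediator follow-up only, a
  negative baseline-FTND slope confined to the intervention arm — that slope
  *alone* generates the published arm gap (intervention 40% vs control 61%);
  the arm intercepts at 1 month are equal, mirroring the finding that
  dependence fully explained the differential response. Intercepts are
  solved to the published marginal rates (3 months: 41/47%; 6 months:
  36/42%; outcome response rates are not printed and default to ~73/77% and
  ~68/72%). Masking replaces values by missing without touching retained
  ones; the mechanism is MAR given recorded baseline fields.

What the generator does *not* emulate: integer-valued items by default
(continuity keeps calibration smooth; a rounding flag exists), correlated
mediator residuals (parameter exists, defaults to 0 — the real correlation
structure is unknown), non-normal mediator noise beyond the range clipping,
and any within-person longitudinal dependence beyond the baseline
carry-over. Passing recovery tests therefore demonstrates estimator
correctness under these assumptions, not robustness to their violation.

## The brute-force oracle and calibration

`oracle_true_effects()` computes ground truth by simulation: draw a large
synthetic population, build each participant's potential mediator values
under both arms with *common* residual noise, evaluate the true outcome
probability under all four compositions, average, and form the odds ratios,
with Monte Carlo standard errors from batch means. Because the truth is
evaluated as probabilities (not sampled outcomes), a population of a few
hundred thousand gives per-mille precision in seconds.

`calibrate_to_target()` inverts the oracle: a one-dimensional monotone
search (geometrically widened bracket, then root finding on a fixed-seed —
hence deterministic and continuous — oracle) rescales the mediator→outcome
coefficients (for a target NIE), the direct effect (for a target NDE or total
effect), or sets the standardised mediator effect. This is how every
recovery test pins the generator truth to a published estimate before asking
the estimator to find it.

Two estimand subtleties the oracle made visible:

* In a single-mediator analysis, mediators outside the analysed set follow
  the *direct* arm in the oracle's compositions — they are part of the
  non-mediated pathway, which is what the single-mediator two-model
  estimator actually estimates when other pathways exist.
* The arm coefficient of a covariate-adjusted logistic model is a
  *conditional* odds ratio and exceeds the marginal one whenever covariates
  (or omitted mediators) carry real risk heterogeneity — odds ratios do not
  collapse. `fit_total_effect()` therefore reports both the conditional
  coefficient and an adjusted marginal OR obtained per draw by averaging
  predicted risks over the observed covariates under each arm; comparisons
  against the oracle's marginal truth use the latter.

## Missing data

The headline analyses are available-data (complete-case): a row enters a
mediation fit only when arm, the adjustment set, the mediator(s) at the
prior interval and the outcome are all observed, and the row subset is
recorded with each fit. The sensitivity analysis (`impute_chained()`) is
multiple imputation by chained equations: continuous mediators by predictive
mean matching (type-1 draw, donor pool 5, so imputed values are always
observed values), binary outcomes by approximate Bayesian logistic draws;
variables visited in ascending missingness, 20 cycles, m = 20 by default
(conventional choices, stated in the run manifest). Each variable's model
conditions on the baseline covariates, arm, and all other analysis
variables, keeping the imputation congenial with analyses in which mediators
and outcomes appear jointly. Fits across completed datasets are combined by
`pool_posteriors()`, which concatenates draws into a mixture posterior —
within- plus between-imputation uncertainty without a normality assumption.

One honest caveat: under this generator's MAR mechanism the missingness
depends only on covariates that the adjusted models already condition on, so
complete-case estimates are themselves consistent and imputation mainly
propagates uncertainty; the tests accordingly assert that both routes cover
the truth, not that imputation is closer.

## Numerical choices and degenerate inputs

* Gauss–Hermite nodes from `pracma::gaussHermite`, rescaled for the normal
  kernel; 32 nodes default (64 in the cross-route agreement test); the
  integrand is bounded and analytic, so the rule converges fast.
* Residual sd → 0 collapses the integral to the plug-in of the conditional
  mean; mediator coefficients = 0 collapse it to the mediator-free logistic
  probability — both are unit-tested limits.
* Standardisation refuses degenerate (zero-sd) references; fits refuse
  fewer than 25 usable rows (naming the interval); the attrition model
  refuses constant responses; the oracle refuses non-positive populations.
  Possible complete separation in an outcome model is detected on a
  maximum-likelihood sidecar fit and flagged in the diagnostics (the
  posterior itself stays proper under the normal priors).
* Internal calibration (latent truncated-normal parameters, raw-scale arm
  coefficients, standardisation constants, attrition intercepts) runs once
  per configuration on a 200k deterministic sample under a private RNG
  stream, cached in the config object and keyed on the parameters it depends
  on; user-visible seeds never touch it.
* All seeds are explicit; stage seeds derive from a master seed by fixed
  offsets, kept within the 32-bit integer range.

## Problem sizes used in the shipped studies

The recovery studies run at the published design size where the claim is
about the trial (attrition realism: 100 replicates of n = 1012) and at
n = 4000–5000 for coefficient and effect recovery, where the posterior is
narrow enough that the published tolerance is several posterior sds wide.
The estimator-vs-oracle equivalence study uses n = 20,000 so that estimator
bias, not sampling noise, would be the binding constraint. Unit tests use
smaller sizes of the same structure. These sizes are the package's own
choices for sharp yet fast checks; nothing about the methods depends on
them.

## Known limitations

* No exposure–mediator interaction terms, matching the models as described;
  with such interactions the two pairings differ more and the estimator
  would need the interaction-aware mediation formulas.
* No sensitivity analysis for unmeasured mediator–outcome confounding; in a
  randomised trial the arm is exogenous but the mediator is not, and the
  no-confounding assumption for the mediator–outcome edge is untestable.
* The linear mediator model is misspecified at hard ceilings (importance);
  recovery of near-null indirect effects remains accurate there, but strong
  indirect effects through a heavily clipped mediator would inherit bias.
* MNAR mechanisms (delta adjustment, pattern mixture) are out of scope.
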