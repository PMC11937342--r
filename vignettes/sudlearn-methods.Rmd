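---
title: "Self-Utility Distance and trait-utility learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-Utility Distance and trait-utility learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sudlearn)
```

## The construct

People hold a profile of beliefs about which traits describe them
(self-ratings) and a second profile of beliefs about how *useful* those
traits are in their current life (utility ratings), both expressed on a
1–100 slider over a fixed list of trait adjectives. **Self-Utility
Distance (SUD)** is the mean absolute difference between the two
profiles,

$$\mathrm{SUD} = \frac{1}{K'}\sum_{k \in \text{usable pairs}} |s_k - u_k|,$$

a Manhattan distance normalised by the number of usable trait pairs so
that subjects with occasional missing responses remain comparable. High
SUD signals a perceived misfit between what one is and what one believes
is useful — a standing "change signal" hypothesised to erode
self-concept clarity. The package also exposes the two control metrics
used to probe robustness: the plain Euclidean distance and the Pearson
correlation between profiles (a *similarity*, so its associations flip
sign). The same machinery computes ideal-self and ought-self
discrepancies by swapping in the respective comparison block.

Design choices worth stating explicitly:

* **Pairwise deletion.** A trait pair is dropped when either side is
  missing; `n_pairs_used` is reported so downstream analyses can filter.
* **Euclidean is not normalised** for missingness — it is the plain
  root-sum-of-squares; users who need comparability under missingness
  should use the default metric.
* **Exclusion rule.** Subjects missing strictly more than 20% of their
  expected responses are excluded; exactly 20% is retained. The rule is
  applied per supplied response set.
* **Questionnaire scores** (12-item Self-Concept Clarity on a 5-point
  scale, 10-item Self-Esteem on a 4-point scale) are item sums after
  reflecting reverse-keyed items (`min + max - x`). Sums rather than
  means keep integer arithmetic exact; correlations are unaffected by
  the choice. Reverse-key sets default to the published standard keys
  (`default_reverse_keys()`) and are configurable, since key sets
  occasionally differ between translations. A subject with any missing
  item gets a missing score — no imputation.

## The five learning models

In the learning task a subject works through $T = 50$ trials, one trait
each. On trial $t$ they hold a self-rating $S(t)$, state a utility
estimate $U(t)$, and then see feedback $F(t)$ — the average utility
rating of that trait in an independent reference panel. The prediction
error is defined on the *stated response*:

$$\mathrm{PE}(t) = F(t) - U(t).$$

Missed responses contribute no prediction error. Five generative
models compete to explain the response series:

**Model 1 (no learning).** $P(t) = \beta_0 + \beta_1 S(t)$: utility
estimates are a linear read-out of the self-concept; feedback is
ignored.

**Model 2 (fine granularity).** A Rescorla–Wagner learner whose errors
generalise across traits through an inter-trait similarity matrix
$\mathrm{SIM}$:

$$P^m(t) = P_\mathrm{init} + \sum_{i < t} \alpha \,\mathrm{PE}(i)\,
  \mathrm{SIM}(i, t), \qquad P(t) = P^m(t).$$

Every answered trial strictly before $t$ contributes, weighted by the
signed similarity between the trait seen then and the trait seen now.
Negative similarities spread sign-flipped updates; no truncation is
applied.

**Model 3 (asymmetric rates).** As Model 2, but the learning rate is
$\alpha_+$ when the feedback lies closer to the self-rating than the
current prediction does ($|F - S| < |P - S|$: feedback pulls the
estimate *toward* the self-concept) and $\alpha_-$ otherwise. Ties use
$\alpha_-$, because the condition is a strict inequality. For the
mixture models below the comparison defaults to the emitted prediction
$P$; a switch (`compare_at = "learning"`) compares at $P^m$ instead,
since either reading is defensible.

**Model 4 (self-adjusted).** Model 2's learning component is mixed with
the trait's own self-rating,

$$P(t) = \gamma\, S(t) + (1 - \gamma)\, P^m(t), \qquad \gamma \in (0, 1),$$

so $\gamma$ measures how strongly the current self-concept anchors
utility estimates against feedback-driven learning.

**Model 5.** Model 4 with Model 3's asymmetric rates.

Initial predictions are $P_\mathrm{init} = 80$ for every trait,
reflecting high prior expectations about trait utility; the variant that
initialises each trait at the subject's own self-rating
(`p_init = "self"`) is available for sensitivity analyses (with
$\alpha = 0$ it pins $P^m(t) = S(t)$).

The sum bounds are deliberately implemented as "all strictly earlier
trials, starting from trial 1": each trial's error updates all upcoming
estimates.

### Observation model

The task description does not pin down a response likelihood, so the
package adopts the simplest one consistent with continuous slider data:
$U(t) \sim \mathcal{N}(P(t), \sigma)$ on answered trials, with a free
per-subject $\sigma$. Simulated responses are rounded and clipped to the
integer 1–100 slider; likelihood evaluation ignores the censoring at
the bounds. This is an explicit modelling assumption: with predictions
concentrated well inside the scale and $\sigma \le 15$, boundary
censoring is rare, but fits to data pinned at the extremes would
misestimate $\sigma$ slightly.

### Similarity matrix and feedback

Both are computed from a reference panel's utility ratings:
$\mathrm{SIM}(j,k)$ is the Pearson correlation between the panel's
columns for traits $j$ and $k$ (pairwise-complete, diagonal forced to
1), and the feedback for trait $k$ is the panel's column mean rounded
half-up to the integer display scale. Zero-variance panel columns are
an error, named per trait.

## Hierarchical inference

Parameters are estimated in a transformed space — logit for
unit-interval parameters, log for $\sigma$, identity for the regression
coefficients — under independent Gaussian priors with mean 0 and
variance 6.25 per coordinate ("wide" on all three scales; the value is
the convention of the hierarchical-modelling toolbox literature and is
configurable).

**Subject level.** `fit_subject_map()` maximises the log-posterior by
BFGS from the prior mean plus 10 random restarts (central-difference
gradients computed in compiled code), then approximates the log model
evidence by Laplace:

$$\log Z \approx \log p(y \mid \hat z) + \log p(\hat z) +
  \tfrac{d}{2}\log 2\pi - \tfrac12 \log \det H.$$

Hessian eigenvalues are floored at the prior precision before taking
the determinant: the curvature of a negative log-posterior cannot be
flatter than its Gaussian prior along any direction, so eigenvalues
below that floor indicate an unidentified parameter combination (for
example the rate asymmetry of Model 5 on data generated with equal
rates) and are treated at prior width. Without the floor, near-singular
Hessians inflate the evidence of over-parameterised models by several
nats and corrupt model comparison; truly non-positive-definite
Hessians are additionally flagged with a warning. On linear-Gaussian
configurations the approximation is exact; on two-parameter nonlinear
toys it agrees with dense grid integration to better than 0.1 nats
(both are asserted in the test suite).

**Group level.** `fit_hierarchical()` treats model identity as a random
effect. Responsibilities $u_{nm} \propto \exp(\log Z_{nm} +
\mathbb{E}[\log f_m])$ and Dirichlet concentrations $\alpha_m =
\alpha_0 + \sum_n u_{nm}$ (prior $\alpha_0 = 1$ per model) are iterated
to convergence; model frequencies are $\alpha_m / \sum \alpha$. The
evidences entering this layer are the ones computed under the **shared
initial wide prior**, and they stay fixed. This is a deliberate design
decision: if each model's evidence were recomputed under a group prior
re-estimated from the same data, a richer nested model (Model 5
relative to Model 4) could tighten its prior around the region its
surplus parameter does not need and escape its complexity penalty — in
our simulations that exactly halves the winning model's frequency and
destabilises the fit. Comparing all models on one fixed wide prior (the
prior the fitting procedure itself declares) keeps the Occam penalty
intact.

The empirical-Bayes iteration then serves parameter estimation:
each model's group mean and variance are updated as
responsibility-weighted moments of the subject-level posteriors (MAP
plus Laplace variance), regularised by one pseudo-subject at the wide
prior, with the group variance bounded between $10^{-3}$ and the wide
prior variance (shrinkage only ever tightens); subjects are refit under
the updated group priors, warm-started from their previous optimum with
2 fresh restarts. Convergence is declared when no transformed group
mean moves by more than 0.02 (default cap: 8 sweeps).

**Model comparison.** The exceedance probability $EP_m$ — the posterior
probability that model $m$ is the most frequent — is estimated from
$10^5$ Monte-Carlo Dirichlet draws. The Bayes omnibus risk compares the
variational free energy of the random-effects model against the
equal-frequency null on the same evidences,
$\mathrm{BOR} = 1/(1 + e^{F_1 - F_0})$, and the protected exceedance
probability shrinks EP towards chance accordingly:

$$\mathrm{PXP}_m = EP_m (1 - \mathrm{BOR}) + \mathrm{BOR}/M.$$

On cohorts simulated from Model 4 under the recovery design below, the
five-model comparison selects Model 4 with $\mathrm{PXP} \approx 1$ and
a model frequency around 0.93; when the generating $\gamma$ is pushed
to 0, selection migrates to Model 2, as it must at the nested boundary.

## Validation designs

**Parameter recovery** (`parameter_recovery()`) simulates 85 subjects
with 50-trial sessions against a synthetic 232-rater panel, with true
parameters drawn as $\alpha \sim U(0.02, 0.5)$,
$\gamma \sim U(0.05, 0.6)$, $\sigma \sim U(5, 15)$ — ranges chosen to
bracket the fitted population values — then refits hierarchically and
correlates true against recovered values in natural space. Under these
conditions $r(\gamma)$ is typically around 0.95–0.97 and $r(\alpha)$
around 0.83–0.93 across seeds. We verified that this is the information
limit of the design rather than an estimator artefact: unregularised
per-subject fits recover $\alpha$ *worse* than the hierarchical
estimates, and in the noiseless limit ($\sigma \to 0$) both
correlations reach 1.0 exactly. Higher published recovery figures are
attainable when the similarity matrix has stronger structure and
feedback varies more across traits than the synthetic panel provides.

**Model confusion** (`model_confusion()`) simulates cohorts from each
generating model, fits the full model set, and tabulates the PXP winner.
With generating parameters kept away from the overlap manifolds (the
no-learning regression coincides with the self-adjusted learner at
$\alpha = 0$, $\beta_0 = (1-\gamma)\,80$, $\beta_1 = \gamma$; the
dual-rate models coincide with their single-rate parents at
$\alpha_+ = \alpha_-$), the diagonal dominates each row.

## The synthetic generators

`gen_reference_panel()` emulates the rater panel with a latent-factor
model: `clip(round(50 + loadings %*% factors + noise), 1, 100)` with 4
factors, loading SD 8 and noise SD 6 by default — values chosen once to
produce a realistic spread of signed inter-trait correlations
(off-diagonal range roughly $\pm 0.5$). Because all trait means sit at
50, panel-derived feedback is nearly uniform across traits; real trait
utilities vary more, which is one reason synthetic recovery should not
be read as an upper bound on real-data recovery.

`gen_survey_cohort()` generates self/utility (optionally ideal/ought)
blocks with known per-trait offsets $\delta_{ik} = \text{scale}_i \,
e_{ik}$ (log-normal per-subject scale, standard-normal $e$), so true
SUD is known by construction, and maps standardised SUD plus a latent
esteem factor onto discretised questionnaire scores through a linear
link. The default link coefficients (0.37 on $-$SUD, 0.42 on esteem,
residual SD 0.7376, esteem–SUD correlation $-0.46$) were derived once
from the latent correlation algebra so that the simulated cohort
reproduces survey associations of the published magnitude
($r(\mathrm{SUD}, \mathrm{SCC}) \approx -0.56$); they were not adjusted
afterwards. What the generator does **not** emulate: the semantic
structure of a real adjective lexicon, valence asymmetries, response
styles (acquiescence, scale-end avoidance), or item-level questionnaire
noise. Passing tests on synthetic cohorts therefore demonstrate the
correctness and statistical behaviour of the pipeline, not empirical
claims about human raters.

`gen_learning_cohort()` produces closed-loop sessions via
`simulate_subject()` — each simulated response feeds the model's own
subsequent predictions, as in the task — and persists the generating
parameters for oracle-based tests.

## Survey statistics

The association layer works from raw data or directly from a printed
correlation matrix with its sample size; the two modes agree to
$10^{-10}$ when the matrix comes from the same data. Conventions:
standardised coefficients standardise both outcome and predictors;
adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-p-1)$; the $R^2$-change test is
$F = \Delta R^2 / ((1-R^2_\mathrm{full})/(n - p_\mathrm{full} - 1))$;
confidence intervals for correlations use the Fisher $z$ transform,
which reproduces the published intervals to their printed precision;
commonality components come from the all-subsets inclusion–exclusion
identity and sum to the full $R^2$ by construction; best-subset
selection uses $\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n$ with
$k$ counting predictors, intercept and error variance. The temporal
test on absolute prediction errors regresses $|\mathrm{PE}|$ on a cubic
B-spline of trial number (3 interior knots at trial quantiles) with
subject fixed intercepts and F-tests the spline block — a fixed-knot
simplification of a penalized GAM smooth, whose estimated effective
degrees of freedom are toolbox-specific and deliberately out of scope.

One caveat surfaced while cross-checking the published survey tables:
the printed standardised coefficients of the two-predictor model are
not reproducible from the printed correlations under the
both-standardised convention (which implies 0.417/−0.375 rather than
0.351/−0.316, consistent instead with an unstandardised-outcome
convention). The package therefore treats $R^2$, its decomposition and
the F statistics — which *are* reproducible — as the anchor quantities.

## Problem sizes and determinism

Every stochastic function takes a mandatory seed and is bit-for-bit
reproducible under it. The bundled validation runs use cohorts of 85
subjects for recovery and model selection (10 recovery seeds for model
selection, 3 for parameter recovery, 40-subject cohorts for the
nested-boundary check), which keeps the full suite within desk-scale
runtimes while matching the study's cohort size. The Monte-Carlo sample
for exceedance probabilities is $10^5$ draws (standard error below
0.002 on any EP).

## Known limitations

* The hierarchical scheme is an empirical-Bayes approximation to full
  hierarchical Bayesian inference: group posteriors are point-estimated
  and subject evidences are Laplace approximations, so it will not
  reproduce a variational toolbox's numbers exactly, only its
  decisions.
* The Gaussian observation model ignores slider censoring and
  integer rounding.
* Commonality analysis is exponential in the number of predictors
  (capped at 12; the surveys use 2–4).
* The no-learning and self-adjusted models overlap on a parameter
  manifold; confusion analyses should sample generating parameters away
  from it, as the defaults do for recovery but any user-supplied
  sampler must too.
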