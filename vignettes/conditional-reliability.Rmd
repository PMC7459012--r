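---
title: "Conditional reliability at the cut score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional reliability at the cut score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

High-stakes multiple-choice exams decide who passes and who fails. A single
global reliability coefficient (Cronbach's alpha) says how precisely the exam
measures *on average*, but a pass-fail decision is made at one point of the
score scale — the cut score — and measurement precision varies across the
scale. The conditional standard error of measurement (cSEM) describes the
error attached to each individual score, and its standardisation at the
between-person score variance,

$$\mathrm{cRel}(x) = \frac{\sigma_x^2 - \mathrm{cSEM}(x)^2}{\sigma_x^2},$$

yields a score-level reliability coefficient comparable across exams. The
package computes this quantity in two psychometric frameworks and compares
them at the cut score:

* **CTT** — the binomial error model gives
  $\mathrm{cSEM}(X) = \sqrt{X(k - X)/(k - 1)}$ for a score of $X$ points on a
  $k$-item test. The error is largest at 50% correct and vanishes at the
  floor and ceiling, so the CTT conditional reliability curve is U-shaped:
  most reliable exactly where nobody's decision is close.
* **IRT** — under a one-parameter logistic (Rasch) partial credit model the
  squared cSEM on the ability metric is the inverse of the test information
  function, $\mathrm{cSEM}(\theta) = 1/\sqrt{I(\theta)}$. Information peaks
  where item difficulties concentrate — for a well-targeted exam, mid-scale —
  so the IRT curve is unimodal with its *maximum* where the CTT curve has its
  minimum.

Because typical cut scores sit near the middle of the scale, the two
frameworks reach systematically different conclusions about the precision of
the pass-fail decision; that inversion, and what drives it, is what the
pipeline quantifies.

A note on the standardisation: some presentations write the numerator as
$\sigma_x^2 - \mathrm{cSEM}$ without the square. The package uses the squared
form throughout; it is the dimensionally consistent one (variance minus
variance) and the one under which $\mathrm{cRel} \le 1$ with equality exactly
where the cSEM vanishes.

## The model

Items are of two kinds. Single-best-answer ("type A") items are scored 0/1
and carry one difficulty parameter. Multiple true-false (MTF) items present
four independent true/false ratings and are scored by partial credit: one
point when all ratings are correct, half a point when more than half are,
zero otherwise (`score_mtf_item()`). For all latent-trait computation the
half-point categories are rescaled to ordered integer categories
$\{0, 1, 2\}$ with a fixed weight of 0.5 points per category step, because
the partial credit model is defined on integer categories. The category
probabilities are

$$P(X_i = x \mid \theta) \propto \exp\!\Big(x\theta - \sum_{j \le x}
\delta_{ij}\Big),$$

with one step parameter $\delta_{i1}$ for type A items and two for MTF items.

**Estimation.** `fit_pcm()` maximises the marginal likelihood by EM over an
equally spaced quadrature of 41 nodes on $[-6, 6]$ with normal weights. The
latent trait is identified by fixing its mean at 0; its SD is estimated (an
exact 1-D M-step on the grid-normalised prior), so that person-separation
statistics reflect sample heterogeneity — essential here, since range
restriction is one of the influencing factors under study. Item M-steps are
safeguarded Newton updates with analytic gradients and Hessians, with
step-halving against the expected complete-data log-likelihood, so every EM
iteration is an ascent; the iteration trace is stored and tested to be
monotone. Convergence is declared when the marginal log-likelihood gains
less than `tol` (default `1e-5`); hitting `max_iter` flags the fit rather
than erroring. Items whose observed responses occupy fewer than two
categories are unidentified and produce an explicit error naming the item;
the study pipeline drops constant items (classical difficulty 0 or 1) from
the analysed form up front. Step parameters are bounded at $\pm 10$ logits,
which is where an MTF step lands when its middle category is (nearly)
unobserved.

**Person estimation.** `wle_theta()` solves Warm's weighted likelihood
equation $\ell'(\theta) + I'(\theta)/(2I(\theta)) = 0$, where
$\ell'(\theta)$ is the raw-score residual and $I'(\theta)$ is the sum of
third central category moments (the derivative of the information). The
correction keeps estimates finite for zero and perfect scores. In the Rasch
family the total category score is sufficient for $\theta$, so the equation
is solved once per distinct raw score, by bisection on $[-8, 8]$ (widened
automatically if a bracket fails); the SE is $1/\sqrt{I(\hat\theta)}$, which
for this model family is both the observed and expected information.

**Curves.** The CTT curve is evaluated on the full achievable score grid
(0.5-point steps when MTF items are present), in percent of maximum points;
achieved scores are marked, since the open question of whether to summarise
over the grid or over achieved scores matters for the report: maximum and
mean conditional reliability are taken over *achieved* scores (for IRT, over
the ability estimates corresponding to achieved raw scores) — the grid
extremes always have cRel = 1 in CTT and would make grid-based maxima
uninformative. The IRT curve standardises by the variance of the WLE ability
estimates. Which variance should standardise the IRT cSEM is genuinely open
(WLE variance, EAP variance, or the model's latent variance); the WLE
variance was chosen because the same estimates feed the separation index, so
alpha and the separation index are exact analogues. Each $\theta$ grid point
is annotated with its expected percent score through the test characteristic
curve — strictly increasing, hence invertible — so both frameworks share a
percent-correct x-axis. Conditional reliability at the cut is read off by
linear interpolation between the two flanking grid points; the grids are
dense (one point per achievable score), so the interpolation error is
negligible. Negative conditional reliabilities (possible in homogeneous
cohorts where the mid-scale cSEM exceeds the score variance) are reported
as-is and flagged, never truncated.

**Fit diagnostics.** Residuals $r_{vi} = x_{vi} - E(X_i \mid
\hat\theta_v)$ use the WLE point estimates, matching the person-estimation
choice. Yen's Q3 is the correlation of residual columns over item pairs; the
headline summary is the mean *absolute* Q3, with the signed mean alongside,
because the signed statistic has a small negative expectation near
$-1/(k-1)$ under local independence (the calibration tests verify exactly
that), and a positive "mean Q3" can only be an absolute-value summary.
Infit is the information-weighted mean square $\sum r^2 / \sum W$, outfit
the unweighted mean of $r^2/W$; cells with numerically saturated
probabilities are excluded and counted. SRMR and SRMSR compare observed and
model-implied inter-item correlations (the implied matrix integrates item
expectations over the fitted latent distribution): SRMR is the mean absolute
off-diagonal residual, SRMSR the root mean square, so SRMSR ≥ SRMR by
construction. Misfit bounds for the mean squares default to $[0.8, 1.2]$,
configurable; the bounds are a reporting convention, not a test.

## Study-level comparison

Each exam contributes one row: conditional reliability at the cut in both
frameworks, alpha and the separation index, the observed performance range
(max minus min percent score), item count, percent MTF, school and study
year. `paired_theory_anova()` runs the two-level repeated-measures ANOVA
(equivalently the squared paired t) with partial
$\eta^2 = SS_{theory}/(SS_{theory}+SS_{error})$.
`stacked_regression()` stacks the report into one row per exam × framework
and regresses cut-score conditional reliability on a framework indicator
(0 = CTT, 1 = IRT), performance range, item count, school and percent MTF
plus the four framework interactions — nine predictors, so 32 exams give
F(9, 54). School enters as a single numeric code rather than dummies, which
keeps the table at one row per influencing variable; with three schools this
imposes an ordinal coding, a deliberate simplification. Standardised betas
come from refitting on z-scored variables, with interaction columns
standardised after the product is formed. `collinearity_screen()` flags
predictors with |r| > 0.7 against a retained predictor and excludes year of
study first — in range-restricted cohorts year and performance range are
nearly redundant, and range is the more proximal predictor.

## What the synthetic generator emulates

No public exam-level data exist for this kind of high-stakes cohort, so the
generator is a first-class module and the analysis' only data source. It
draws, per exam: item count uniform on 59–150; MTF fraction from a normal
(mean 0.306, SD 0.08) truncated to 0.19–0.53; cut score from a normal
(mean 56.6, SD 4.7) truncated to 47.5–70 percent; examinee count uniform on
146–378. Item locations come from a left-skewed two-component mixture — 85%
N(−0.8, 0.9²) plus a 15% easy tail N(−2.5, 1²) — chosen so that classical
difficulty averages about 0.69 while spanning nearly the whole unit
interval, and so that the exam carries real information at the low end of
the ability scale; that low-end information is what pushes the IRT curve's
minimum to the very high scores rather than to both extremes. MTF steps are
placed at centre ± spread with spread uniform on 0.4–1 logits. Abilities
are normal with mean 0 and SD 0.7; the SD calibrates the generator to the
grand reliability level characteristic of such exams (alpha ≈ 0.85 at
around a hundred items). Range restriction is modelled by symmetric
truncation of the ability distribution with half-width
$2.75 - 0.45\,(\mathrm{year}-1)$ SD units as exams cycle through study
years 1–5, which reproduces a strong negative year-range correlation and
first-to-fifth-year homogenisation with minimal assumptions. Responses are
drawn from the same partial credit model used for analysis — the design
decision that makes parameter recovery a meaningful check on the estimator.
MTF responses are generated directly at the category level; the
rating-level scoring rule (`score_mtf_item()`) is provided separately for
scoring raw data, since no rating-level response model is assumed.

What the generator does *not* emulate: distractor behaviour within type A
options, multidimensional abilities, missing data, item-level drift or
local dependence, and real item-review workflows (post-hoc eliminated items
are supported only as a drop list). Passing shape and direction checks on
these synthetics therefore shows that the *pipeline* reproduces the
theoretical contrast between frameworks under realistic exam geometry — not
that any particular real exam behaves this way.

## Numerical choices and problem sizes

Quadrature: 41 equally spaced nodes on [−6, 6]; EM tolerance `1e-5` on the
log-likelihood, `max_iter` 1000. WLE bisection: 80 halvings on [−8, 8],
giving far better than `1e-6` precision; TCC inversion: 60 halvings on
[−10, 10]. Degenerate inputs are errors with explicit messages (fewer than
two examinees, zero score variance, unidentified items, cuts outside a
curve's support) except where a flagged value is more informative (negative
conditional reliability, non-converged EM).

The test suite exercises the full study design at its natural size — one
32-exam study with the default generator bands — and uses reduced designs where
replication across studies matters more than scale: the range-restriction
sign checks run five replicate studies of 16 exams (120–220 examinees,
50–90 items), and parameter recovery uses a dedicated design with type A
locations uniform on [−2, 2] and MTF centres on [−1.5, 1.5] (spread
0.4–0.8), which keeps every category observable at moderate samples, with
the RMSE pooled over three response replicates per sample size (a
single-replicate RMSE is itself a noisy Monte-Carlo estimate); these
sizes are the package's choice of a convincing-but-economical simulation
budget. The EM oracle check compares against an exhaustive 0.05-step grid:
a full grid over two items, and cyclic coordinate-wise exhaustive grid
ascent plus direct BFGS maximisation of the marginal likelihood for the
five-item instance, where a joint 0.05 grid over seven step parameters
(about $10^{13}$ evaluations) is not a computable oracle.

## Known limitations

* The binomial error model assumes integer scores; with MTF half-points the
  formula is evaluated on the points scale with $k$ the maximum points, the
  same pragmatic extension implicit in applying the model to mixed-format
  exams.
* School as a numeric code (see above) is an ordinal simplification; with
  more schools, dummy coding would be preferable.
* MTF steps with unobserved middle categories saturate at the ±10 bound
  rather than being re-parameterised; affected items are rare at realistic
  sample sizes and show up clearly in the fit report.
* The separation index uses WLE estimates; EAP-based indices would be
  slightly shrunken and are not provided.

## Reproducibility

Every generator function takes an explicit seed and is deterministic given
`(config, seed)`; `run_study()` derives per-exam seeds from the study seed,
and `scripts/acceptance.R` derives all of its seeds from a single `--seed`
argument. Outputs written by `write_study_outputs()` are regenerable from
the manifest's configuration and seed alone.
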