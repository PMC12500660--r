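---
title: "Models and methods behind shiftsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shiftsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftsleep)
```

`shiftsleep` implements a complete, synthetic-data-driven pipeline for
studying how circadian type (CTI flexibility and languidness) and
objective shift-work demands jointly shape sleep quality (PSQI) and
depressive symptoms (PHQ-9) in rotating-shift nurses. This vignette
records the models, the parameter choices and the reasoning behind the
places where the design was genuinely open.

## 1. The synthetic cohort generator

### Marginals

Each bounded instrument score is modelled as a beta distribution
rescaled to its support and rounded to integers. A two-parameter family
is the smallest one able to match two summary targets on a bounded
support, and the beta is the canonical choice. The shape parameters are
solved by least squares over *quantile anchors expressed in score
units*:

* the median (PSQI 8, PHQ-9 7, FR 12, LV 18.5),
* the interquartile range (4, 5, 6, 6),
* where a clinical screening prevalence is reported, the corresponding
  cutoff quantile: 51.39% above PSQI 7 and 24.31% at or above PHQ-9 10.

The third anchor deserves a comment. Matching the *continuous* median
exactly at 8 centres the rounded cell 8 on probability 0.5 and
necessarily places about 56% of the mass above 7 — no smooth
two-parameter fit can then reproduce the reported insomnia prevalence.
Because the screening prevalences are first-class published marginals,
and because downstream screening analyses depend on them, the
calibration treats all three targets as quantile constraints and takes
the least-squares compromise. The realized large-sample values are:
median 8 and IQR 4 exactly, insomnia prevalence 53.9% (reported 51.39%),
depression prevalence 25.2% (reported 24.31%).

BMI uses the same machinery with the published category proportions as
anchors (6.3% under 18.5, 82.0% cumulative under 24, 98.6% under 28) and
stays continuous. Age is discrete-uniform on 24–44; its realized median
(34) is within the one-unit tolerance of the reported 33.5 without
post-stratification, so none is applied. Gender is Bernoulli with
P(female) = 0.8958.

The demand-side marginals (night count, shift work hours, workload
exposures) are centred on the typical 4-week demand condition — 4
nights, 44 shift hours, shift workload exposure 147 — with IQRs chosen
once at realistic roster scale (2, 22, 70 respectively); the full
empirical distributions are not published.

### Dependence

Dependence is a Gaussian copula. Each target Spearman correlation is
converted to the latent Pearson correlation by the exact bivariate
normal identity $r = 2\sin(\pi\rho/6)$. The published significant pairs
(sleep–depression 0.560, sleep–languidness 0.356, sleep–BMI −0.122,
depression–flexibility −0.179, depression–languidness 0.412) populate
the matrix; unreported cells default to zero — a modelling choice forced
by the unavailability of the full empirical matrix — except for a few
structural demand–demand correlations (e.g. night count with shift
hours, 0.8), since those indicators are arithmetically linked in any
real roster. If the assembled matrix is not positive semi-definite it is
repaired with `Matrix::nearPD` and both the original and repaired
matrices are kept in the cohort's provenance attribute.

Discretizing the marginals introduces ties and attenuates the realized
Spearman slightly: the sleep–depression correlation realizes at about
0.555 against the 0.560 target at study size, well inside the ±0.05
fidelity band the generator promises.

### Planted-truth modes

*Model mode* draws the covariates from the copula (with the outcome's
marginal removed), learns the same Yeo–Johnson + z-score recipe the
fitting side would learn, forms the standardized design including
interaction products, and draws the outcome from a log-link Poisson
model with the declared coefficients, clipped to the instrument range.
Because generation and refitting share the preprocessing procedure,
refitted coefficients are unbiased for the planted ones; clipping events
at the instrument ceiling are rare enough (the linear predictor stays
below ~3 for the published coefficient sets) not to move the mean
estimate materially. The two built-in coefficient sets are the published
optimal sleep-quality and depressive-symptoms models, so parameter
recovery doubles as a regression test of the whole GLM stack. Because
the two scores predict each other, each model's generator draws the
*other* score from the copula — one generative configuration per target
model — which avoids a circular definition while preserving each
recovery test.

*Piecewise mode* draws shift work hours uniformly on 8–60 h per 4-week
window (about a third of the mass below the kink) and sets the outcome
to a continuous broken-stick mean — slope −0.221 PSQI/h below 24 h,
+0.031 above, value 7 at the breakpoint — plus Gaussian noise with SD 3
PSQI points, rounded and clipped. The slopes and breakpoint are the
published dose–response; the anchor value and noise SD are the
generator's realistic-scale choices, fixed once.

## 2. Workload metrics

Shift classification works on clock windows at minute resolution: an
event with at least four consecutive worked hours inside 18:00–24:00 is
an evening shift, inside 00:00–08:00 a night shift, and an event
qualifying as both — the long 18:00–08:00 night with its three-hour nap
— is a night shift by precedence (the rule for this boundary case is a
package decision; the convention is logged here). Net hours subtract the
nap. Events longer than 24 h are rejected as malformed.

The expected nurse-to-patient ratio curve $\mathrm{NPR} = a e^{bs}$ is
fitted to the three severity anchors by least squares on the *original*
scale: for fixed $b$ the optimal $a$ is
$\sum y e^{bs} / \sum e^{2bs}$, and $b$ is profiled by 1-D
optimization. This reproduces $a \approx 0.1154$, $b \approx 1.0791$;
the log-linear alternative (0.1226, 1.0397) has a visibly larger
original-scale SSE because it underweights the severe-care anchor. Unit
CMI values map onto severity by min–max normalization to [0, 2] (a
constant input maps to 1 by convention; a fixed reference range is
available for cross-hospital use).

Workload is expected ÷ actual NPR, averaged across census periods with
hours weights so that exposure = mean workload × hours holds exactly.
Nurses whose units lack census rows receive `NA` intensity fields and
are listed in an attribute — mirroring the situation where some
departments cannot report patient-assignment counts — rather than
failing the run.

## 3. Preprocessing and univariate statistics

Outlier fences are $Q_1 - 3\,\mathrm{IQR}$ and $Q_3 + 3\,\mathrm{IQR}$
with type-7 (linear-interpolation) quartiles — stated explicitly because
the fences depend on the quantile convention. The wide 3× multiplier
reflects that bounded, skewed instrument scores legitimately occupy
their tails. Missing values are imputed by median (continuous) or mode
(categorical); an imputation fraction above 20% aborts, on the view that
a column that degraded needs investigation, not silent repair. The
Yeo–Johnson power is estimated by maximizing the profile log-likelihood
on [−5, 5]; the transform then feeds z-scoring whose mean/SD are stored
so held-out or simulated values can be mapped through the identical
recipe. Spearman correlations are tie-corrected with asymptotic
p-values; two-group contrasts use the Mann–Whitney U, three or more the
Kruskal–Wallis H.

## 4. The moderated GLM suite

The family is the one genuinely open modelling question: only the
coefficient tables are published, and their intercepts (2.114 for sleep
quality, 1.809 for depression) sit exactly where log-median outcomes
would put them, so the default is a log-link Poisson count model (with a
quasi-Poisson option for robust dispersion). Pseudo-R² is defined as
$1 - \mathrm{deviance}/\mathrm{null\ deviance}$ and is configurable,
since the published table does not define its version. Continuous
predictors enter Yeo–Johnson-transformed and z-scored; the binary gender
code stays 0/1 (female = 1); interaction terms are products of
*standardized* mains so their coefficients live on the same standardized
scale as the published table; the outcome itself stays on its raw count
scale, consistent with the log-scale intercepts. Three candidates per
outcome differ in which demand variable moderates (night count, shift
hours, workload exposure); they are ranked by AIC, then BIC, then
pseudo-R², then parameter count. Diagnostics: per-term VIF from
auxiliary regressions with the usual < 5 rule, deviance-residual plots
and normal QQ pairs.

## 5. Nonlinearity and breakpoints

The GAM screen refits the selected model's predictors with penalized
cubic regression splines (basis size 10; discrete demand counts with
very short supports fall back to linear terms automatically), Poisson
family, and smoothing parameters by GCV with the customary γ = 1.4
degrees-of-freedom inflation — plain GCV undersmooths often enough to
push a truly linear term's EDoF past the 1.2 nonlinearity flag, which
would make the screen unusable. A term is flagged when EDoF > 1.2 *and*
its smooth is significant at 0.05.

Breakpoints use the continuous hinge parameterization
$y = \beta_0 + \beta_1 x + \beta_2 (x-c)_+$ rather than two disjoint
per-segment regressions, because the underlying dose–response is a
continuous fitted curve; the candidate grid is every distinct observed
dose between the 5th and 95th percentiles with at least 10 points per
side, searched exhaustively (the problem is small enough that nothing
cleverer is warranted). The below-segment slope is $\beta_1$, the
above-segment slope $\beta_1 + \beta_2$ with a delta-method standard
error, and the structural-change test is the Wald test on $\beta_2$.
The breakpoint's own sampling uncertainty is visible in the exported
SSE profile but no confidence interval is constructed for it.

## 6. The trajectory simulator

Predictive functions are the fitted GLMs applied to raw-scale inputs:
raw covariates are winsorized to the recipe fences, transformed,
standardized, multiplied into the interaction products, pushed through
the linear predictor and the inverse log link, and clipped to the
instrument range. Each simulated day, the sleep prediction uses
yesterday's *smoothed* depression score and vice versa — a synchronous
update, chosen because it makes the result independent of the order the
two equations are written — and both scores are then updated by
exponentially weighted smoothing with α = 0.2 (sensitivity analyses
re-run with other α; a larger α strictly accelerates threshold
crossings without reordering scenarios). Trajectories start from the
minimum observed scores (PSQI 1, PHQ-9 0), a low-symptom baseline.

Population runs bootstrap 1,000 virtual nurses from the cohort and
report per-day cross-individual means and SDs (the bands are
across-individual SD, not Monte-Carlo error, which matches how such
trajectory fans are usually read). Scenario runs classify nurses into
adaptability profiles — moderate (both FR and LV between the cohort's
25th and 75th percentiles), high (FR ≥ P75 and LV ≤ P25), low (FR ≤ P25
and LV ≥ P75), with H/L taking precedence at shared boundaries — and
scale the whole demand bundle (4 nights, 44 h, exposure 147) by a
common multiplier, since the scenario of interest is "more/less shift
work", not one indicator moving alone. Threshold crossings are detected
on the group mean trajectory (PSQI > 7, PHQ-9 ≥ 10), with per-individual
crossing fractions also reported. Prediction noise is off by default:
the mean-field trajectories are the object of interest, and the noise
switch exists for band realism only.

## 7. Numerical choices and degenerate inputs

* Copula determinism: one integer seed fixes the whole cohort; the RNG
  state is saved and restored around every generator call.
* Beta-shape solving uses Nelder–Mead on log-shape parameters
  (relative tolerance 1e−14); the objective is smooth because all
  anchors are continuous quantiles.
* IRLS convergence: relative deviance change below 1e−8, at most 100
  iterations; non-convergence aborts with the iteration count.
* Constant columns abort z-scoring; all-missing columns abort
  imputation; fewer than 8 observations abort fencing.
* A demand distribution whose mass sits ≥ 80% on one side of a planted
  breakpoint triggers a warning from the piecewise generator.
* Clipping keeps every simulated value inside its instrument range by
  construction; clip events are invisible in the output by design.

## 8. What the tests show — and what they cannot

The test suite runs the generator at n = 288 (the study scale) with
25–200 replicates per recovery study, 10,000–20,000 draws for copula
fidelity, and trajectory populations of 15–60 individuals over 10–60
days; the acceptance script uses 200 piecewise replicates and 100
descriptive replicates at n = 288. These sizes make the Monte-Carlo
error small relative to every tolerance asserted.

Passing them shows that the pipeline is internally coherent: the
estimators recover what the generator plants, the closed forms hold, and
the published summary statistics are reproduced *under the generator's
assumptions* — smooth unimodal marginals, a Gaussian copula, a
correctly specified count model, cross-sectionally stable coefficients.
Real cohort data violate all of these in ways the generator does not
emulate: item-level questionnaire structure, within-person day-to-day
dynamics, informative missingness, departmental clustering, and
measurement error in the staffing records. The simulator in particular
extrapolates cross-sectional associations into daily dynamics; its
trajectories are scenario arithmetic, not forecasts. Conclusions about
real nurses require the real data; this package establishes that the
machinery applied to such data does what it claims.
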