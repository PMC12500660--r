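# shiftsleep

Rotating shift work disturbs sleep, and disturbed sleep erodes mental
health — but not equally for everyone. Two circadian-type traits measured
by the Circadian Type Inventory modulate the damage: **flexibility** (FR,
5–25; the ability to sleep and wake at unusual times) is protective, and
**languidness** (LV, 6–30; vulnerability to drowsiness after sleep loss)
is a risk factor. `shiftsleep` is a toolkit for studying how these traits
interact with *objective* shift-work demands — night-shift counts, shift
work hours, and workload exposure derived from nurse-to-patient ratios —
to shape sleep quality (PSQI, 0–21, insomnia screen at > 7) and
depressive symptoms (PHQ-9, 0–27, depression screen at ≥ 10) in hospital
nurses.

It is written for occupational-health and biostatistics researchers who
want a fully synthetic, reproducible version of this analysis: every
stage runs off a calibrated cohort generator, so there is no dependency
on restricted hospital data.

## What the package computes

**Workload metrics.** Shift events are classified by clock-window rules
(evening = ≥ 4 consecutive worked hours in 18:00–24:00, night = ≥ 4 in
00:00–08:00, the long 18:00–08:00 night with a 3-hour nap counts as a
night at 11 net hours). Work intensity uses the expected
nurse-to-patient ratio

```
expected NPR = a · exp(b · severity),   severity = CMI normalized to [0, 2]
```

fitted by original-scale least squares to the anchors (0, 1:8), (1, 1:3),
(2, 1:1), giving a ≈ 0.1154 and b ≈ 1.0791. Workload is expected ÷
actual NPR; workload exposure is workload × corresponding work hours
over a 4-week window.

**Moderated GLMs.** Each instrument score is modelled with a log-link
count GLM on Yeo–Johnson-transformed, z-scored predictors, with one
demand variable as moderator (three candidates compared by AIC, BIC and
pseudo-R²; VIF < 5 checked throughout):

```
log E[PSQI]  = β0 + β1·PHQ9 + β2·SWH + β3·PHQ9×SWH + β4·LV + … 
log E[PHQ9]  = β0 + β1·PSQI + β2·FR + β3·PSQI×FR + β4·LV + …
```

**Nonlinear dose–response.** A GAM screen (cubic regression splines,
GCV) flags demand variables with effective degrees of freedom
substantially above 1, then a continuous hinge (broken-stick) regression
`y ~ 1 + x + max(0, x − c)` locates the breakpoint by exhaustive SSE
search — around 24 shift work hours per 4 weeks for sleep quality.

**Trajectory simulation.** Daily coupled predictions (each score
predicted from yesterday's smoothed value of the other) are combined by
exponentially weighted smoothing, `s_t = α·prediction + (1−α)·s_{t−1}`
with α = 0.2, over 100 days for bootstrap populations of 1,000 virtual
nurses, overall and within adaptability profiles (M/H/L percentile rules
on FR and LV) across demand multipliers.

**Synthetic cohorts.** A Gaussian copula with discretized scaled-beta
marginals reproduces the published medians, IQRs, screening prevalences
and Spearman structure; model mode and piecewise mode plant known
coefficient sets or dose–response shapes for parameter-recovery studies.

## Worked example

```r
library(shiftsleep)

cohort <- generate_cohort(288, seed = 1)
dplyr::summarise(cohort, median_psqi = median(psqi),
                 insomnia = mean(psqi > 7), depression = mean(phq9 >= 10))
#>   median_psqi insomnia depression
#> 1           8    0.538      0.243

spearman_matrix(cohort, c("psqi", "phq9")) |>
  dplyr::filter(var1 == "psqi", var2 == "phq9")
#>   var1  var2    rho        p     n
#> 1 psqi  phq9  0.530 2.74e-22   288
```

A cohort of 288 virtual nurses reproduces the study-scale marginals
(median PSQI 8, 53.8% insomnia-positive) and the sleep–depression rank
correlation (0.53 here; the published value is 0.560). Refitting a
cohort whose outcome was *generated* from the published sleep-quality
coefficient set recovers those coefficients:

```r
planted <- generate_cohort_glm(psqi_model_truth(), n = 288, seed = 2)
fit <- fit_shift_glm(planted, psqi_spec())
dplyr::filter(tidy(fit), term %in% c("phq9", "shift_work_hours", "lv"))
#>   term             estimate std_error statistic  p_value
#> 1 phq9               0.267     0.0252     10.6  2.89e-26
#> 2 shift_work_hours   0.112     0.0405      2.76 5.75e-3
#> 3 lv                 0.0616    0.0242      2.54 1.10e-2
```

The planted values were 0.245, 0.093 and 0.065: each single-replicate
estimate sits within its standard error, and across 200 replicates the
means are unbiased. The planted dose–response is recovered the same way:

```r
pc <- generate_cohort_piecewise(n = 288, seed = 3)
fit_breakpoint(pc, "shift_work_hours", "psqi")
#> <breakpoint_fit> psqi ~ shift_work_hours: breakpoint 25.0 h, slopes -0.275 | 0.048
```

`run_pipeline(pipeline_config(n_nurses = 288, seed = 1))` chains everything —
generation, demand summaries, univariate screen, candidate model
comparison, GAM/breakpoint analysis and the trajectory simulations — and
`write_results()` exports the bundle as CSV.

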