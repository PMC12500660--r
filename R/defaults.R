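#' Default marginals for the synthetic nurse cohort
#'
#' Calibration targets are the published cohort summaries for 288 rotating
#' shift nurses: PSQI median 8 (IQR 4, range 1-17, 51.39% above the
#' insomnia cutoff of 7), PHQ-9 median 7 (IQR 5, range 0-22, 24.31% at or
#' above the depression cutoff of 10), CTI flexibility (FR, 5-25) and
#' languidness (LV, 6-30) medians/IQRs, 89.58% female, age 24-44, BMI
#' category proportions, and 4-week shift-demand indicators centred on the
#' typical demand condition (4 night shifts, 44 shift work hours, shift
#' workload exposure 147).
#'
#' @return Named list of `marginal_spec` objects.
#' @export
default_marginals <- function() {
  specs <- list(
    beta_marginal("psqi", 1, 17, median = 8, iqr = 4,
                  cutoff = 7, cutoff_prevalence = 0.5139,
                  cutoff_direction = ">"),
    beta_marginal("phq9", 0, 22, median = 7, iqr = 5,
                  cutoff = 10, cutoff_prevalence = 0.2431,
                  cutoff_direction = ">="),
    beta_marginal("fr", 5, 25, median = 12, iqr = 6),
    beta_marginal("lv", 6, 30, median = 18.5, iqr = 6),
    # BMI anchored at the published category proportions
    # (<18.5: 6.3%, <24: 82.0%, <28: 98.6% cumulative).
    beta_marginal("bmi", 15, 35, median = 21.5, iqr = 3.5,
                  anchors = list(c(0.063, 18.5), c(0.820, 24),
                                 c(0.986, 28)),
                  discrete = FALSE),
    uniform_marginal("age", 24, 44),
    bernoulli_marginal("gender", prob = 0.8958),
    beta_marginal("night_count", 0, 9, median = 4, iqr = 2),
    beta_marginal("shift_work_hours", 0, 88, median = 44, iqr = 22),
    beta_marginal("shift_workload_exposure", 0, 400, median = 147,
                  iqr = 70, discrete = FALSE),
    beta_marginal("day_workload_exposure", 0, 400, median = 120,
                  iqr = 60, discrete = FALSE)
  )
  setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Default rank-correlation structure
#'
#' The published significant Spearman correlations (sleep quality with
#' depressive symptoms 0.560, with languidness 0.356, with BMI -0.122;
#' depressive symptoms with flexibility -0.179, with languidness 0.412),
#' plus structural correlations among the shift-demand indicators (night
#' count, shift work hours and shift workload exposure are arithmetically
#' linked in real rosters). Unlisted pairs default to zero.
#'
#' @return A `dependence_spec`.
#' @export
default_dependence <- function() {
  dependence_spec(tibble::tribble(
    ~var1,          ~var2,                      ~rho,
    "psqi",          "phq9",                    0.560,
    "psqi",          "lv",                      0.356,
    "psqi",          "bmi",                    -0.122,
    "phq9",          "fr",                     -0.179,
    "phq9",          "lv",                      0.412,
    "night_count",   "shift_work_hours",        0.80,
    "night_count",   "shift_workload_exposure", 0.50,
    "shift_work_hours", "shift_workload_exposure", 0.60,
    "day_workload_exposure", "shift_workload_exposure", 0.30
  ))
}

#' Generating coefficient sets for the two optimal moderated GLMs
#'
#' Standardized log-link coefficient sets used as ground truth by the
#' model-mode generator and as the reference fits for the trajectory
#' simulator: one predicting sleep quality (PSQI) with shift work hours as
#' the moderator, one predicting depressive symptoms (PHQ-9). Interaction
#' terms are products of standardized main effects (written `a:b`).
#'
#' @return A [glm_truth()] object.
#' @name model_truths
#' @examples
#' psqi_model_truth()$coefficients[["phq9"]]
NULL

#' @rdname model_truths
#' @export
psqi_model_truth <- function() {
  glm_truth(
    outcome = "psqi",
    coefficients = c(
      "(Intercept)"              =  2.114,
      "gender"                   = -0.064,
      "phq9"                     =  0.245,
      "shift_work_hours"         =  0.093,
      "phq9:shift_work_hours"    = -0.047,
      "lv"                       =  0.065,
      "phq9:lv"                  = -0.035,
      "shift_work_hours:lv"      =  0.014,
      "night_count"              = -0.050,
      "shift_workload_exposure"  =  0.002,
      "age"                      =  0.022,
      "bmi"                      = -0.056,
      "day_workload_exposure"    =  0.062,
      "fr"                       =  0.042
    ),
    family = "poisson"
  )
}

#' @rdname model_truths
#' @export
phq9_model_truth <- function() {
  glm_truth(
    outcome = "phq9",
    coefficients = c(
      "(Intercept)"              =  1.809,
      "gender"                   =  0.075,
      "psqi"                     =  0.314,
      "fr"                       = -0.129,
      "psqi:fr"                  =  0.091,
      "lv"                       =  0.159,
      "psqi:lv"                  =  0.004,
      "shift_work_hours"         = -0.054,
      "psqi:shift_work_hours"    = -0.008,
      "fr:shift_work_hours"      = -0.020,
      "lv:shift_work_hours"      =  0.069,
      "age"                      =  0.009,
      "night_count"              =  0.028,
      "shift_workload_exposure"  =  0.008,
      "day_workload_exposure"    = -0.083
    ),
    family = "poisson"
  )
}

#' Declare a generative GLM truth
#'
#' @param outcome Outcome variable name (`psqi` or `phq9`).
#' @param coefficients Named numeric vector of standardized-scale
#'   coefficients; interaction terms written `a:b`.
#' @param family Model family label; `"poisson"` (log link) is the only
#'   built-in generative family.
#' @return An object of class `glm_truth`.
#' @export
glm_truth <- function(outcome, coefficients, family = "poisson") {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!"(Intercept)" %in% names(coefficients)) {
    abort("coefficients must include an '(Intercept)' term")
  }
  structure(list(outcome = outcome, coefficients = coefficients,
                 family = family),
            class = "glm_truth")
}

#' Default planted dose-response (piecewise mode)
#'
#' The published segmented relationship between 4-week shift work hours and
#' sleep quality: a breakpoint near 24 hours, slope -0.221 PSQI points per
#' hour below it and +0.031 above it. The mean PSQI at the breakpoint (7)
#' and the residual SD (3 PSQI points) are the generator's realistic-scale
#' choices; hours are drawn uniformly on 8-60 per 4-week window so both
#' segments are well populated.
#'
#' @return A `piecewise_truth` object.
#' @export
default_piecewise_truth <- function() {
  piecewise_truth(x_var = "shift_work_hours", outcome = "psqi",
                  breakpoint = 24, slope_below = -0.221,
                  slope_above = 0.031, y_at_break = 7, noise_sd = 3,
                  x_range = c(8, 60))
}

#' Declare a planted two-segment dose-response
#'
#' @param x_var Demand variable name (the dose).
#' @param outcome Outcome score name (for clipping support).
#' @param breakpoint Kink location in hours; must lie inside `x_range`.
#' @param slope_below,slope_above Segment slopes (outcome units per hour).
#' @param y_at_break Mean outcome at the breakpoint.
#' @param noise_sd Gaussian residual SD (outcome units, `>= 0`).
#' @param x_range Range the dose is drawn from (uniform, integer hours).
#' @return An object of class `piecewise_truth`.
#' @export
piecewise_truth <- function(x_var, outcome, breakpoint, slope_below,
                            slope_above, y_at_break, noise_sd,
                            x_range) {
  stopifnot(noise_sd >= 0, length(x_range) == 2, x_range[1] < x_range[2])
  if (breakpoint <= x_range[1] || breakpoint >= x_range[2]) {
    abort("breakpoint must lie strictly inside `x_range`")
  }
  structure(list(x_var = x_var, outcome = outcome, breakpoint = breakpoint,
                 slope_below = slope_below, slope_above = slope_above,
                 y_at_break = y_at_break, noise_sd = noise_sd,
                 x_range = x_range),
            class = "piecewise_truth")
}

#' Baseline 4-week shift-work demand condition
#'
#' The typical demand bundle used as the simulation baseline: 4 night
#' shifts, 44 shift work hours and a shift workload exposure of 147
#' (ratio-hours) per 4-week window.
#'
#' @return Named numeric vector.
#' @export
baseline_demand <- function() {
  c(night_count = 4, shift_work_hours = 44, shift_workload_exposure = 147)
}
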