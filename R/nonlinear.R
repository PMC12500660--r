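#' GAM nonlinearity screen
#'
#' Refits the optimal model's predictors as a generalized additive model:
#' penalized cubic regression spline smooths (basis size 10) for the
#' continuous predictors, ordinary factor/linear terms for categorical
#' covariates, smoothing parameters chosen by GCV with the customary
#' `gamma = 1.4` degrees-of-freedom inflation that guards against GCV's
#' tendency to undersmooth. A term is flagged
#' nonlinear when its effective degrees of freedom (EDoF) exceed
#' `edof_flag` and its smooth is significant at `alpha` — EDoF near 1
#' indicates an essentially linear partial effect.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column (count score; log-link Poisson family,
#'   matching the GLM suite).
#' @param smooth_terms Continuous predictors to receive smooths.
#' @param factor_terms Categorical/binary predictors entered parametrically.
#' @param k Spline basis size per smooth.
#' @param edof_flag,alpha Nonlinearity flag thresholds.
#' @return An object of class `gam_screen`: tibble of per-term EDoF and
#'   p-values in `$terms`, plus `pseudo_r2`, `gcv`, `total_edof` and the
#'   underlying `mgcv` fit.
#' @examples
#' pc <- generate_cohort_piecewise(n = 288, seed = 1)
#' fit_gam_screen(pc, "psqi", "shift_work_hours")$terms
#' @export
fit_gam_screen <- function(data, outcome, smooth_terms,
                           factor_terms = character(), k = 10,
                           edof_flag = 1.2, alpha = 0.05) {
  if (nrow(data) < 30) abort("need at least 30 observations")
  # a cr basis needs fewer knots than distinct covariate values; discrete
  # demand counts with very short supports fall back to linear terms
  k_term <- vapply(smooth_terms, function(v) {
    min(k, length(unique(data[[v]])) - 2)
  }, numeric(1))
  linear_fallback <- smooth_terms[k_term < 3]
  smooth_kept <- smooth_terms[k_term >= 3]
  rhs <- c(sprintf("s(%s, k = %d, bs = \"cr\")", smooth_kept,
                   k_term[k_term >= 3]),
           linear_fallback, factor_terms)
  form <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = "+")))
  fit <- tryCatch(
    mgcv::gam(form, data = data, family = poisson(link = "log"),
              method = "GCV.Cp", gamma = 1.4),
    error = function(e) {
      abort(paste0("GAM fit failed (try a smaller basis size k): ",
                   conditionMessage(e)))
    }
  )
  sm <- summary(fit)
  st <- sm$s.table
  terms <- tibble::tibble(
    term = smooth_kept,
    edof = unname(st[, "edf"]),
    p_value = unname(st[, "p-value"]),
    basis_size = unname(k_term[k_term >= 3]),
    smoothing_parameter = unname(fit$sp),
    nonlinear = unname(st[, "edf"]) > edof_flag &
      unname(st[, "p-value"]) < alpha
  )
  if (length(linear_fallback)) {
    pt <- sm$p.table
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term = linear_fallback,
      edof = 1,
      p_value = unname(pt[linear_fallback, "Pr(>|z|)"]),
      basis_size = NA_real_, smoothing_parameter = NA_real_,
      nonlinear = FALSE))
  }
  structure(list(
    terms = terms,
    pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
    gcv = unname(fit$gcv.ubre),
    total_edof = sum(fit$edf),
    gam = fit, outcome = outcome
  ), class = "gam_screen")
}

#' Continuous hinge (broken-stick) breakpoint regression
#'
#' For every candidate breakpoint `c`, fits the continuous two-segment
#' model `y ~ 1 + x + pmax(x - c, 0)` by OLS and selects the candidate
#' minimizing the residual sum of squares. The fitted mean is continuous
#' at the breakpoint by construction. Segment slopes are the coefficient
#' on `x` below the breakpoint and its sum with the hinge coefficient
#' above it (delta-method standard error for the latter). The default
#' candidate grid is every distinct observed `x` between the 5th and 95th
#' percentiles with at least `min_side` observations on each side.
#'
#' @param data Data frame.
#' @param x,y Column names of the dose and outcome.
#' @param grid Optional numeric vector of candidate breakpoints.
#' @param min_side Minimum observations required on each side.
#' @return An object of class `breakpoint_fit` with the selected
#'   `breakpoint`, `slope_below`/`slope_above` (with SEs and p-values),
#'   `intercept`, `sse`, and the full SSE `profile`.
#' @examples
#' pc <- generate_cohort_piecewise(n = 288, seed = 1)
#' fit <- fit_breakpoint(pc, "shift_work_hours", "psqi")
#' c(fit$breakpoint, fit$slope_above)
#' @export
fit_breakpoint <- function(data, x, y, grid = NULL, min_side = 10) {
  xv <- data[[x]]; yv <- data[[y]]
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (is.null(grid)) {
    qs <- quantile(xv, c(0.05, 0.95), names = FALSE)
    grid <- sort(unique(xv[xv >= qs[1] & xv <= qs[2]]))
  }
  grid <- grid[vapply(grid, function(c0) {
    sum(xv < c0) >= min_side && sum(xv >= c0) >= min_side
  }, logical(1))]
  if (!length(grid)) {
    abort("no candidate breakpoint leaves enough points on both sides")
  }
  sse_of <- vapply(grid, function(c0) {
    sum(lm.fit(cbind(1, xv, pmax(xv - c0, 0)), yv)$residuals^2)
  }, numeric(1))
  c_best <- grid[which.min(sse_of)]
  fit <- lm(yv ~ xv + hinge, data = data.frame(
    yv = yv, xv = xv, hinge = pmax(xv - c_best, 0)))
  # noiseless segments fit perfectly; the SEs are still well defined
  ct <- suppressWarnings(summary(fit)$coefficients)
  V <- suppressWarnings(vcov(fit))
  b_below <- ct["xv", 1]
  b_above <- b_below + ct["hinge", 1]
  se_above <- sqrt(V["xv", "xv"] + V["hinge", "hinge"] +
                     2 * V["xv", "hinge"])
  structure(list(
    breakpoint = c_best,
    intercept = ct["(Intercept)", 1],
    slope_below = b_below, slope_below_se = ct["xv", 2],
    p_below = ct["xv", 4],
    slope_above = b_above, slope_above_se = se_above,
    p_above = 2 * pnorm(-abs(b_above / se_above)),
    hinge_coef = ct["hinge", 1], hinge_se = ct["hinge", 2],
    p_hinge = ct["hinge", 4],
    sse = min(sse_of),
    profile = tibble::tibble(candidate = grid, sse = sse_of),
    lm = fit, x = x, y = y
  ), class = "breakpoint_fit")
}

#' Test for a structural slope change at the breakpoint
#'
#' Wald test on the hinge coefficient: under the null the two segment
#' slopes are equal and the broken stick collapses to a single line.
#'
#' @param fit A [fit_breakpoint()] result.
#' @return One-row tibble with `estimate` (slope difference), `statistic`,
#'   `p_value`.
#' @export
slope_contrast <- function(fit) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  tibble::tibble(estimate = fit$hinge_coef,
                 statistic = fit$hinge_coef / fit$hinge_se,
                 p_value = fit$p_hinge)
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_fit> %s ~ %s: breakpoint %.1f h, slopes %.3f | %.3f\n",
    x$y, x$x, x$breakpoint, x$slope_below, x$slope_above))
  invisible(x)
}

#' @export
print.gam_screen <- function(x, ...) {
  cat(sprintf("<gam_screen> %s: pseudo-R2 %.3f, GCV %.2f, EDoF %.2f\n",
              x$outcome, x$pseudo_r2, x$gcv, x$total_edof))
  print(x$terms)
  invisible(x)
}
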