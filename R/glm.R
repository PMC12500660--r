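#' Specify a moderated GLM candidate
#'
#' Each candidate model predicts an instrument score from standardized main
#' effects plus interaction terms (products of standardized mains), with
#' one shift-demand variable designated as the moderator. Continuous
#' predictors are Yeo-Johnson transformed and z-scored via a
#' [learn_recipe()] recipe; binary predictors are coded 0/1 (female = 1).
#'
#' @param outcome Outcome column name (left on its raw count scale).
#' @param mains Character vector of main-effect columns.
#' @param interactions Character vector of `"a:b"` interaction labels whose
#'   components appear in `mains`.
#' @param moderator The shift-demand moderator; must appear in `mains`.
#' @param family `"poisson"` (log link, default) or `"quasipoisson"`.
#' @param binary Which mains are binary 0/1 codes (skipped by the recipe).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome, mains, interactions = character(),
                       moderator = NULL, family = "poisson",
                       binary = "gender") {
  for (tm in interactions) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% mains)) {
      abort(paste0("interaction '", tm,
                   "' must name two declared main effects"))
    }
  }
  if (!is.null(moderator) && !moderator %in% mains) {
    abort("moderator must appear among the main effects")
  }
  structure(list(outcome = outcome, mains = mains,
                 interactions = interactions, moderator = moderator,
                 family = family, binary = intersect(binary, mains)),
            class = "model_spec")
}

#' Build the standardized design matrix for a candidate model
#'
#' @param cohort Cohort tibble.
#' @param spec A [model_spec()].
#' @param recipe A [learn_recipe()] recipe covering every continuous main;
#'   learned from `cohort` when `NULL`.
#' @return A list with `x` (design tibble, no intercept column),
#'   `y` (outcome vector), and the `recipe` used.
#' @export
build_design <- function(cohort, spec, recipe = NULL) {
  continuous <- setdiff(spec$mains, spec$binary)
  if (is.null(recipe)) recipe <- learn_recipe(cohort, continuous)
  not_covered <- setdiff(continuous, names(recipe))
  if (length(not_covered)) {
    abort(paste0("recipe missing entries for: ",
                 paste(not_covered, collapse = ", ")))
  }
  std <- apply_recipe(recipe, cohort[continuous])
  x <- dplyr::bind_cols(std, cohort[spec$binary])[spec$mains]
  for (tm in spec$interactions) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    x[[tm]] <- x[[parts[1]]] * x[[parts[2]]]
  }
  list(x = x, y = cohort[[spec$outcome]], recipe = recipe)
}

#' Fit a moderated GLM candidate
#'
#' Fits the log-link GLM by iteratively reweighted least squares and
#' packages the coefficient table (Wald z, p, 95% CI), information
#' criteria, pseudo-R2 (1 - deviance / null deviance) and per-term VIFs
#' together with the preprocessing recipe, so the fit can later be applied
#' to raw-scale covariates.
#'
#' @inheritParams build_design
#' @return An object of class `shift_glm`.
#' @examples
#' cohort <- generate_cohort_glm(psqi_model_truth(), n = 288, seed = 1)
#' fit <- fit_shift_glm(cohort, psqi_spec())
#' glance(fit)
#' @export
fit_shift_glm <- function(cohort, spec, recipe = NULL) {
  d <- build_design(cohort, spec, recipe)
  if (length(d$y) <= ncol(d$x) + 1) abort("more parameters than rows")
  fam <- switch(spec$family,
    poisson = poisson(link = "log"),
    quasipoisson = quasipoisson(link = "log"),
    abort(paste0("unsupported family '", spec$family, "'"))
  )
  df <- dplyr::bind_cols(tibble::tibble(.outcome = d$y), d$x)
  names(df) <- make.names(names(df))
  fit <- glm(.outcome ~ ., data = df, family = fam,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    abort(sprintf("IRLS did not converge in %d iterations", fit$iter))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  terms_out <- c("(Intercept)", names(d$x))
  coefs <- tibble::tibble(
    term = terms_out,
    estimate = ct[, 1], std_error = ct[, 2],
    statistic = ct[, 3], p_value = ct[, 4],
    conf_low = ct[, 1] - 1.96 * ct[, 2],
    conf_high = ct[, 1] + 1.96 * ct[, 2]
  )
  ll <- as.numeric(logLik(fit))
  k <- length(coef(fit))
  n <- nrow(df)
  structure(list(
    spec = spec, recipe = d$recipe, coefficients = coefs,
    log_lik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
    pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
    deviance = fit$deviance, null_deviance = fit$null.deviance,
    vif = vif(as.matrix(d$x)), n = n, k = k, glm = fit,
    outcome_range = instrument_range(spec$outcome)
  ), class = "shift_glm")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from the auxiliary OLS regression of design
#' column `j` on the remaining columns; values are capped at `Inf` for
#' numerically collinear columns.
#'
#' @param x Numeric design matrix (no intercept column).
#' @return Named numeric vector.
#' @examples
#' vif(cbind(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(setNames(rep(1, ncol(x)), colnames(x)))
  out <- vapply(seq_len(ncol(x)), function(j) {
    # collinear columns give a degenerate auxiliary fit; only R2 is needed
    r2 <- suppressWarnings(
      summary(lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(x))
}

#' Compare candidate moderated GLMs
#'
#' Ranks fitted candidates by AIC, then BIC, then pseudo-R2 (higher
#' better), breaking remaining ties by parameter count.
#'
#' @param fits Named list of `shift_glm` fits (one per candidate
#'   moderator).
#' @return A list with `table` (comparison tibble, best first) and
#'   `selected` (the winning fit).
#' @export
compare_candidates <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm,
                   moderator = f$spec$moderator %||% NA_character_,
                   aic = f$aic, bic = f$bic, pseudo_r2 = f$pseudo_r2,
                   log_lik = f$log_lik, k = f$k, n = f$n)
  })
  tab <- dplyr::arrange(tab, .data$aic, .data$bic,
                        dplyr::desc(.data$pseudo_r2), .data$k)
  list(table = tab, selected = fits[[tab$model[1]]])
}

#' Residual diagnostics for a fitted candidate
#'
#' @param fit A `shift_glm`.
#' @return A list of tibbles: `residuals` (fitted vs deviance residual)
#'   and `qq` (theoretical vs empirical normal quantile pairs).
#' @export
residual_diagnostics <- function(fit) {
  r <- residuals(fit$glm, type = "deviance")
  res <- tibble::tibble(fitted = fitted(fit$glm), deviance_residual = r)
  n <- length(r)
  qq <- tibble::tibble(theoretical = qnorm(ppoints(n)),
                       empirical = sort(r))
  list(residuals = res, qq = qq)
}

#' Candidate specifications for the two outcomes
#'
#' The published optimal model structure: the outcome predicted from the
#' other instrument score, circadian type (FR, LV), a shift-demand
#' moderator with its interactions, and confounders (gender, age, plus BMI
#' and day workload exposure for sleep quality, day workload exposure for
#' depressive symptoms).
#'
#' @param moderator One of `"shift_work_hours"`, `"night_count"`,
#'   `"shift_workload_exposure"`.
#' @return A [model_spec()].
#' @name candidate_specs
NULL

#' @rdname candidate_specs
#' @export
psqi_spec <- function(moderator = "shift_work_hours") {
  mains <- c("gender", "phq9", "shift_work_hours", "lv", "night_count",
             "shift_workload_exposure", "age", "bmi",
             "day_workload_exposure", "fr")
  model_spec(
    outcome = "psqi", mains = mains,
    interactions = paste0("phq9:", c(moderator, "lv")) |>
      c(paste0(moderator, ":lv")) |> unique(),
    moderator = moderator
  )
}

#' @rdname candidate_specs
#' @export
phq9_spec <- function(moderator = "shift_work_hours") {
  mains <- c("gender", "psqi", "fr", "lv", "shift_work_hours",
             "night_count", "shift_workload_exposure", "age",
             "day_workload_exposure")
  if (!moderator %in% mains) mains <- c(mains, moderator)
  model_spec(
    outcome = "phq9", mains = mains,
    interactions = unique(c("psqi:fr", "psqi:lv",
                            paste0(c("psqi", "fr", "lv"), ":", moderator))),
    moderator = moderator
  )
}

#' @export
print.shift_glm <- function(x, ...) {
  cat(sprintf("<shift_glm> %s ~ %d terms (%s, moderator: %s)\n",
              x$spec$outcome, x$k - 1, x$spec$family,
              x$spec$moderator %||% "none"))
  cat(sprintf("  AIC %.2f  BIC %.2f  pseudo-R2 %.4f  n %d\n",
              x$aic, x$bic, x$pseudo_r2, x$n))
  invisible(x)
}
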