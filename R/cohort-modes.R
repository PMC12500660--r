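#' Generate a cohort with a planted GLM truth (model mode)
#'
#' Covariates are drawn from the Gaussian copula exactly as in
#' [generate_cohort()], except that the outcome's marginal (and any
#' dependence pairs involving it) are dropped. The outcome is then drawn
#' from the declared log-link count family with linear predictor
#' `eta = sum(beta * standardized terms)`, where the standardization recipe
#' (Yeo-Johnson + z-score) is learned on the drawn covariates — the same
#' procedure the fitting side applies, so refitting recovers the planted
#' coefficients. Outcomes are clipped to the instrument support.
#'
#' @param truth A [glm_truth()] coefficient set (see
#'   [psqi_model_truth()], [phq9_model_truth()]).
#' @param n Cohort size.
#' @param seed Integer RNG seed.
#' @param marginals,dependence Covariate configuration, as in
#'   [generate_cohort()].
#' @return A cohort tibble including the simulated outcome; the generating
#'   coefficients are stored in `attr(, "provenance")$truth`.
#' @examples
#' cohort <- generate_cohort_glm(psqi_model_truth(), n = 288, seed = 7)
#' range(cohort$psqi)
#' @export
generate_cohort_glm <- function(truth, n, seed,
                                marginals = default_marginals(),
                                dependence = default_dependence()) {
  stopifnot(inherits(truth, "glm_truth"))
  beta <- truth$coefficients
  terms <- setdiff(names(beta), "(Intercept)")
  mains <- terms[!grepl(":", terms, fixed = TRUE)]
  interactions <- setdiff(terms, mains)
  # outcome must not also be a copula covariate
  marginals <- marginals[setdiff(names(marginals), truth$outcome)]
  dep <- dependence
  keep <- dep$pairs$var1 != truth$outcome & dep$pairs$var2 != truth$outcome
  dep$pairs <- dep$pairs[keep, ]
  absent <- setdiff(mains, names(marginals))
  if (length(absent)) {
    abort(paste0("terms reference covariates without marginals: ",
                 paste(absent, collapse = ", ")))
  }
  covs <- generate_cohort(n, seed, marginals = marginals, dependence = dep)
  binary <- mains[vapply(marginals[mains], function(m) {
    m$family == "bernoulli"
  }, logical(1))]
  spec <- model_spec(outcome = truth$outcome, mains = mains,
                     interactions = interactions, binary = binary)
  continuous <- setdiff(mains, binary)
  recipe <- learn_recipe(covs, continuous)
  std <- dplyr::bind_cols(apply_recipe(recipe, covs[continuous]),
                          covs[binary])
  eta <- rep(beta[["(Intercept)"]], n)
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    col <- if (length(parts) == 2) {
      std[[parts[1]]] * std[[parts[2]]]
    } else {
      std[[tm]]
    }
    eta <- eta + beta[[tm]] * col
  }
  rng <- instrument_range(truth$outcome)
  y <- with_seed(seed + 10^6, rpois(n, exp(eta)))
  covs[[truth$outcome]] <- clip(y, rng[1], rng[2])
  prov <- attr(covs, "provenance")
  prov$mode <- "model"
  prov$truth <- truth
  prov$spec <- spec
  prov$recipe <- recipe
  attr(covs, "provenance") <- prov
  covs
}

#' Generate a cohort with a planted two-segment dose-response
#' (piecewise mode)
#'
#' The dose (4-week shift work hours) is drawn uniformly over the declared
#' integer range; the outcome is the continuous broken-stick mean plus
#' Gaussian noise, rounded and clipped to the instrument support.
#'
#' @param truth A [piecewise_truth()]; defaults to
#'   [default_piecewise_truth()].
#' @param n Cohort size.
#' @param seed Integer RNG seed.
#' @return A tibble with the dose and outcome columns; generating
#'   parameters in `attr(, "provenance")`.
#' @examples
#' pc <- generate_cohort_piecewise(n = 288, seed = 3)
#' fit_breakpoint(pc, "shift_work_hours", "psqi")$breakpoint
#' @export
generate_cohort_piecewise <- function(truth = default_piecewise_truth(),
                                      n, seed) {
  stopifnot(inherits(truth, "piecewise_truth"))
  rng <- instrument_range(truth$outcome)
  out <- with_seed(seed, {
    x <- sample(seq(truth$x_range[1], truth$x_range[2]), n, replace = TRUE)
    mu <- truth$y_at_break +
      truth$slope_below * pmin(x - truth$breakpoint, 0) +
      truth$slope_above * pmax(x - truth$breakpoint, 0)
    y <- mu + rnorm(n, sd = truth$noise_sd)
    tibble::tibble(nurse_id = seq_len(n), !!truth$x_var := x,
                   !!truth$outcome := clip(round(y), rng[1], rng[2]))
  })
  below <- mean(out[[truth$x_var]] < truth$breakpoint)
  if (below < 0.2 || below > 0.8) {
    warn(sprintf("only %.0f%% of the dose mass lies below the breakpoint",
                 100 * min(below, 1 - below)))
  }
  attr(out, "provenance") <- list(mode = "piecewise", n = n, seed = seed,
                                  truth = truth)
  class(out) <- c("shift_cohort", class(out))
  out
}
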