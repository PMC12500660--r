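#' Simulation settings for the trajectory engine
#'
#' @param alpha Exponential smoothing factor in `(0, 1]`; the daily update
#'   combines `alpha` of the current model prediction with `1 - alpha` of
#'   yesterday's score.
#' @param horizon Days to simulate.
#' @param n_individuals Virtual individuals per group (bootstrap size).
#' @param init_psqi,init_phq9 Starting scores — the minimum observed
#'   values (PSQI 1, PHQ-9 0) represent a low-symptom baseline.
#' @param demand Named baseline demand bundle (night count, shift work
#'   hours, shift workload exposure).
#' @param demand_multiplier Scales the whole demand bundle.
#' @param noise Add per-day Gaussian prediction noise? Off by default
#'   (mean-field trajectories).
#' @param noise_sd SD of the optional prediction noise (score units).
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(alpha = 0.2, horizon = 100,
                              n_individuals = 1000, init_psqi = 1,
                              init_phq9 = 0, demand = baseline_demand(),
                              demand_multiplier = 1, noise = FALSE,
                              noise_sd = 1, seed = 1) {
  stopifnot(alpha > 0, alpha <= 1, horizon >= 1)
  stopifnot(init_psqi >= 0, init_psqi <= 21,
            init_phq9 >= 0, init_phq9 <= 27)
  structure(list(alpha = alpha, horizon = horizon,
                 n_individuals = n_individuals, init_psqi = init_psqi,
                 init_phq9 = init_phq9, demand = demand,
                 demand_multiplier = demand_multiplier, noise = noise,
                 noise_sd = noise_sd, seed = seed),
            class = "simulation_config")
}

#' Raw-scale predictive function from a fitted GLM
#'
#' Maps raw covariates through the fit's stored preprocessing recipe
#' (winsorize to fences, Yeo-Johnson, z-score), forms the standardized
#' interaction products, applies the linear predictor and the inverse log
#' link, and clips to the instrument range.
#'
#' @param fit A [fit_shift_glm()] result.
#' @param newdata Data frame of raw-scale covariates (one or more rows).
#' @return Numeric vector of expected scores.
#' @export
predict_score <- function(fit, newdata) {
  spec <- fit$spec
  d <- build_design(newdata, spec, recipe = fit$recipe)
  beta <- fit$coefficients$estimate
  names(beta) <- fit$coefficients$term
  eta <- beta[["(Intercept)"]] +
    as.numeric(as.matrix(d$x) %*% beta[names(d$x)])
  clip(exp(eta), fit$outcome_range[1], fit$outcome_range[2])
}

#' One exponentially weighted smoothing update
#'
#' @param previous Yesterday's smoothed score.
#' @param predicted Today's model prediction.
#' @param alpha Smoothing factor in `(0, 1]`.
#' @return `alpha * predicted + (1 - alpha) * previous`.
#' @examples
#' ews_update(1, 8, 0.2)  # 2.4
#' @export
ews_update <- function(previous, predicted, alpha) {
  alpha * predicted + (1 - alpha) * previous
}

#' Simulate one individual's coupled daily trajectories
#'
#' Each day both instrument scores are predicted from the fixed covariates
#' and demand condition together with the *other* score's smoothed value
#' from the previous day (synchronous update, so the result does not
#' depend on the order the two scores are written). Both scores are then
#' smoothed with [ews_update()] and clipped to their instrument ranges.
#'
#' @param covariates One-row tibble of raw-scale covariates (the demand
#'   columns are overwritten from `config`).
#' @param psqi_fit,phq9_fit Fitted models for the two outcomes.
#' @param config A [simulation_config()].
#' @return A tibble with `day`, `psqi`, `phq9`.
#' @export
simulate_individual <- function(covariates, psqi_fit, phq9_fit, config) {
  paths <- simulate_paths(tibble::as_tibble(covariates)[1, ], psqi_fit,
                          phq9_fit, config)
  tibble::tibble(day = seq_len(config$horizon),
                 psqi = as.numeric(paths$psqi),
                 phq9 = as.numeric(paths$phq9))
}

# Vectorized trajectory engine: simulates all rows of `covariates`
# simultaneously, one coupled synchronous update per day. Returns
# n x horizon matrices. Optional prediction noise uses the current RNG
# stream (seed management is the caller's).
simulate_paths <- function(covariates, psqi_fit, phq9_fit, config) {
  n <- nrow(covariates)
  dm <- config$demand * config$demand_multiplier
  for (v in names(dm)) covariates[[v]] <- dm[[v]]
  s_psqi <- rep(config$init_psqi, n)
  s_phq9 <- rep(config$init_phq9, n)
  eps_psqi <- eps_phq9 <- matrix(0, n, config$horizon)
  if (config$noise) {
    eps_psqi <- matrix(rnorm(n * config$horizon, sd = config$noise_sd),
                       n, config$horizon)
    eps_phq9 <- matrix(rnorm(n * config$horizon, sd = config$noise_sd),
                       n, config$horizon)
  }
  out_psqi <- out_phq9 <- matrix(NA_real_, n, config$horizon)
  for (t in seq_len(config$horizon)) {
    cov_psqi <- covariates; cov_psqi$phq9 <- s_phq9
    cov_phq9 <- covariates; cov_phq9$psqi <- s_psqi
    p_psqi <- predict_score(psqi_fit, cov_psqi) + eps_psqi[, t]
    p_phq9 <- predict_score(phq9_fit, cov_phq9) + eps_phq9[, t]
    s_psqi <- clip(ews_update(s_psqi, p_psqi, config$alpha), 0, 21)
    s_phq9 <- clip(ews_update(s_phq9, p_phq9, config$alpha), 0, 27)
    out_psqi[, t] <- s_psqi
    out_phq9[, t] <- s_phq9
  }
  list(psqi = out_psqi, phq9 = out_phq9)
}

#' Bootstrap population trajectory simulation
#'
#' Draws `n_individuals` virtual nurses from the cohort with replacement
#' and simulates each with [simulate_individual()], reporting the per-day
#' cross-individual mean and SD of both scores and the day the mean
#' trajectory first crosses each clinical threshold.
#'
#' @param cohort Cohort tibble to bootstrap from.
#' @inheritParams simulate_individual
#' @return A `trajectory_set`: tibble with `group`, `day`, `mean_psqi`,
#'   `sd_psqi`, `mean_phq9`, `sd_phq9`; crossing days in
#'   `attr(, "crossings")`.
#' @export
simulate_population <- function(cohort, psqi_fit, phq9_fit, config,
                                group = "population") {
  stopifnot(nrow(cohort) >= 1)
  paths <- with_seed(config$seed, {
    idx <- sample(nrow(cohort), config$n_individuals, replace = TRUE)
    simulate_paths(tibble::as_tibble(cohort)[idx, ], psqi_fit, phq9_fit,
                   config)
  })
  sd0 <- function(m) if (nrow(m) > 1) apply(m, 2, sd) else rep(0, ncol(m))
  traj <- tibble::tibble(
    group = group,
    day = seq_len(config$horizon),
    mean_psqi = colMeans(paths$psqi), sd_psqi = sd0(paths$psqi),
    mean_phq9 = colMeans(paths$phq9), sd_phq9 = sd0(paths$phq9)
  )
  attr(traj, "crossings") <- tibble::tibble(
    group = group,
    psqi_crossing_day = crossing_day(traj$mean_psqi, 7, ">"),
    phq9_crossing_day = crossing_day(traj$mean_phq9, 10, ">="),
    psqi_crossing_fraction = mean(apply(paths$psqi, 1,
                                        function(r) any(r > 7))),
    phq9_crossing_fraction = mean(apply(paths$phq9, 1,
                                        function(r) any(r >= 10)))
  )
  attr(traj, "config") <- config
  class(traj) <- c("trajectory_set", class(traj))
  traj
}

#' Classify circadian adaptability profiles
#'
#' Percentile rules over the cohort's FR (flexibility) and LV
#' (languidness) distributions: moderate (M) — both scores between the
#' 25th and 75th percentiles; high (H) — FR at or above the 75th and LV at
#' or below the 25th; low (L) — FR at or below the 25th and LV at or above
#' the 75th. H and L take precedence over M at the shared boundaries;
#' anything else is UNCLASSIFIED.
#'
#' @param fr,lv Score vectors.
#' @param fr_quartiles,lv_quartiles Optional `c(p25, p75)` reference
#'   quartiles; computed from `fr`/`lv` when `NULL`.
#' @return Character vector in `{"M", "H", "L", "UNCLASSIFIED"}`.
#' @examples
#' cohort <- generate_cohort(288, seed = 1)
#' table(classify_adaptability(cohort$fr, cohort$lv))
#' @export
classify_adaptability <- function(fr, lv, fr_quartiles = NULL,
                                  lv_quartiles = NULL) {
  fq <- fr_quartiles %||% quantile(fr, c(0.25, 0.75), names = FALSE)
  lq <- lv_quartiles %||% quantile(lv, c(0.25, 0.75), names = FALSE)
  dplyr::case_when(
    fr >= fq[2] & lv <= lq[1] ~ "H",
    fr <= fq[1] & lv >= lq[2] ~ "L",
    fr >= fq[1] & fr <= fq[2] & lv >= lq[1] & lv <= lq[2] ~ "M",
    TRUE ~ "UNCLASSIFIED"
  )
}

#' Scenario grid over adaptability profiles and demand multipliers
#'
#' For every adaptability group present in the cohort and every demand
#' multiplier, bootstraps `n_individuals` members from the group and
#' simulates their coupled trajectories under the scaled demand bundle.
#'
#' @param cohort Cohort tibble (must contain `fr` and `lv`).
#' @param multipliers Demand multipliers applied jointly to the bundle.
#' @param groups Which profiles to simulate.
#' @inheritParams simulate_individual
#' @return A list with `trajectories` (stacked `trajectory_set` rows with
#'   `group` and `multiplier`) and `summary` (crossing days per cell).
#' @export
scenario_run <- function(cohort, psqi_fit, phq9_fit,
                         config = simulation_config(),
                         multipliers = c(0.25, 1, 1.5, 2),
                         groups = c("M", "H", "L")) {
  profile <- classify_adaptability(cohort$fr, cohort$lv)
  cells <- tidyr::expand_grid(group = groups, multiplier = multipliers)
  res <- purrr::pmap(cells, function(group, multiplier) {
    members <- cohort[profile == group, ]
    if (nrow(members) == 0) return(NULL)
    cfg <- config
    cfg$demand_multiplier <- multiplier
    cfg$seed <- config$seed + round(1000 * multiplier) +
      match(group, groups)
    tr <- simulate_population(members, psqi_fit, phq9_fit, cfg,
                              group = group)
    tr$multiplier <- multiplier
    tr
  })
  res <- purrr::compact(res)
  trajectories <- dplyr::bind_rows(lapply(res, function(tr) {
    tibble::as_tibble(tr)
  }))
  summary <- purrr::map_dfr(res, function(tr) {
    cr <- attr(tr, "crossings")
    cr$multiplier <- tr$multiplier[1]
    cr$final_psqi <- tr$mean_psqi[nrow(tr)]
    cr$final_phq9 <- tr$mean_phq9[nrow(tr)]
    cr
  })
  list(trajectories = trajectories, summary = summary)
}

#' First day a trajectory crosses a clinical threshold
#'
#' The screening conventions: insomnia when mean PSQI exceeds 7
#' (direction `">"`), probable depression when mean PHQ-9 reaches 10
#' (direction `">="`).
#'
#' @param trajectory Numeric vector indexed by day.
#' @param threshold Threshold value.
#' @param direction `">"` or `">="`.
#' @return First day index, or `NA` when never crossed.
#' @examples
#' crossing_day(8 - 7 * 0.8^(1:100), 7, ">")  # closed form: day 9
#' @export
crossing_day <- function(trajectory, threshold, direction = ">") {
  hit <- switch(direction,
    ">" = trajectory > threshold,
    ">=" = trajectory >= threshold,
    abort("direction must be '>' or '>='")
  )
  if (!any(hit)) return(NA_integer_)
  which(hit)[1]
}
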