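#' Read and write the pipeline's tabular artifacts
#'
#' Cohort, shift-log and census tables travel as UTF-8 CSV with ISO-8601
#' timestamps. Reads are schema-validated: required columns must be
#' present and numeric columns must parse without coercion.
#'
#' @param path CSV file path.
#' @param x Object to write.
#' @return Read functions return validated tibbles; write functions return
#'   `path` invisibly.
#' @name pipeline_io
NULL

read_checked <- function(path, required, timestamp = character()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0(basename(path), " is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(sprintf("%s: malformed value at line %d, column %s",
                  basename(path), prob$row[1] + 1, prob$col[1]))
  }
  for (tc in timestamp) {
    raw <- as.character(df[[tc]])
    parsed <- as.POSIXct(raw, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    alt <- as.POSIXct(raw, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    parsed[is.na(parsed)] <- alt[is.na(parsed)]
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1]
      abort(sprintf("%s: unparseable ISO-8601 timestamp in '%s', line %d",
                    basename(path), tc, bad + 1L))
    }
    df[[tc]] <- parsed
  }
  df
}

#' @rdname pipeline_io
#' @export
read_cohort <- function(path) {
  read_checked(path, c("nurse_id", "psqi", "phq9", "fr", "lv"))
}

#' @rdname pipeline_io
#' @export
write_cohort <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_shift_log <- function(path) {
  read_checked(path, c("nurse_id", "start", "end", "nap_hours", "unit_id"),
               timestamp = c("start", "end"))
}

#' @rdname pipeline_io
#' @export
write_shift_log <- function(x, path) {
  x <- dplyr::mutate(
    tibble::as_tibble(x),
    start = format(.data$start, "%Y-%m-%dT%H:%M:%S"),
    end = format(.data$end, "%Y-%m-%dT%H:%M:%S"))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_census <- function(path) {
  read_checked(path, c("unit_id", "period", "active_nurses",
                       "assigned_patients", "cmi"))
}

#' Configure an end-to-end pipeline run
#'
#' All analysis thresholds are surfaced here with their conventional
#' defaults: the insomnia cutoff (PSQI > 7), the probable-depression
#' cutoff (PHQ-9 >= 10), the VIF acceptability limit (5), the EDoF
#' nonlinearity flag (1.2) and the two-tailed significance level (0.05).
#'
#' @param n_nurses Cohort size for generator-driven runs.
#' @param seed Master seed; every stage derives its RNG stream from it.
#' @param cohort_path,shift_log_path,census_path Optional CSV inputs; when
#'   absent the synthetic generator supplies them.
#' @param moderators Candidate moderators to compare.
#' @param simulation A [simulation_config()].
#' @param multipliers Demand multipliers for the scenario stage.
#' @param stages Which stages to run.
#' @param psqi_cutoff,phq9_cutoff,vif_limit,edof_flag,alpha Thresholds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_nurses = 288, seed = 1, cohort_path = NULL,
                            shift_log_path = NULL, census_path = NULL,
                            moderators = c("shift_work_hours",
                                           "night_count",
                                           "shift_workload_exposure"),
                            simulation = simulation_config(seed = seed),
                            multipliers = c(0.25, 1, 1.5, 2),
                            stages = c("generate", "demand", "univariate",
                                       "glm", "nonlinear", "simulate"),
                            psqi_cutoff = 7, phq9_cutoff = 10,
                            vif_limit = 5, edof_flag = 1.2,
                            alpha = 0.05) {
  structure(list(n_nurses = n_nurses, seed = seed, cohort_path = cohort_path,
                 shift_log_path = shift_log_path,
                 census_path = census_path, moderators = moderators,
                 simulation = simulation, multipliers = multipliers,
                 stages = stages, psqi_cutoff = psqi_cutoff,
                 phq9_cutoff = phq9_cutoff, vif_limit = vif_limit,
                 edof_flag = edof_flag, alpha = alpha),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; keys under
#' `simulation` mirror [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(paste0("unknown configuration keys: ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: cohort acquisition (CSV or
#' synthetic generator), shift-log demand summaries, univariate screen,
#' candidate moderated GLM comparison for both outcomes, GAM/breakpoint
#' nonlinearity analysis of the demand variables, and the population and
#' scenario trajectory simulations. Every result carries the master seed
#' in its provenance.
#'
#' @param config A [pipeline_config()].
#' @return A named result bundle (list).
#' @examples
#' \donttest{
#' bundle <- run_pipeline(pipeline_config(n_nurses = 200, seed = 1))
#' bundle$glm$psqi$comparison$table
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list(config = config)

  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path)
  } else {
    generate_cohort(config$n_nurses, seed = config$seed)
  }
  bundle$cohort <- cohort

  if ("demand" %in% config$stages) {
    log <- if (!is.null(config$shift_log_path)) {
      list(events = read_shift_log(config$shift_log_path),
           census = if (!is.null(config$census_path)) {
             read_census(config$census_path)
           },
           window_start = as.Date(min(
             read_shift_log(config$shift_log_path)$start)))
    } else {
      generate_shift_log(config$n_nurses, seed = config$seed + 1)
    }
    bundle$demand <- summarize_demand(log$events, log$window_start,
                                      log$census)
    excluded <- attr(bundle$demand, "intensity_excluded")
    if (length(excluded)) {
      warn(sprintf(
        "%d nurses lack census coverage; excluded from intensity analysis",
        length(excluded)))
    }
  }

  if ("univariate" %in% config$stages) {
    bundle$univariate <- univariate_screen(cohort)
  }

  if ("glm" %in% config$stages) {
    bundle$glm <- lapply(
      setNames(c("psqi", "phq9"), c("psqi", "phq9")),
      function(outcome) {
        spec_fun <- if (outcome == "psqi") psqi_spec else phq9_spec
        fits <- lapply(setNames(config$moderators, config$moderators),
                       function(m) fit_shift_glm(cohort, spec_fun(m)))
        cmp <- compare_candidates(fits)
        list(fits = fits, comparison = cmp, selected = cmp$selected,
             diagnostics = residual_diagnostics(cmp$selected))
      })
  }

  if ("nonlinear" %in% config$stages) {
    demand_vars <- intersect(
      c("night_count", "shift_work_hours", "shift_workload_exposure"),
      names(cohort))
    bundle$nonlinear <- lapply(
      setNames(c("psqi", "phq9"), c("psqi", "phq9")),
      function(outcome) {
        others <- setdiff(c("psqi", "phq9"), outcome)
        gam <- fit_gam_screen(
          cohort, outcome,
          smooth_terms = c(others, "fr", "lv", "age", "bmi", demand_vars),
          factor_terms = "gender", edof_flag = config$edof_flag,
          alpha = config$alpha)
        flagged <- gam$terms$term[gam$terms$nonlinear &
                                    gam$terms$term %in% demand_vars]
        breakpoints <- lapply(setNames(flagged, flagged), function(v) {
          fit_breakpoint(cohort, v, outcome)
        })
        list(gam = gam, breakpoints = breakpoints)
      })
  }

  if ("simulate" %in% config$stages && !is.null(bundle$glm)) {
    psqi_fit <- bundle$glm$psqi$selected
    phq9_fit <- bundle$glm$phq9$selected
    bundle$population <- simulate_population(cohort, psqi_fit, phq9_fit,
                                             config$simulation)
    bundle$scenarios <- scenario_run(cohort, psqi_fit, phq9_fit,
                                     config$simulation,
                                     multipliers = config$multipliers)
  }
  bundle
}

#' Write a pipeline result bundle to CSV files
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(x, name) {
    readr::write_csv(tibble::as_tibble(x), file.path(dir, name))
  }
  write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  if (!is.null(bundle$demand)) out(bundle$demand, "demand_summary.csv")
  if (!is.null(bundle$univariate)) {
    out(bundle$univariate$correlations, "spearman_matrix.csv")
    out(bundle$univariate$group_tests, "group_tests.csv")
  }
  if (!is.null(bundle$glm)) {
    for (outcome in names(bundle$glm)) {
      out(tidy(bundle$glm[[outcome]]$selected),
          paste0("glm_", outcome, "_coefficients.csv"))
      out(bundle$glm[[outcome]]$comparison$table,
          paste0("glm_", outcome, "_comparison.csv"))
    }
  }
  if (!is.null(bundle$nonlinear)) {
    for (outcome in names(bundle$nonlinear)) {
      out(bundle$nonlinear[[outcome]]$gam$terms,
          paste0("gam_", outcome, "_terms.csv"))
    }
  }
  if (!is.null(bundle$population)) out(bundle$population,
                                       "population_trajectories.csv")
  if (!is.null(bundle$scenarios)) {
    out(bundle$scenarios$trajectories, "scenario_trajectories.csv")
    out(bundle$scenarios$summary, "scenario_summary.csv")
  }
  jsonlite::write_json(list(seed = bundle$config$seed,
                            n = bundle$config$n_nurses),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
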