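# Shared fixtures: fitted reference models built once per test run from
# model-mode cohorts planted with the published coefficient sets.
fixture_env <- new.env(parent = emptyenv())

test_fits <- function() {
  if (is.null(fixture_env$fits)) {
    psqi_cohort <- generate_cohort_glm(psqi_model_truth(), n = 288,
                                       seed = 4201)
    phq9_cohort <- generate_cohort_glm(phq9_model_truth(), n = 288,
                                       seed = 4202)
    fixture_env$fits <- list(
      psqi = fit_shift_glm(psqi_cohort, psqi_spec()),
      phq9 = fit_shift_glm(phq9_cohort, phq9_spec())
    )
  }
  fixture_env$fits
}

test_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- generate_cohort(288, seed = 4200)
  }
  fixture_env$cohort
}

# Brute-force Spearman: rank (average ties) then Pearson.
oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# Brute-force Kruskal-Wallis H with tie correction.
oracle_kruskal <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Brute-force Mann-Whitney U (count of pairs where x beats y, ties 0.5).
oracle_mann_whitney <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Minute-resolution oracle for worked hours inside a daily clock window.
oracle_window_hours <- function(start, end, from, to) {
  mins <- seq(as.numeric(start), as.numeric(end) - 60, by = 60)
  hod <- (mins %% 86400) / 3600
  sum(hod >= from & hod < to) / 60
}
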