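test_that("the smoothing update is the declared convex combination", {
  expect_equal(ews_update(1, 8, 0.2), 2.4)
  expect_equal(ews_update(5, 5, 0.7), 5)  # fixed point
  # constant prediction P from start s0: day-t value P + (s0-P)(1-a)^t
  s <- 1
  for (t in 1:50) s <- ews_update(s, 8, 0.2)
  expect_equal(s, 8 + (1 - 8) * 0.8^50, tolerance = 1e-12)
})

test_that("threshold crossing matches the closed-form day", {
  path <- vapply(1:100, function(t) 8 + (1 - 8) * 0.8^t, numeric(1))
  expect_equal(crossing_day(path, 7, ">"),
               as.integer(ceiling(log(1 / 7) / log(0.8))))  # day 9
  expect_equal(crossing_day(path, 7, ">"), 9L)
  expect_true(is.na(crossing_day(path, 10, ">")))
  expect_equal(crossing_day(c(9, 9.5, 10, 11), 10, ">="), 3L)
  expect_error(crossing_day(path, 7, "<"), "direction")
})

test_that("raw-scale predictions invert the recipe correctly", {
  fit <- test_fits()$psqi
  co <- test_cohort()
  # at the training medians every standardized main is the transformed
  # median; verify against an explicit hand chain on one row
  row <- co[5, ]
  pred <- predict_score(fit, row)
  d <- build_design(row, fit$spec, recipe = fit$recipe)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  eta <- beta[["(Intercept)"]] +
    sum(beta[names(d$x)] * as.numeric(d$x[1, ]))
  expect_equal(pred, min(max(exp(eta), 0), 21), tolerance = 1e-12)
  expect_true(all(predict_score(fit, co) >= 0 &
                    predict_score(fit, co) <= 21))
})

test_that("predicted sleep quality rises with the depression input", {
  fit <- test_fits()$psqi
  row <- test_cohort()[1, ]
  lo <- hi <- row
  lo$phq9 <- 2; hi$phq9 <- 15
  expect_gt(predict_score(fit, hi), predict_score(fit, lo))
})

test_that("coupled paths match an independent synchronous recursion", {
  fits <- test_fits()
  cfg <- simulation_config(horizon = 40, noise = FALSE)
  row <- test_cohort()[3, ]
  got <- simulate_individual(row, fits$psqi, fits$phq9, cfg)

  cov <- row
  dm <- cfg$demand * cfg$demand_multiplier
  for (v in names(dm)) cov[[v]] <- dm[[v]]
  s_p <- cfg$init_psqi; s_q <- cfg$init_phq9
  for (t in 1:40) {
    cp <- cov; cp$phq9 <- s_q
    cq <- cov; cq$psqi <- s_p
    pp <- predict_score(fits$psqi, cp)
    pq <- predict_score(fits$phq9, cq)
    s_p <- min(max(0.2 * pp + 0.8 * s_p, 0), 21)
    s_q <- min(max(0.2 * pq + 0.8 * s_q, 0), 27)
    expect_equal(got$psqi[t], s_p, tolerance = 1e-9)
    expect_equal(got$phq9[t], s_q, tolerance = 1e-9)
  }
})

test_that("trajectories stay inside instrument bounds and rise to the
           fixed point from a low-symptom start", {
  fits <- test_fits()
  cfg <- simulation_config(horizon = 60)
  tr <- simulate_individual(test_cohort()[2, ], fits$psqi, fits$phq9, cfg)
  expect_true(all(tr$psqi >= 0 & tr$psqi <= 21))
  expect_true(all(tr$phq9 >= 0 & tr$phq9 <= 27))
  expect_true(all(diff(tr$psqi) > -1e-9))
  expect_true(all(diff(tr$phq9) > -1e-9))
})

test_that("alpha = 1 jumps to the prediction immediately", {
  fits <- test_fits()
  cfg <- simulation_config(alpha = 1, horizon = 3)
  row <- test_cohort()[4, ]
  tr <- simulate_individual(row, fits$psqi, fits$phq9, cfg)
  cov <- row
  dm <- cfg$demand
  for (v in names(dm)) cov[[v]] <- dm[[v]]
  cov$phq9 <- cfg$init_phq9
  expect_equal(tr$psqi[1],
               min(max(predict_score(fits$psqi, cov), 0), 21),
               tolerance = 1e-9)
})

test_that("population simulation is seed-deterministic with honest bands", {
  fits <- test_fits()
  co <- test_cohort()
  cfg <- simulation_config(horizon = 25, n_individuals = 50, seed = 9)
  a <- simulate_population(co, fits$psqi, fits$phq9, cfg)
  b <- simulate_population(co, fits$psqi, fits$phq9, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$sd_psqi >= 0))

  one <- simulate_population(co[7, ], fits$psqi, fits$phq9, cfg)
  expect_lt(max(one$sd_psqi), 1e-10)  # identical individuals, zero band
  expect_lt(max(one$sd_phq9), 1e-10)
  cr <- attr(a, "crossings")
  expect_true(is.na(cr$psqi_crossing_day) ||
                a$mean_psqi[cr$psqi_crossing_day] > 7)
})

test_that("prediction noise is reproducible and widens nothing at sd=0", {
  fits <- test_fits()
  co <- test_cohort()
  cfg <- simulation_config(horizon = 10, n_individuals = 20, seed = 3,
                           noise = TRUE, noise_sd = 1)
  a <- simulate_population(co, fits$psqi, fits$phq9, cfg)
  b <- simulate_population(co, fits$psqi, fits$phq9, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("adaptability profiles follow the percentile rules", {
  q <- c(10, 20)  # explicit reference quartiles
  expect_equal(classify_adaptability(25, 5, q, q), "H")
  expect_equal(classify_adaptability(15, 15, q, q), "M")
  expect_equal(classify_adaptability(5, 25, q, q), "L")
  expect_equal(classify_adaptability(5, 5, q, q), "UNCLASSIFIED")
  # boundary: H beats M when both rules match
  expect_equal(classify_adaptability(20, 10, q, q), "H")
  co <- test_cohort()
  labels <- classify_adaptability(co$fr, co$lv)
  expect_true(all(labels %in% c("M", "H", "L", "UNCLASSIFIED")))
  expect_gt(sum(labels == "M"), 0)
})

test_that("scenario runs order dose-response by demand multiplier", {
  fits <- test_fits()
  co <- test_cohort()
  sc <- scenario_run(co, fits$psqi, fits$phq9,
                     simulation_config(horizon = 50, n_individuals = 60,
                                       seed = 11),
                     multipliers = c(0.5, 1, 2), groups = c("M", "L"))
  sm <- sc$summary[sc$summary$group == "M", ]
  sm <- sm[order(sm$multiplier), ]
  expect_true(all(diff(sm$final_psqi) > 0))  # monotone dose-response
  expect_true(all(sc$trajectories$mean_psqi <= 21))
  expect_setequal(unique(sc$trajectories$group), c("M", "L"))
})
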