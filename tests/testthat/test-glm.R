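test_that("design construction standardizes mains and forms products", {
  co <- test_cohort()
  spec0 <- model_spec("psqi", mains = c("phq9", "lv", "gender"))
  d0 <- build_design(co, spec0)
  expect_equal(names(d0$x), c("phq9", "lv", "gender"))

  spec <- psqi_spec()
  d <- build_design(co, spec)
  expect_equal(ncol(d$x), 13)  # published sleep-quality model width
  expect_equal(d$x[["phq9:lv"]], d$x$phq9 * d$x$lv, tolerance = 1e-12)
  expect_true(all(d$x$gender %in% 0:1))
  expect_equal(mean(d$x$phq9), 0, tolerance = 1e-10)

  expect_equal(ncol(build_design(co, phq9_spec())$x), 14)

  rec <- learn_recipe(co, "phq9")
  expect_error(build_design(co, spec, recipe = rec), "lv")
})

test_that("model specs validate interactions and moderators", {
  expect_error(model_spec("psqi", mains = "phq9",
                          interactions = "phq9:lv"), "main effects")
  expect_error(model_spec("psqi", mains = c("phq9", "lv"),
                          moderator = "shift_work_hours"), "moderator")
})

test_that("a null log-link model recovers log of the sample mean", {
  set.seed(41)
  co <- tibble::tibble(y = rpois(200, 6))
  spec <- model_spec("y", mains = character(), binary = character())
  fit <- fit_shift_glm(co, spec)
  intercept <- fit$coefficients$estimate[1]
  expect_equal(unname(intercept), log(mean(co$y)), tolerance = 1e-8)
})

test_that("estimates match a direct likelihood-maximization oracle", {
  set.seed(42)
  n <- 20
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  eta <- 1.5 + 0.4 * d$x1 - 0.3 * d$x2
  d$y <- rpois(n, exp(eta))
  spec <- model_spec("y", mains = c("x1", "x2"), binary = character())
  fit <- fit_shift_glm(d, spec)
  dd <- build_design(d, spec)
  X <- cbind(1, as.matrix(dd$x))
  nll <- function(b) -sum(d$y * (X %*% b) - exp(X %*% b))
  ora <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients$estimate), unname(ora$par),
               tolerance = 1e-6)
})

test_that("planted coefficient sets are recovered without material bias", {
  est <- vapply(1:25, function(s) {
    cg <- generate_cohort_glm(psqi_model_truth(), n = 288, seed = s)
    fit <- fit_shift_glm(cg, psqi_spec())
    co <- tidy(fit)
    setNames(co$estimate, co$term)[c("phq9", "shift_work_hours", "lv")]
  }, numeric(3))
  expect_equal(unname(rowMeans(est)), c(0.245, 0.093, 0.065),
               tolerance = 0.035)
})

test_that("information criteria identities hold from stored pieces", {
  fits <- test_fits()
  for (f in fits) {
    expect_equal(f$aic, -2 * f$log_lik + 2 * f$k, tolerance = 1e-10)
    expect_equal(f$bic, -2 * f$log_lik + f$k * log(f$n),
                 tolerance = 1e-10)
    co <- f$coefficients
    expect_equal(co$conf_low, co$estimate - 1.96 * co$std_error)
    expect_equal(co$conf_high, co$estimate + 1.96 * co$std_error)
    expect_true(f$pseudo_r2 > 0 && f$pseudo_r2 < 1)
  }
})

test_that("variance inflation factors match their analytic values", {
  set.seed(43)
  n <- 500
  z1 <- as.numeric(scale(rnorm(n)))
  e <- as.numeric(scale(residuals(lm(rnorm(n) ~ z1))))
  x2 <- 0.8 * z1 + 0.6 * e  # empirical Pearson r exactly 0.8
  v <- vif(cbind(a = z1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-6)

  ortho <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  expect_equal(unname(vif(ortho)), rep(1, 3), tolerance = 1e-3)

  dup <- cbind(z1, z1)
  expect_true(all(is.infinite(vif(dup))))
})

test_that("interaction products are order-invariant", {
  co <- test_cohort()
  s1 <- model_spec("psqi", mains = c("phq9", "lv"),
                   interactions = "phq9:lv", binary = character())
  s2 <- model_spec("psqi", mains = c("phq9", "lv"),
                   interactions = "lv:phq9", binary = character())
  f1 <- fit_shift_glm(co, s1)
  f2 <- fit_shift_glm(co, s2)
  expect_equal(f1$log_lik, f2$log_lik, tolerance = 1e-10)
  expect_equal(unname(tidy(f1)$estimate[4]), unname(tidy(f2)$estimate[4]),
               tolerance = 1e-10)
})

test_that("candidate ranking uses AIC then parsimony", {
  stub <- function(ll, k, n = 100, r2 = 0.4, moderator = "m") {
    structure(list(spec = list(moderator = moderator),
                   log_lik = ll, aic = -2 * ll + 2 * k,
                   bic = -2 * ll + k * log(n), pseudo_r2 = r2,
                   n = n, k = k), class = "shift_glm")
  }
  cmp <- compare_candidates(list(a = stub(-10, 3), b = stub(-10, 2)))
  expect_equal(cmp$table$model[1], "b")
  expect_equal(cmp$table$aic, c(24, 26))

  tie <- compare_candidates(list(a = stub(-10, 3), b = stub(-11, 2)))
  # AIC ties at 26; BIC prefers the more parsimonious model
  expect_equal(tie$table$model[1], "b")
})

test_that("moderator selection finds the generating demand variable", {
  # a generator whose moderation clearly runs through shift work hours
  truth <- glm_truth("psqi", c(
    "(Intercept)" = 2.1, "phq9" = 0.25, "shift_work_hours" = 0.09,
    "phq9:shift_work_hours" = -0.15, "lv" = 0.07, "night_count" = -0.05,
    "shift_workload_exposure" = 0.0, "bmi" = -0.06))
  wins <- vapply(1:12, function(s) {
    cg <- generate_cohort_glm(truth, n = 288, seed = 600 + s)
    fits <- lapply(
      setNames(c("shift_work_hours", "night_count",
                 "shift_workload_exposure"),
               c("shift_work_hours", "night_count",
                 "shift_workload_exposure")),
      function(m) fit_shift_glm(cg, psqi_spec(m)))
    compare_candidates(fits)$table$model[1]
  }, character(1))
  expect_gt(mean(wins == "shift_work_hours"), 0.5)
})

test_that("residual diagnostics flag misspecification and pass when clean", {
  fits <- test_fits()
  diag_ok <- residual_diagnostics(fits$psqi)
  qq <- diag_ok$qq
  slope <- coef(lm(empirical ~ theoretical, data = qq))[2]
  expect_equal(unname(slope), 1, tolerance = 0.25)

  set.seed(44)
  x <- runif(300, -2, 2)
  d <- tibble::tibble(y = rpois(300, exp(1 + 0.8 * x^2)), x = x)
  bad <- fit_shift_glm(d, model_spec("y", mains = "x",
                                     binary = character()))
  r <- residual_diagnostics(bad)$residuals
  # U-shaped residual trend: residuals correlate with the squared predictor
  expect_gt(cor(r$deviance_residual, scale(d$x)^2), 0.2)
})

test_that("tidy and glance expose the fit in broom style", {
  f <- test_fits()$psqi
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "p_value") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$n, 288)
  expect_equal(gl$moderator, "shift_work_hours")
  expect_lt(gl$max_vif, 5)
})
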