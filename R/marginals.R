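#' Declare a bounded questionnaire-score marginal
#'
#' Defines the marginal distribution of a bounded (typically integer-valued)
#' instrument score as a beta distribution rescaled to `[lo, hi]` and, for
#' discrete scores, rounded to the nearest integer. The beta shape parameters
#' are solved numerically so that the distribution reproduces the published
#' summary statistics: the median, the interquartile range, and (optionally)
#' the proportion screening positive at a clinical cutoff. All three targets
#' are quantile constraints in score units, so they enter a single
#' least-squares objective on the beta quantile function.
#'
#' @param name Variable name used as the cohort column name.
#' @param lo,hi Support bounds in score units (`lo < hi`).
#' @param median Target median in score units; must lie in `[lo, hi]`.
#' @param iqr Target interquartile range; must be in `[0, hi - lo]`.
#' @param cutoff Optional clinical screening cutoff in score units.
#' @param cutoff_prevalence Proportion expected to screen positive at
#'   `cutoff` (required when `cutoff` is given).
#' @param cutoff_direction `">"` if screening positive means strictly above
#'   the cutoff, `">="` if at-or-above.
#' @param anchors Optional list of extra `c(prob, value)` quantile anchors,
#'   e.g. published category proportions for a continuous measure.
#' @param discrete Round generated values to integers? Default `TRUE`.
#'
#' @return An object of class `marginal_spec` carrying the solved beta shape
#'   parameters in `$alpha`, `$beta`.
#' @examples
#' psqi <- beta_marginal("psqi", 1, 17, median = 8, iqr = 4,
#'                       cutoff = 7, cutoff_prevalence = 0.5139)
#' psqi$alpha
#' @export
beta_marginal <- function(name, lo, hi, median, iqr,
                          cutoff = NULL, cutoff_prevalence = NULL,
                          cutoff_direction = ">",
                          anchors = list(), discrete = TRUE) {
  stopifnot(lo < hi, median >= lo, median <= hi, iqr >= 0, iqr <= hi - lo)
  pts <- list(c(0.5, median))
  if (!is.null(cutoff)) {
    if (is.null(cutoff_prevalence)) {
      abort("`cutoff_prevalence` is required when `cutoff` is given")
    }
    # For a rounded score, "> c" happens iff the continuous draw exceeds
    # c + 0.5 (">= c" iff it exceeds c - 0.5): anchor the corresponding
    # quantile at the complement of the prevalence.
    edge <- if (cutoff_direction == ">") cutoff + 0.5 else cutoff - 0.5
    pts <- c(pts, list(c(1 - cutoff_prevalence, edge)))
  }
  pts <- c(pts, anchors)
  shape <- solve_beta_shape(lo, hi, pts, iqr)
  structure(
    list(name = name, family = "beta", lo = lo, hi = hi,
         target_median = median, target_iqr = iqr,
         cutoff = cutoff, cutoff_prevalence = cutoff_prevalence,
         cutoff_direction = cutoff_direction,
         alpha = shape[1], beta = shape[2], discrete = discrete),
    class = "marginal_spec"
  )
}

# Least squares over quantile anchors (prob, value) plus an IQR target,
# all expressed in score units on the rescaled support.
solve_beta_shape <- function(lo, hi, points, iqr = NULL) {
  r <- hi - lo
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    e <- sum(vapply(points, function(pt) {
      (qbeta(pt[1], a, b) * r + lo - pt[2])^2
    }, numeric(1)))
    if (!is.null(iqr)) {
      q <- qbeta(c(0.25, 0.75), a, b) * r + lo
      e <- e + (q[2] - q[1] - iqr)^2
    }
    e
  }
  fit <- optim(c(0, 0), obj, control = list(maxit = 5000, reltol = 1e-14))
  exp(fit$par)
}

#' Declare a Bernoulli (binary) marginal
#'
#' @param name Variable name.
#' @param prob Probability of the value 1 (e.g. female = 1).
#' @return A `marginal_spec`.
#' @export
bernoulli_marginal <- function(name, prob) {
  stopifnot(prob >= 0, prob <= 1)
  structure(list(name = name, family = "bernoulli", prob = prob,
                 lo = 0, hi = 1, discrete = TRUE),
            class = "marginal_spec")
}

#' Declare a discrete-uniform marginal
#'
#' @param name Variable name.
#' @param lo,hi Integer support bounds.
#' @return A `marginal_spec`.
#' @export
uniform_marginal <- function(name, lo, hi) {
  stopifnot(lo < hi)
  structure(list(name = name, family = "uniform", lo = lo, hi = hi,
                 discrete = TRUE),
            class = "marginal_spec")
}

# Quantile map from copula uniforms onto the declared marginal.
marginal_quantile <- function(spec, u) {
  x <- switch(spec$family,
    beta = spec$lo + (spec$hi - spec$lo) * qbeta(u, spec$alpha, spec$beta),
    bernoulli = as.numeric(u > 1 - spec$prob),
    uniform = spec$lo + u * (spec$hi - spec$lo),
    abort(paste0("unknown marginal family '", spec$family, "'"))
  )
  if (isTRUE(spec$discrete) && spec$family != "bernoulli") {
    x <- clip(round(x), spec$lo, spec$hi)
  }
  x
}

#' @export
print.marginal_spec <- function(x, ...) {
  cat("<marginal_spec>", x$name, "-", x$family,
      sprintf("on [%g, %g]", x$lo, x$hi), "\n")
  if (x$family == "beta") {
    cat(sprintf("  median %g, IQR %g, shape (%.3f, %.3f)\n",
                x$target_median, x$target_iqr, x$alpha, x$beta))
  }
  invisible(x)
}
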