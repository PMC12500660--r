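#' Flag and remove extreme outliers with 3xIQR fences
#'
#' Values outside `[Q1 - 3 IQR, Q3 + 3 IQR]` are set to missing. The wide
#' 3xIQR multiplier (rather than the exploratory 1.5x) reflects that
#' bounded, skewed instrument scores legitimately occupy their tails.
#' Quartiles use the linear-interpolation convention (`type = 7`).
#'
#' @param x Numeric vector with at least 8 non-missing values.
#' @return A list with `values` (fenced vector), `flagged` (logical),
#'   and `fences` (length-2 numeric).
#' @examples
#' fence_outliers(c(rpois(30, 8), 1e6))$fences
#' @export
fence_outliers <- function(x) {
  if (sum(!is.na(x)) < 8) abort("need at least 8 non-missing values")
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 3 * iqr, q[2] + 3 * iqr)
  flagged <- !is.na(x) & (x < fences[1] | x > fences[2])
  x[flagged] <- NA
  list(values = x, flagged = flagged, fences = fences)
}

#' Impute missing values by median or mode
#'
#' @param x Vector with missing values.
#' @param kind `"continuous"` (median) or `"categorical"` (mode).
#' @param max_fraction Abort if more than this fraction is missing.
#' @return A list with `values`, `imputed` (value used), `n_imputed`.
#' @export
impute_missing <- function(x, kind = c("continuous", "categorical"),
                           max_fraction = 0.2) {
  kind <- match.arg(kind)
  miss <- is.na(x)
  if (all(miss)) abort("cannot impute an all-missing column")
  if (mean(miss) > max_fraction) {
    abort(sprintf("%.0f%% missing exceeds the %.0f%% limit",
                  100 * mean(miss), 100 * max_fraction))
  }
  fill <- if (kind == "continuous") {
    median(x, na.rm = TRUE)
  } else {
    tab <- table(x)
    names(tab)[which.max(tab)]
  }
  if (is.numeric(x) && kind == "categorical") fill <- as.numeric(fill)
  x[miss] <- fill
  list(values = x, imputed = fill, n_imputed = sum(miss))
}

#' Yeo-Johnson power transformation
#'
#' Applies the Yeo-Johnson transform at a given `lambda`, or (default)
#' chooses `lambda` by maximising the profile log-likelihood of the
#' transformed sample under a normal model.
#'
#' @param x Numeric vector.
#' @param lambda Power parameter; `NULL` to estimate by maximum likelihood
#'   over `[-5, 5]`.
#' @return A list with `values` and `lambda`.
#' @examples
#' yeo_johnson(rlnorm(100))$lambda  # near 0 for lognormal input
#' @export
yeo_johnson <- function(x, lambda = NULL) {
  if (is.null(lambda)) lambda <- yj_lambda(x)
  list(values = yj_apply(x, lambda), lambda = lambda)
}

yj_apply <- function(x, lambda) {
  out <- x
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out
}

# Profile log-likelihood for the Yeo-Johnson parameter under normality.
yj_loglik <- function(lambda, x) {
  y <- yj_apply(x, lambda)
  n <- length(x)
  s2 <- mean((y - mean(y))^2)
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

yj_lambda <- function(x, interval = c(-5, 5)) {
  x <- x[!is.na(x)]
  optimize(yj_loglik, interval, x = x, maximum = TRUE, tol = 1e-8)$maximum
}

#' Z-score standardization with stored parameters
#'
#' @param x Numeric vector.
#' @param center,scale Mean and SD to use; learned from `x` when `NULL`.
#' @return A list with `values`, `center`, `scale`.
#' @export
zscore <- function(x, center = NULL, scale = NULL) {
  center <- center %||% mean(x, na.rm = TRUE)
  scale <- scale %||% sd(x, na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0) {
    abort("cannot z-score a constant column (SD = 0)")
  }
  list(values = (x - center) / scale, center = center, scale = scale)
}

#' Learn a per-variable transformation recipe
#'
#' For every named continuous variable, learns in order: 3xIQR outlier
#' fences, median imputation, the maximum-likelihood Yeo-Johnson power, and
#' the post-transform mean/SD for z-scoring. Applying the recipe to its own
#' training data yields columns with mean 0 and SD 1.
#'
#' @param data A data frame (one row per nurse).
#' @param vars Character vector of continuous columns to cover.
#' @return An object of class `transform_recipe`; a named list of
#'   per-variable parameter sets.
#' @examples
#' cohort <- generate_cohort(50, seed = 1)
#' rec <- learn_recipe(cohort, c("psqi", "phq9"))
#' round(colMeans(apply_recipe(rec, cohort)[c("psqi", "phq9")]), 10)
#' @export
learn_recipe <- function(data, vars) {
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("variables absent from data: ",
                 paste(missing_vars, collapse = ", ")))
  }
  steps <- lapply(vars, function(v) {
    f <- fence_outliers(data[[v]])
    im <- impute_missing(f$values, "continuous")
    yj <- yeo_johnson(im$values)
    z <- zscore(yj$values)
    list(fences = f$fences, impute = im$imputed, n_fenced = sum(f$flagged),
         n_imputed = im$n_imputed, lambda = yj$lambda,
         center = z$center, scale = z$scale)
  })
  structure(setNames(steps, vars), class = "transform_recipe")
}

#' Apply a learned recipe to (possibly new) data
#'
#' Raw values are winsorized to the stored fences, imputed with the stored
#' value, Yeo-Johnson transformed at the stored lambda, and z-scored with
#' the stored mean/SD. Columns not covered by the recipe pass through
#' unchanged.
#'
#' @param recipe A [learn_recipe()] object.
#' @param data Data frame with the recipe's variables.
#' @return A tibble with transformed columns.
#' @export
apply_recipe <- function(recipe, data) {
  out <- tibble::as_tibble(data)
  for (v in names(recipe)) {
    if (!v %in% names(out)) abort(paste0("recipe variable '", v,
                                         "' absent from data"))
    p <- recipe[[v]]
    x <- clip(out[[v]], p$fences[1], p$fences[2])
    x[is.na(x)] <- p$impute
    x <- yj_apply(x, p$lambda)
    out[[v]] <- (x - p$center) / p$scale
  }
  out
}

#' @export
print.transform_recipe <- function(x, ...) {
  cat("<transform_recipe> for", length(x), "variables\n")
  for (v in names(x)) {
    cat(sprintf("  %s: lambda %.3f, center %.3f, scale %.3f\n",
                v, x[[v]]$lambda, x[[v]]$center, x[[v]]$scale))
  }
  invisible(x)
}

#' Write / read a recipe as JSON
#'
#' @param recipe A `transform_recipe`.
#' @param path File path.
#' @return `read_recipe` returns a `transform_recipe`.
#' @export
write_recipe <- function(recipe, path) {
  jsonlite::write_json(unclass(recipe), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(raw, function(p) {
    p$fences <- as.numeric(p$fences)
    p
  }), class = "transform_recipe")
}
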