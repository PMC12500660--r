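#' Declare the rank-correlation structure of a synthetic cohort
#'
#' Pairwise Spearman targets for the Gaussian copula. Cells not listed
#' default to zero; the implied latent correlation matrix is repaired to the
#' nearest positive semi-definite correlation matrix when needed, and any
#' repaired cells are kept in the object's provenance.
#'
#' @param pairs A data frame with columns `var1`, `var2`, `rho`
#'   (target Spearman correlations in `[-1, 1]`).
#' @return An object of class `dependence_spec`.
#' @examples
#' dependence_spec(tibble::tribble(
#'   ~var1, ~var2, ~rho,
#'   "psqi", "phq9", 0.560))
#' @export
dependence_spec <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("var1", "var2", "rho") %in% names(pairs)))
  bad <- abs(pairs$rho) > 1
  if (any(bad)) {
    abort(paste0("Spearman targets outside [-1, 1] for pairs: ",
                 paste(pairs$var1[bad], pairs$var2[bad],
                       sep = "-", collapse = ", ")))
  }
  structure(list(pairs = pairs), class = "dependence_spec")
}

# Exact Spearman -> latent Pearson conversion for the bivariate normal
# copula: r = 2 sin(pi * rho / 6).
spearman_to_latent <- function(rho) 2 * sin(pi * rho / 6)

# Assemble the latent correlation matrix over `vars`, filling unspecified
# cells with 0, then repair to the nearest PSD correlation matrix if needed.
latent_correlation <- function(dependence, vars) {
  d <- length(vars)
  R <- diag(d)
  dimnames(R) <- list(vars, vars)
  pr <- dependence$pairs
  for (k in seq_len(nrow(pr))) {
    i <- match(pr$var1[k], vars)
    j <- match(pr$var2[k], vars)
    if (is.na(i) || is.na(j)) next
    R[i, j] <- R[j, i] <- spearman_to_latent(pr$rho[k])
  }
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    fixed <- try(
      as.matrix(Matrix::nearPD(R, corr = TRUE, keepDiag = TRUE)$mat),
      silent = TRUE
    )
    if (inherits(fixed, "try-error")) {
      off <- which(abs(R) > 0 & row(R) < col(R), arr.ind = TRUE)
      abort(paste0(
        "dependence matrix is not repairable to PSD; check pairs: ",
        paste(vars[off[, 1]], vars[off[, 2]], sep = "-", collapse = ", ")
      ))
    }
    dimnames(fixed) <- dimnames(R)
    repaired <- TRUE
    R_orig <- R
    R <- fixed
    attr(R, "original") <- R_orig
  }
  attr(R, "repaired") <- repaired
  R
}

#' Generate a synthetic nurse cohort (descriptive mode)
#'
#' Draws `n` nurses from a Gaussian copula: a latent multivariate normal
#' vector with the declared rank-correlation structure is mapped through the
#' normal CDF and each uniform coordinate through the quantile function of
#' its declared marginal. Discrete instrument scores are rounded onto their
#' support, so realized medians/IQRs match the published targets and the
#' realized tie-corrected Spearman correlations match the (repaired)
#' targets up to discretization.
#'
#' @param n Cohort size (`n >= 10`).
#' @param seed Integer RNG seed; identical `(configuration, seed)` give an
#'   identical cohort.
#' @param marginals List of [beta_marginal()] / [bernoulli_marginal()] /
#'   [uniform_marginal()] specs; defaults to [default_marginals()].
#' @param dependence A [dependence_spec()]; defaults to
#'   [default_dependence()].
#'
#' @return A tibble with one row per nurse and one column per marginal,
#'   carrying the full generating configuration in
#'   `attr(, "provenance")`.
#' @examples
#' cohort <- generate_cohort(288, seed = 1)
#' dplyr::summarise(cohort, median(psqi), median(phq9))
#' @export
generate_cohort <- function(n, seed, marginals = default_marginals(),
                            dependence = default_dependence()) {
  stopifnot(n >= 10)
  vars <- vapply(marginals, `[[`, character(1), "name")
  if (anyDuplicated(vars)) abort("duplicate marginal names")
  R <- latent_correlation(dependence, vars)
  L <- chol(R)
  x <- with_seed(seed, {
    z <- matrix(rnorm(n * length(vars)), nrow = n) %*% L
    u <- pnorm(z)
    cols <- lapply(seq_along(marginals), function(j) {
      marginal_quantile(marginals[[j]], u[, j])
    })
    tibble::as_tibble(setNames(cols, vars))
  })
  x <- dplyr::bind_cols(tibble::tibble(nurse_id = seq_len(n)), x)
  attr(x, "provenance") <- list(
    mode = "descriptive", n = n, seed = seed,
    marginals = marginals, dependence = dependence,
    latent_correlation = R,
    psd_repaired = isTRUE(attr(R, "repaired"))
  )
  class(x) <- c("shift_cohort", class(x))
  x
}

#' @export
print.shift_cohort <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<shift_cohort> %d nurses (%s mode, seed %s)\n",
              nrow(x), prov$mode %||% "?", format(prov$seed %||% NA)))
  NextMethod()
}
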