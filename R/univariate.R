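#' Tie-corrected Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations with asymptotic p-values
#' (t approximation), mirroring the published correlation heatmap among
#' instrument scores and work-demand indicators.
#'
#' @param data A data frame.
#' @param vars Columns to correlate; defaults to all numeric columns.
#' @return A tibble in long form with columns `var1`, `var2`, `rho`, `p`,
#'   `n`; the square matrix is available via [corr_matrix()].
#' @examples
#' cohort <- generate_cohort(100, seed = 1)
#' spearman_matrix(cohort, c("psqi", "phq9", "lv"))
#' @export
spearman_matrix <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, "nurse_id")
  }
  combos <- tidyr::expand_grid(var1 = vars, var2 = vars)
  purrr::pmap_dfr(combos, function(var1, var2) {
    x <- data[[var1]]; y <- data[[var2]]
    ok <- !is.na(x) & !is.na(y)
    if (var1 == var2) {
      return(tibble::tibble(var1 = var1, var2 = var2, rho = 1, p = 0,
                            n = sum(ok)))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(var1 = var1, var2 = var2,
                   rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
}

#' Reshape a long Spearman table into a square matrix
#'
#' @param long Output of [spearman_matrix()].
#' @param value Which column to spread (`"rho"` or `"p"`).
#' @return A named square matrix.
#' @export
corr_matrix <- function(long, value = "rho") {
  wide <- tidyr::pivot_wider(long[c("var1", "var2", value)],
                             names_from = "var2",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$var1
  m
}

#' Rank-based group comparison
#'
#' Two groups are compared with the two-sided tie-corrected Mann-Whitney U
#' test; three or more with the Kruskal-Wallis H test — the convention used
#' for comparing instrument scores across sociodemographic strata.
#'
#' @param values Numeric outcome vector.
#' @param groups Grouping vector (factor or character).
#' @return A one-row tibble with `test`, `statistic`, `p`, `n_groups`.
#' @examples
#' group_compare(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
group_compare <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2) abort("need at least two groups")
  if (k == 2) {
    ht <- suppressWarnings(
      wilcox.test(values ~ groups, exact = FALSE, correct = TRUE)
    )
    tibble::tibble(test = "mann-whitney", statistic = unname(ht$statistic),
                   p = ht$p.value, n_groups = 2L)
  } else {
    ht <- kruskal.test(values, groups)
    tibble::tibble(test = "kruskal-wallis",
                   statistic = unname(ht$statistic),
                   p = ht$p.value, n_groups = k)
  }
}

#' Univariate screen of a cohort
#'
#' Runs [group_compare()] for each instrument score across each categorical
#' characteristic and [spearman_matrix()] over the continuous variables.
#'
#' @param cohort A cohort tibble.
#' @param scores Score columns (default PSQI, PHQ-9, FR, LV).
#' @param strata Categorical columns (default gender).
#' @return A list with `group_tests` (tibble) and `correlations` (long
#'   tibble).
#' @export
univariate_screen <- function(cohort,
                              scores = c("psqi", "phq9", "fr", "lv"),
                              strata = "gender") {
  strata <- intersect(strata, names(cohort))
  grid <- tidyr::expand_grid(score = scores, stratum = strata)
  group_tests <- purrr::pmap_dfr(grid, function(score, stratum) {
    dplyr::bind_cols(tibble::tibble(score = score, stratum = stratum),
                     group_compare(cohort[[score]], cohort[[stratum]]))
  })
  numeric_vars <- setdiff(
    names(cohort)[vapply(cohort, is.numeric, logical(1))],
    c("nurse_id", strata)
  )
  list(group_tests = group_tests,
       correlations = spearman_matrix(cohort, numeric_vars))
}
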