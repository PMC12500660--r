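#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted moderated GLM
#'
#' @param x A `shift_glm`.
#' @param ... Unused.
#' @return The coefficient table as a tibble (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `conf_low`, `conf_high`).
#' @method tidy shift_glm
#' @export
tidy.shift_glm <- function(x, ...) x$coefficients

#' @rdname tidy.shift_glm
#' @method glance shift_glm
#' @export
glance.shift_glm <- function(x, ...) {
  tibble::tibble(outcome = x$spec$outcome,
                 moderator = x$spec$moderator %||% NA_character_,
                 log_lik = x$log_lik, aic = x$aic, bic = x$bic,
                 pseudo_r2 = x$pseudo_r2, n = x$n, k = x$k,
                 max_vif = max(x$vif))
}

#' Tidy a breakpoint fit
#'
#' @param x A `breakpoint_fit`.
#' @param ... Unused.
#' @return One row per segment with slope, SE and p-value.
#' @method tidy breakpoint_fit
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    segment = c("below", "above"),
    slope = c(x$slope_below, x$slope_above),
    std_error = c(x$slope_below_se, x$slope_above_se),
    p_value = c(x$p_below, x$p_above)
  )
}

#' @rdname tidy.breakpoint_fit
#' @method glance breakpoint_fit
#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(breakpoint = x$breakpoint, sse = x$sse,
                 hinge_p = x$p_hinge)
}

#' Tidy a GAM nonlinearity screen
#'
#' @param x A `gam_screen`.
#' @param ... Unused.
#' @return The per-smooth-term EDoF table.
#' @method tidy gam_screen
#' @export
tidy.gam_screen <- function(x, ...) x$terms

#' @rdname tidy.gam_screen
#' @method glance gam_screen
#' @export
glance.gam_screen <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, pseudo_r2 = x$pseudo_r2,
                 gcv = x$gcv, total_edof = x$total_edof)
}
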