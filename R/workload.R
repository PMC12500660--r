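#' Classify shift events as day, evening or night work
#'
#' A shift event counts as an evening shift when it contains at least four
#' consecutive worked hours inside 18:00-24:00, and as a night shift when
#' it contains at least four consecutive hours inside 00:00-08:00; an
#' event qualifying as both (the long 18:00-08:00 night with nap break) is
#' classified as a night shift. Everything else is day work. Net hours are
#' gross duration minus nap hours.
#'
#' @param events Tibble with columns `start`, `end` (POSIXct) and
#'   optionally `nap_hours`.
#' @return The events tibble with added `class` (`"DAY"`, `"EVENING"`,
#'   `"NIGHT"`), `net_hours`, `evening_overlap_hours`,
#'   `night_overlap_hours`.
#' @examples
#' ev <- tibble::tibble(
#'   start = as.POSIXct("2026-03-02 18:00", tz = "UTC"),
#'   end = as.POSIXct("2026-03-03 08:00", tz = "UTC"), nap_hours = 3)
#' classify_shift(ev)$class
#' @export
classify_shift <- function(events) {
  events <- tibble::as_tibble(events)
  if (!"nap_hours" %in% names(events)) events$nap_hours <- 0
  gross <- as.numeric(difftime(events$end, events$start, units = "hours"))
  if (any(gross <= 0)) abort("event end must be after start")
  if (any(gross > 24)) abort("events longer than 24 h are malformed")
  if (any(events$nap_hours >= gross)) {
    abort("nap hours must be shorter than the event")
  }
  ev_overlap <- window_overlap_hours(events$start, events$end, 18, 24)
  ni_overlap <- window_overlap_hours(events$start, events$end, 0, 8)
  cls <- dplyr::case_when(
    ni_overlap >= 4 ~ "NIGHT",
    ev_overlap >= 4 ~ "EVENING",
    TRUE ~ "DAY"
  )
  dplyr::mutate(events, class = cls, net_hours = gross - events$nap_hours,
                evening_overlap_hours = ev_overlap,
                night_overlap_hours = ni_overlap)
}

# Hours of a (start, end] interval falling inside the daily clock window
# [from, to) (hours), accumulated at minute resolution over the calendar
# days the event touches.
window_overlap_hours <- function(start, end, from, to) {
  vapply(seq_along(start), function(i) {
    day0 <- as.POSIXct(format(start[i], "%Y-%m-%d 00:00:00"), tz = "UTC")
    total <- 0
    for (d in 0:1) {
      w1 <- day0 + (d * 24 + from) * 3600
      w2 <- day0 + (d * 24 + to) * 3600
      lo <- max(as.numeric(start[i]), as.numeric(w1))
      hi <- min(as.numeric(end[i]), as.numeric(w2))
      total <- total + max(0, hi - lo)
    }
    round(total / 60) / 60  # minute resolution
  }, numeric(1))
}

#' Summarize 4-week work-quantity and work-intensity demands
#'
#' Computes, per nurse, the work-quantity indicators (evening, night and
#' total shift counts; shift, day and total work hours) and — when a unit
#' census is supplied — the work-intensity indicators: workload (expected
#' divided by actual nurse-to-patient ratio, hours-weighted across
#' periods) and workload exposure (workload times the corresponding work
#' hours), separately for day and shift work. Nurses whose units lack
#' census rows get `NA` intensity fields and are listed in
#' `attr(, "intensity_excluded")`.
#'
#' @param events Shift-event tibble (`nurse_id`, `start`, `end`,
#'   `nap_hours`, `unit_id`).
#' @param window_start First day of the 28-day window; events must start
#'   inside the window.
#' @param census Optional census tibble (`unit_id`, `period`,
#'   `active_nurses`, `assigned_patients`, `cmi`) with periods labelled
#'   `"W<week>-<day|shift>"`.
#' @param curve An [npr_curve] for the expected nurse-to-patient ratio;
#'   defaults to the published severity-anchored fit.
#' @return A tibble keyed by `nurse_id` with one column per demand
#'   indicator.
#' @export
summarize_demand <- function(events, window_start, census = NULL,
                             curve = default_npr_curve()) {
  if (nrow(events) == 0) {
    return(tibble::tibble(nurse_id = integer(), evening_count = numeric(),
                          night_count = numeric(),
                          total_shift_count = numeric(),
                          shift_work_hours = numeric(),
                          day_work_hours = numeric(),
                          total_work_hours = numeric()))
  }
  t0 <- as.POSIXct(paste(as.Date(window_start), "00:00:00"), tz = "UTC")
  off_days <- as.numeric(difftime(events$start, t0, units = "days"))
  outside <- off_days < 0 | off_days >= 28
  if (any(outside)) {
    abort(paste0("events starting outside the 28-day window for nurses: ",
                 paste(unique(events$nurse_id[outside]), collapse = ", ")))
  }
  ev <- classify_shift(events)
  ev$week <- floor(off_days / 7) + 1
  ev$worktype <- ifelse(ev$class == "DAY", "day", "shift")
  ev$period <- paste0("W", ev$week, "-", ev$worktype)

  quantity <- ev |>
    dplyr::group_by(.data$nurse_id) |>
    dplyr::summarise(
      evening_count = sum(.data$class == "EVENING"),
      night_count = sum(.data$class == "NIGHT"),
      total_shift_count = .data$evening_count + .data$night_count,
      shift_work_hours = sum(.data$net_hours[.data$class != "DAY"]),
      day_work_hours = sum(.data$net_hours[.data$class == "DAY"]),
      total_work_hours = .data$shift_work_hours + .data$day_work_hours,
      .groups = "drop"
    )
  if (is.null(census)) return(quantity)

  census <- dplyr::mutate(
    census,
    severity = normalize_cmi(.data$cmi),
    expected_npr = expected_npr(curve, .data$severity),
    actual_npr = .data$active_nurses / .data$assigned_patients,
    workload = .data$expected_npr / .data$actual_npr
  )
  joined <- dplyr::left_join(ev, census[c("unit_id", "period", "workload")],
                             by = c("unit_id", "period"))
  intensity <- joined |>
    dplyr::group_by(.data$nurse_id) |>
    dplyr::summarise(
      day_workload = weighted_workload(.data$workload, .data$net_hours,
                                       .data$worktype == "day"),
      shift_workload = weighted_workload(.data$workload, .data$net_hours,
                                         .data$worktype == "shift"),
      .groups = "drop"
    )
  out <- dplyr::left_join(quantity, intensity, by = "nurse_id") |>
    dplyr::mutate(
      day_workload_exposure = .data$day_workload * .data$day_work_hours,
      shift_workload_exposure = .data$shift_workload *
        .data$shift_work_hours
    )
  miss <- joined$nurse_id[is.na(joined$workload)]
  attr(out, "intensity_excluded") <- sort(unique(miss))
  out
}

# Hours-weighted mean workload over the selected events; NA when any
# selected event lacks a census match, 0-hour case yields NA.
weighted_workload <- function(workload, hours, sel) {
  w <- workload[sel]; h <- hours[sel]
  if (!length(h) || sum(h) == 0) return(NA_real_)
  if (anyNA(w)) return(NA_real_)
  sum(w * h) / sum(h)
}

#' Fit the expected nurse-to-patient-ratio curve
#'
#' Least squares on the original (untransformed) scale for
#' `NPR = a * exp(b * severity)`: for fixed `b` the optimal `a` has the
#' closed form `sum(y * exp(b s)) / sum(exp(2 b s))`, and `b` is found by
#' profiling. The original-scale fit weights the severe-care anchor more
#' heavily than a log-linear regression would.
#'
#' @param anchors Data frame with columns `severity` and `npr`
#'   (at least two distinct severities; `npr > 0`).
#' @return An object of class `npr_curve` with elements `a`, `b`, `sse`.
#' @examples
#' fit_npr_curve(tibble::tibble(severity = 0:2, npr = c(1/8, 1/3, 1)))
#' @export
fit_npr_curve <- function(anchors) {
  stopifnot(all(c("severity", "npr") %in% names(anchors)))
  if (any(anchors$npr <= 0)) abort("expected NPR anchors must be positive")
  if (length(unique(anchors$severity)) < 2) {
    abort("need at least two distinct severities")
  }
  s <- anchors$severity; y <- anchors$npr
  sse_at <- function(b) {
    e <- exp(b * s)
    a <- sum(y * e) / sum(e^2)
    sum((y - a * e)^2)
  }
  opt <- optimize(sse_at, c(-5, 5), tol = 1e-12)
  b <- opt$minimum
  a <- sum(y * exp(b * s)) / sum(exp(2 * b * s))
  structure(list(a = a, b = b, sse = opt$objective,
                 anchors = tibble::as_tibble(anchors)),
            class = "npr_curve")
}

#' The published severity-anchored expected-NPR curve
#'
#' Fit to the anchors: mild (severity 0) 1:8, moderate (1) 1:3, severe
#' (2) 1:1.
#' @return An `npr_curve` (a near 0.1154, b near 1.0791).
#' @export
default_npr_curve <- function() {
  fit_npr_curve(tibble::tibble(severity = c(0, 1, 2),
                               npr = c(1 / 8, 1 / 3, 1)))
}

#' Expected nurse-to-patient ratio at a given severity
#'
#' @param curve An `npr_curve`.
#' @param severity Severity score(s) in `[0, 2]`.
#' @return `a * exp(b * severity)`.
#' @export
expected_npr <- function(curve, severity) {
  stopifnot(inherits(curve, "npr_curve"))
  if (any(severity < 0 | severity > 2, na.rm = TRUE)) {
    abort("severity must lie in [0, 2]")
  }
  curve$a * exp(curve$b * severity)
}

#' Normalize case-mix-index values to the severity scale
#'
#' Linear min-max map of unit CMI values onto `[0, 2]`; a constant input
#' maps to 1 (mid-severity) by convention. An optional fixed reference
#' range supports cross-hospital comparability.
#'
#' @param cmi Numeric CMI values.
#' @param range Optional fixed `c(lo, hi)` reference range; values are
#'   clipped into it.
#' @return Severity scores in `[0, 2]`.
#' @examples
#' normalize_cmi(c(0.5, 1, 1.5))
#' @export
normalize_cmi <- function(cmi, range = NULL) {
  if (!length(cmi)) abort("need at least one CMI value")
  if (is.null(range)) {
    lo <- min(cmi, na.rm = TRUE); hi <- max(cmi, na.rm = TRUE)
    if (hi == lo) return(rep(1, length(cmi)))
  } else {
    lo <- range[1]; hi <- range[2]
    cmi <- clip(cmi, lo, hi)
  }
  2 * (cmi - lo) / (hi - lo)
}

#' @export
print.npr_curve <- function(x, ...) {
  cat(sprintf("<npr_curve> expected NPR = %.4f * exp(%.4f * severity)\n",
              x$a, x$b))
  invisible(x)
}
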