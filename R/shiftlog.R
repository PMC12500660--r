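#' Describe a weekly rotating-shift mix
#'
#' Default mirrors the predominant day-night (DN) rotation: one long night
#' shift (18:00-08:00, three-hour nap break, 11 net working hours) per
#' week plus four 8-hour day shifts. An evening-containing (APN-style) mix
#' is obtained by raising `weekly_evenings`.
#'
#' @param weekly_nights,weekly_evenings,weekly_days Shifts per week; their
#'   sum must be at most 7.
#' @param night_nap Nap hours inside the long night shift.
#' @return An object of class `shift_schedule`.
#' @export
shift_schedule <- function(weekly_nights = 1, weekly_evenings = 0,
                           weekly_days = 4, night_nap = 3) {
  if (weekly_nights + weekly_evenings + weekly_days > 7) {
    abort("more shifts per week than days: events would overlap")
  }
  structure(list(weekly_nights = weekly_nights,
                 weekly_evenings = weekly_evenings,
                 weekly_days = weekly_days, night_nap = night_nap,
                 night = c(18, 32), evening = c(18, 24), day = c(8, 16)),
            class = "shift_schedule")
}

#' Generate a 4-week shift-event log and a unit census table
#'
#' Each nurse is assigned to a unit and scheduled over a 28-day window
#' according to the weekly mix: long night shifts (18:00 to 08:00 the next
#' day with the configured nap), 6-hour evening shifts (18:00-24:00) and
#' 8-hour day shifts (08:00-16:00) on distinct weekdays. The census table
#' provides, for every (unit, period) referenced by the events, the active
#' primary nurse count, assigned patients and the unit case-mix index
#' (CMI); periods are labelled `"W<week>-<day|shift>"`.
#'
#' @param n Number of nurses.
#' @param seed Integer RNG seed.
#' @param schedule A [shift_schedule()].
#' @param window_start First day of the 28-day window (a `Date`).
#' @param n_units Number of hospital units.
#' @return A list with `events` (nurse_id, start, end, nap_hours,
#'   unit_id), `census` (unit_id, period, active_nurses,
#'   assigned_patients, cmi) and `window_start`.
#' @examples
#' log <- generate_shift_log(5, seed = 1)
#' summarize_demand(log$events, log$window_start, log$census)
#' @export
generate_shift_log <- function(n, seed, schedule = shift_schedule(),
                               window_start = as.Date("2026-03-02"),
                               n_units = 8) {
  t0 <- as.POSIXct(paste(window_start, "00:00:00"), tz = "UTC")
  with_seed(seed, {
    unit_of <- sample(seq_len(n_units), n, replace = TRUE)
    events <- purrr::map_dfr(seq_len(n), function(i) {
      purrr::map_dfr(0:3, function(wk) {
        k <- schedule$weekly_nights + schedule$weekly_evenings +
          schedule$weekly_days
        days <- sample(0:6, k)
        kinds <- rep(c("night", "evening", "day"),
                     c(schedule$weekly_nights, schedule$weekly_evenings,
                       schedule$weekly_days))
        win <- lapply(kinds, function(kd) schedule[[kd]])
        tibble::tibble(
          nurse_id = i,
          start = t0 + ((wk * 7 + days) * 24 +
                          vapply(win, `[`, numeric(1), 1)) * 3600,
          end = t0 + ((wk * 7 + days) * 24 +
                        vapply(win, `[`, numeric(1), 2)) * 3600,
          nap_hours = ifelse(kinds == "night", schedule$night_nap, 0),
          unit_id = unit_of[i]
        )
      })
    })
    cmi <- runif(n_units, 0.8, 1.6)
    severity <- normalize_cmi(cmi)
    exp_npr <- expected_npr(default_npr_curve(), severity)
    census <- tidyr::expand_grid(unit_id = seq_len(n_units), week = 1:4,
                                 worktype = c("day", "shift"))
    # Staffing tracks acuity (sicker units assign fewer patients per
    # nurse); the understaffing factor is the realized workload ratio,
    # heavier off-hours than during day work.
    census <- dplyr::mutate(
      census,
      period = paste0("W", .data$week, "-", .data$worktype),
      active_nurses = ifelse(.data$worktype == "day",
                             sample(4:6, dplyr::n(), replace = TRUE),
                             sample(1:2, dplyr::n(), replace = TRUE)),
      understaffing = ifelse(.data$worktype == "day",
                             runif(dplyr::n(), 0.8, 1.6),
                             runif(dplyr::n(), 2.5, 4.5)),
      assigned_patients = pmax(1, round(
        .data$active_nurses * .data$understaffing /
          exp_npr[.data$unit_id])),
      cmi = cmi[.data$unit_id]
    )
    census <- dplyr::select(census, "unit_id", "period", "active_nurses",
                            "assigned_patients", "cmi")
    list(events = events, census = census, window_start = window_start)
  })
}
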