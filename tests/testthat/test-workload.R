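ev_row <- function(start, end, nap = 0, nurse = 1, unit = 1) {
  tibble::tibble(nurse_id = nurse,
                 start = as.POSIXct(start, tz = "UTC"),
                 end = as.POSIXct(end, tz = "UTC"),
                 nap_hours = nap, unit_id = unit)
}

test_that("shift classification follows the 4-consecutive-hour windows", {
  long_night <- classify_shift(ev_row("2026-03-02 18:00", "2026-03-03 08:00",
                                      nap = 3))
  expect_equal(long_night$class, "NIGHT")
  expect_equal(long_night$net_hours, 11)

  short <- classify_shift(ev_row("2026-03-02 20:00", "2026-03-02 22:00"))
  expect_equal(short$class, "DAY")

  evening <- classify_shift(ev_row("2026-03-02 19:00", "2026-03-02 23:30"))
  expect_equal(evening$class, "EVENING")
  expect_equal(evening$net_hours, 4.5)

  # overnight with >= 4 h in both windows counts as night (precedence)
  both <- classify_shift(ev_row("2026-03-02 19:30", "2026-03-03 05:00"))
  expect_equal(both$class, "NIGHT")
})

test_that("window overlaps agree with a minute-resolution sweep", {
  cases <- ev_row(
    c("2026-03-02 19:00", "2026-03-02 16:10", "2026-03-02 23:40",
      "2026-03-02 06:30", "2026-03-02 18:00"),
    c("2026-03-02 23:30", "2026-03-03 00:20", "2026-03-03 07:55",
      "2026-03-02 18:45", "2026-03-03 08:00"))
  got <- classify_shift(cases)
  for (i in seq_len(nrow(cases))) {
    expect_equal(got$evening_overlap_hours[i],
                 oracle_window_hours(cases$start[i], cases$end[i], 18, 24),
                 tolerance = 1e-8)
    expect_equal(got$night_overlap_hours[i],
                 oracle_window_hours(cases$start[i], cases$end[i], 0, 8),
                 tolerance = 1e-8)
  }
})

test_that("malformed events are rejected", {
  expect_error(classify_shift(ev_row("2026-03-03 08:00", "2026-03-02 18:00")),
               "after start")
  expect_error(classify_shift(ev_row("2026-03-02 08:00", "2026-03-03 10:00")),
               "24")
  expect_error(classify_shift(ev_row("2026-03-02 20:00", "2026-03-02 22:00",
                                     nap = 3)), "nap")
})

test_that("the DN roster yields 4 nights and 44 shift work hours", {
  log <- generate_shift_log(6, seed = 1)
  dd <- summarize_demand(log$events, log$window_start, log$census)
  expect_true(all(dd$night_count == 4))
  expect_true(all(dd$evening_count == 0))
  expect_true(all(dd$shift_work_hours == 44))
  expect_true(all(dd$total_shift_count == 4))
  expect_true(all(dd$total_work_hours ==
                    dd$day_work_hours + dd$shift_work_hours))
})

test_that("an APN-style roster matches a hand tally", {
  log <- generate_shift_log(4, seed = 2,
                            schedule = shift_schedule(weekly_nights = 1,
                                                      weekly_evenings = 2,
                                                      weekly_days = 3))
  dd <- summarize_demand(log$events, log$window_start)
  expect_true(all(dd$night_count == 4))      # 1 night x 4 weeks
  expect_true(all(dd$evening_count == 8))    # 2 evenings x 4 weeks
  expect_true(all(dd$shift_work_hours == 4 * 11 + 8 * 6))
  expect_true(all(dd$day_work_hours == 12 * 8))
})

test_that("shift hours equal the summed net hours of shift events", {
  log <- generate_shift_log(5, seed = 3)
  cls <- classify_shift(log$events)
  manual <- tapply(cls$net_hours[cls$class != "DAY"],
                   cls$nurse_id[cls$class != "DAY"], sum)
  dd <- summarize_demand(log$events, log$window_start)
  expect_equal(dd$shift_work_hours,
               as.numeric(manual[as.character(dd$nurse_id)]))
})

test_that("empty logs and out-of-window events are handled", {
  empty <- summarize_demand(tibble::tibble(), as.Date("2026-03-02"))
  expect_equal(nrow(empty), 0)
  expect_error(
    summarize_demand(ev_row("2026-05-01 08:00", "2026-05-01 16:00"),
                     as.Date("2026-03-02")),
    "outside")
})

test_that("missing census coverage yields NA intensity, not an error", {
  log <- generate_shift_log(8, seed = 4)
  dropped_unit <- log$events$unit_id[1]
  census <- log$census[log$census$unit_id != dropped_unit, ]
  dd <- summarize_demand(log$events, log$window_start, census)
  affected <- unique(log$events$nurse_id[log$events$unit_id == dropped_unit])
  expect_true(all(is.na(dd$shift_workload[dd$nurse_id %in% affected])))
  expect_setequal(attr(dd, "intensity_excluded"), affected)
  untouched <- setdiff(dd$nurse_id, affected)
  if (length(untouched)) {
    expect_true(all(!is.na(dd$shift_workload[dd$nurse_id %in% untouched])))
  }
})

test_that("the severity-anchored NPR fit reproduces the published curve", {
  crv <- default_npr_curve()
  expect_lt(abs(crv$a - 0.1154), 0.001)
  expect_lt(abs(crv$b - 1.0791), 0.001)
  expect_equal(expected_npr(crv, 0), crv$a)
  expect_equal(expected_npr(crv, 1), 0.3396, tolerance = 1e-3)
  expect_equal(expected_npr(crv, 2), 0.9990, tolerance = 1e-3)
})

test_that("exact exponential anchors are recovered with zero residual", {
  s <- c(0, 0.5, 1, 1.5, 2)
  crv <- fit_npr_curve(tibble::tibble(severity = s,
                                      npr = 0.2 * exp(0.5 * s)))
  expect_equal(crv$a, 0.2, tolerance = 1e-6)
  expect_equal(crv$b, 0.5, tolerance = 1e-6)
  expect_lt(crv$sse, 1e-12)
})

test_that("profiled fit beats the log-linear fit on the original scale", {
  anchors <- tibble::tibble(severity = 0:2, npr = c(1 / 8, 1 / 3, 1))
  crv <- fit_npr_curve(anchors)
  ll <- lm(log(npr) ~ severity, data = anchors)
  a_ll <- exp(coef(ll)[1]); b_ll <- coef(ll)[2]
  expect_equal(unname(a_ll), 0.1226, tolerance = 1e-3)
  expect_equal(unname(b_ll), 1.0397, tolerance = 1e-3)
  sse_ll <- sum((anchors$npr - a_ll * exp(b_ll * anchors$severity))^2)
  expect_lt(crv$sse, sse_ll)
})

test_that("expected NPR is monotone and validates severity", {
  crv <- default_npr_curve()
  s <- seq(0, 2, by = 0.1)
  expect_true(all(diff(expected_npr(crv, s)) > 0))
  expect_error(expected_npr(crv, 2.5), "0, 2")
  expect_error(fit_npr_curve(tibble::tibble(severity = 0:1,
                                            npr = c(-1, 2))), "positive")
})

test_that("CMI normalization maps onto the 0-2 severity scale", {
  expect_equal(normalize_cmi(c(0.5, 1, 1.5)), c(0, 1, 2))
  expect_equal(normalize_cmi(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(normalize_cmi(c(0.8, 1.0, 1.4)), c(0, 2 / 3, 2))
  expect_equal(normalize_cmi(c(0.5, 1.5), range = c(0.5, 2.5)),
               c(0, 1))
})
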