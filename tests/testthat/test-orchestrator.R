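spec <- default_analyte_specs("PLT")

test_that("event classification implements the dual-record rule", {
  expect_equal(classify_event("ma_alert", "pass"), "alerting")
  expect_equal(classify_event("ma_alert", "pending"), "alerting")
  expect_equal(classify_event("westgard_violation", "violation"), "out_of_control")
  expect_setequal(
    classify_event("ma_alert", "violation"),
    c("alerting", "out_of_control")
  )
  expect_setequal(
    classify_event("lstm_warning", "violation"),
    c("alerting", "out_of_control")
  )
})

test_that("plans gate the tiers: disabled tiers emit no events", {
  sim <- simulate_patient_stream(scenario_spec(
    n_samples = 1500, seed = 55,
    errors = list(error_spec("step_shift", onset = 1000, magnitude = 1.5, duration = 501))
  ))
  qc <- simulate_qc_stream(spec, levels = 2, runs = 6, bias_pct = 0, cv_pct = 2.8, seed = 3)
  plan_off <- list(tier = "high", rules = "1-2s", ma_enabled = FALSE, qc_frequency = "once_daily")
  res <- run_monitoring(sim$stream, qc, spec, plan_off)
  expect_false(any(grepl("^ma_", res$events$kind)))
  expect_null(res$ma)
  expect_null(res$forecasts) # no forecaster supplied
})

test_that("a stationary run yields no rejections and reconciling counts", {
  sim <- simulate_patient_stream(scenario_spec(n_samples = 1200, seed = 77))
  qc <- simulate_qc_stream(spec, levels = 2, runs = 12, bias_pct = 0, cv_pct = 2.8, seed = 9)
  plan <- stratify_plan(tibble::tibble(analyte = "PLT", sigma = 2.55))
  res <- run_monitoring(sim$stream, qc, spec, plan)
  expect_false(any(res$events$kind == "westgard_violation"))
  counts <- event_counts(res$events)
  expect_gte(counts$n_alerting, counts$n_dual)
  expect_gte(counts$n_ooc, counts$n_dual)
  expect_true(!is.unsorted(res$events$t_trigger))
})

test_that("an instrument shift raises MA alerts that Westgard confirms (dual record)", {
  shift_sd <- 1.0
  onset <- 2001L
  sim <- simulate_patient_stream(scenario_spec(
    n_samples = 3000, seed = 91,
    errors = list(error_spec("step_shift", onset = onset, magnitude = shift_sd, duration = 1000L))
  ))
  onset_time <- sim$stream$timestamp[onset]
  # the shift affects the control materials identically from onset onwards
  qc_pre <- simulate_qc_stream(spec,
    levels = 2, runs = 8, bias_pct = 0, cv_pct = 2.8,
    seed = 5, start = as.POSIXct("2024-01-01 06:00:00", tz = "UTC")
  )
  qc_post <- simulate_qc_stream(spec,
    levels = 2, runs = 8,
    bias_pct = 100 * shift_sd * spec$target_sd / spec$target_mean, cv_pct = 2.8,
    seed = 6, start = onset_time + 3600
  )
  plan <- list(
    tier = "low", rules = c("1-3s", "2-2s", "4-1s", "10x"),
    ma_enabled = TRUE, qc_frequency = "every_4h"
  )
  res <- run_monitoring(sim$stream, dplyr::bind_rows(qc_pre, qc_post), spec, plan)
  ev <- res$events
  post <- ev[ev$t_trigger >= onset_time, ]
  expect_true(any(post$kind %in% c("ma_alert", "ma_ooc")))
  expect_true(any(post$kind == "westgard_violation"))
  dual <- post[post$classification == "dual", ]
  expect_gte(nrow(dual), 1)
  expect_true(all(!is.na(dual$t_confirmed)))
  expect_true(all(dual$t_confirmed >= dual$t_trigger))
  counts <- event_counts(ev)
  expect_gte(counts$n_alerting, counts$n_dual)
  expect_gte(counts$n_ooc, counts$n_dual)
})

test_that("lead times are timestamp arithmetic over paired episodes", {
  t0 <- as.POSIXct("2024-01-02 08:00:00", tz = "UTC")
  events <- tibble::tibble(
    kind = c("lstm_warning", "ma_alert", "westgard_violation"),
    classification = c("alerting", "dual", "out_of_control"),
    analyte = "PLT", center_id = "C1",
    t_trigger = c(t0, t0 + 3.2 * 3600, t0 + 3.2 * 3600),
    t_confirmed = c(NA, t0 + 3.2 * 3600, t0 + 3.2 * 3600),
    confirmed_by = c(NA, "1-3s", "1-3s"),
    action = "none", note = NA_character_
  )
  lt <- compute_lead_times(events)
  expect_equal(lt$mean_hours[lt$pair == "lstm_to_ma"], 3.2)
  # confirmation at the same timestamp: zero lead
  expect_equal(lt$mean_hours[lt$pair == "ma_to_westgard"], 0)
  expect_equal(lt$n_unconfirmed, c(0, 0))

  # an upstream warning with no downstream event is excluded but counted
  lonely <- events[1, ]
  lt2 <- compute_lead_times(lonely)
  expect_equal(lt2$n_unconfirmed[lt2$pair == "lstm_to_ma"], 1)
  expect_true(is.na(lt2$mean_hours[lt2$pair == "lstm_to_ma"]))
})

test_that("warnings within one episode horizon collapse to one episode", {
  t0 <- as.POSIXct("2024-01-02 08:00:00", tz = "UTC")
  events <- tibble::tibble(
    kind = c("lstm_warning", "lstm_warning", "ma_alert"),
    classification = c("alerting", "alerting", "alerting"),
    analyte = "PLT", center_id = "C1",
    t_trigger = c(t0, t0 + 3600, t0 + 2 * 3600),
    t_confirmed = as.POSIXct(NA), confirmed_by = NA_character_,
    action = "none", note = NA_character_
  )
  lt <- compute_lead_times(events)
  row <- lt[lt$pair == "lstm_to_ma", ]
  expect_equal(row$n_episodes, 1)
  expect_equal(row$mean_hours, 2)
})
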