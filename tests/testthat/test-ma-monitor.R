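test_that("preprocessing removes flagged samples and gross outliers, counts reconcile", {
  spec <- plt_spec()
  stream <- tibble::tibble(
    timestamp = as.POSIXct("2024-01-01", tz = "UTC") + 1:4 * 60,
    center_id = "C1", analyte = "PLT",
    value = c(250, 255, 320, 248), # 320 is 3.5 SD out (target 250, SD 20 scaled)
    flags = list(character(0), "clot", character(0), character(0)),
    stream = "patient", qc_level = NA_character_
  )
  wide <- analyte_spec("PLT", "10^9/L", 250, 20, tea = 10, tea_mode = "absolute")
  out <- preprocess_stream(stream, wide)
  expect_equal(out$report$n_flag_removed, 1)
  expect_equal(out$report$n_outlier_removed, 1)
  expect_equal(out$report$n_out, 2)
  expect_equal(
    out$report$n_out + out$report$n_flag_removed + out$report$n_outlier_removed,
    out$report$n_in
  )
  expect_equal(out$stream$value, c(250, 248))

  # clean in-range stream passes through unchanged
  clean <- stream[c(1, 4), ]
  out2 <- preprocess_stream(clean, spec)
  expect_equal(out2$stream, clean)
  expect_equal(out2$report$n_flag_removed + out2$report$n_outlier_removed, 0)
})

test_that("window adaptation follows the CV comparison with baseline fallback", {
  expect_equal(adapt_window(3.6, 2.8), 50)
  expect_equal(adapt_window(2.8, 2.8), 150) # <= branch includes equality
  expect_equal(adapt_window(2.0, 2.8), 150)
  expect_equal(adapt_window(NA, NA), 100)
  expect_equal(adapt_window(3.0, NA), 100)
})

test_that("status follows the dynamic limits on constant and stepped streams", {
  spec <- plt_spec()
  cfg <- run_config(ma = list(sd_mode = "population"))

  mon <- ma_monitor(rep(spec$target_mean, 300), spec, cfg)
  ev <- mon$trace$status[!is.na(mon$trace$status)]
  expect_true(all(ev == "in_control"))
  expect_equal(mon$trace$ma[300], spec$target_mean)

  # MA settles at +1.6 SD: alert band (1.5 < 1.6 <= 2.5)
  shifted <- c(
    rep(spec$target_mean, 150),
    rep(spec$target_mean + 1.6 * spec$target_sd, 400)
  )
  mon <- ma_monitor(shifted, spec, cfg)
  expect_equal(mon$trace$status[550], "alert")
  expect_false(any(mon$trace$status == "out_of_control", na.rm = TRUE))

  # MA settles at +2.6 SD: out of control (> 2.5)
  shifted <- c(
    rep(spec$target_mean, 150),
    rep(spec$target_mean + 2.6 * spec$target_sd, 400)
  )
  mon <- ma_monitor(shifted, spec, cfg)
  expect_equal(mon$trace$status[550], "out_of_control")
})

test_that("escalation suspends on three consecutive alerts or one OOC breach", {
  expect_equal(escalation_decision("alert", 3), "suspend_and_investigate")
  expect_equal(escalation_decision("out_of_control", 1), "suspend_and_investigate")
  expect_equal(escalation_decision("alert", 2), "continue")
  expect_equal(escalation_decision("in_control", 0), "continue")
})

test_that("consecutive alert counting resets on return to control", {
  spec <- plt_spec()
  cfg <- run_config(ma = list(sd_mode = "population"))
  # constant stream sitting in the alert band: every evaluation is an alert
  values <- c(
    rep(spec$target_mean + 1.7 * spec$target_sd, 250),
    rep(spec$target_mean, 400)
  )
  tr <- ma_monitor(values, spec, cfg)$trace
  alert_rows <- which(tr$status == "alert")
  expect_gt(length(alert_rows), 3)
  first3 <- alert_rows[1:3]
  expect_equal(tr$consecutive_alerts[first3], 1:3)
  expect_equal(tr$decision[first3], c("continue", "continue", "suspend_and_investigate"))
  expect_equal(tr$consecutive_alerts[which(tr$status == "in_control")][1], 0L)
})

test_that("MA equals the brute-force mean over the adapted window", {
  spec <- plt_spec()
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(120:260, 1)
    values <- rnorm(n, spec$target_mean, spec$target_sd)
    if (rep %% 3 == 0) values[(n - 50):n] <- values[(n - 50):n] + spec$target_sd
    tr <- ma_monitor(values, spec)$trace
    idx <- which(!is.na(tr$ma))
    brute <- vapply(idx, function(i) {
      w <- min(tr$window[i], i)
      mean(values[(i - w + 1):i])
    }, numeric(1))
    expect_lt(max(abs(tr$ma[idx] - brute) / abs(brute)), 1e-12)
  }
})

test_that("stationary alert rate stays under the calibrated bound", {
  # calibrated ceiling: the +/-1.5 SD(MA) alert limit has a ~13% marginal
  # exceedance per evaluation on in-control streams; bound pinned at 200
  # alerts per 1000 evaluated samples (~1.5x the marginal rate)
  spec <- plt_spec()
  rates <- vapply(1:6, function(s) {
    sim <- simulate_patient_stream(scenario_spec(n_samples = 2000, seed = 400 + s))
    acc <- preprocess_stream(sim$stream, spec)$stream
    tr <- ma_monitor(acc, spec)$trace
    ev <- tr$status[!is.na(tr$status)]
    1000 * mean(ev == "alert")
  }, numeric(1))
  expect_lt(mean(rates), 200)

  # population-scale limits essentially never fire in control
  cfg <- run_config(ma = list(sd_mode = "population"))
  sim <- simulate_patient_stream(scenario_spec(n_samples = 3000, seed = 123))
  acc <- preprocess_stream(sim$stream, spec, cfg)$stream
  tr <- ma_monitor(acc, spec, cfg)$trace
  ev <- tr$status[!is.na(tr$status)]
  expect_lt(1000 * mean(ev != "in_control"), 5)
})
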