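test_that("analyte specs validate their invariants and convert TEa both ways", {
  plt <- analyte_spec("PLT", "10^9/L", 250, 7, tea = 10, tea_mode = "absolute")
  expect_equal(tea_units(plt), 10)
  expect_equal(tea_pct(plt), 4)

  hb <- analyte_spec("Hb", "g/L", 150, 1.35, tea = 7, tea_mode = "percent")
  expect_equal(tea_units(hb), 10.5)
  expect_equal(tea_pct(hb), 7)

  expect_error(analyte_spec("X", "", 100, 0, tea = 5), "target_sd")
  expect_error(analyte_spec("X", "", 100, 1, tea = -1), "tea")
  expect_error(analyte_spec("X", "", 100, 1, tea = 5, reference_value = 0), "reference_value")
})

test_that("run_config enforces window ordering and limit ordering", {
  expect_error(run_config(ma = list(min_window = 200L)), "min_window")
  expect_error(run_config(ma = list(k_alert = 3)), "k_alert")
  expect_error(run_config(westgard = list(rules = "2-3s")), "unknown Westgard")
  cfg <- run_config()
  expect_lt(cfg$ma$k_alert, cfg$ma$k_ooc)
  expect_true(cfg$lstm$warn_fraction_of_tea > 0 && cfg$lstm$warn_fraction_of_tea < 1)
})

test_that("run_config round-trips through YAML", {
  cfg <- run_config(
    ma = list(k_alert = 1.2, sd_mode = "population"),
    westgard = list(rules = c("1-3s", "2-2s")),
    lstm = list(seed = 42L, hidden_units = 8L)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$ma$k_alert, 1.2)
  expect_equal(back$ma$sd_mode, "population")
  expect_equal(back$westgard$rules, c("1-3s", "2-2s"))
  expect_equal(back$lstm$seed, 42L)
  expect_equal(back$lstm$hidden_units, 8L)
})

test_that("result streams round-trip through CSV exactly", {
  sim <- simulate_patient_stream(scenario_spec(
    n_samples = 50, seed = 5, flag_rate = 0.2, outlier_rate = 0.05
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(sim$stream, path)
  back <- read_results(path)
  expect_equal(back$value, sim$stream$value)
  expect_equal(back$timestamp, sim$stream$timestamp)
  expect_equal(back$flags, sim$stream$flags)
  expect_equal(back$stream, sim$stream$stream)
})

test_that("read_results maps custom schemas and rejects unknown flag tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time,param,result,flag",
    "2024-01-01T00:00:00,PLT,250.5,HEM",
    "2024-01-01T00:03:00,PLT,249.1,none",
    "2024-01-01T00:06:00,PLT,251.2,"
  ), path)
  schema <- list(
    columns = c(timestamp = "time", analyte = "param", value = "result", flags = "flag"),
    flag_map = c(HEM = "hemolysis", LIP = "lipemia", CLT = "clot")
  )
  out <- read_results(path, schema)
  expect_equal(nrow(out), 3)
  expect_equal(out$flags[[1]], "hemolysis")
  expect_equal(out$flags[[2]], character(0))
  expect_equal(out$flags[[3]], character(0))

  writeLines(c(
    "time,param,result,flag",
    "2024-01-01T00:00:00,PLT,250.5,XYZ"
  ), path)
  expect_error(read_results(path, schema), "unknown flag token")
})

test_that("read_results reports schema and row-level errors precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,analyte", "2024-01-01,PLT"), path)
  expect_error(read_results(path), "missing required column.*value")

  writeLines(c(
    "timestamp,analyte,value",
    "2024-01-01T00:00:00,PLT,250",
    "2024-01-01T00:01:00,PLT,not-a-number"
  ), path)
  expect_error(read_results(path), "row 2")
})

test_that("empty files and empty event lists produce empty, valid objects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,center_id,analyte,value,flags,stream,qc_level", path)
  expect_equal(nrow(read_results(path)), 0)

  empty <- tibble::tibble(
    kind = character(0), classification = character(0),
    analyte = character(0), center_id = character(0),
    t_trigger = as.POSIXct(character(0), tz = "UTC")
  )
  write_events(empty, path)
  expect_equal(nrow(read_events(path)), 0)
})

test_that("timestamp regressions within a stream are a hard error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,analyte,value",
    "2024-01-01T01:00:00,PLT,250",
    "2024-01-01T00:59:00,PLT,251"
  ), path)
  expect_error(read_results(path), "non-decreasing")
})

test_that("event logs round-trip with dual classification preserved", {
  events <- tibble::tibble(
    kind = c("ma_alert", "westgard_violation"),
    classification = c("dual", "out_of_control"),
    analyte = "PLT",
    center_id = "C1",
    t_trigger = as.POSIXct(c("2024-01-02 08:00:00", "2024-01-02 09:00:00"), tz = "UTC"),
    t_confirmed = as.POSIXct(c("2024-01-02 09:00:00", "2024-01-02 09:00:00"), tz = "UTC"),
    confirmed_by = c("1-3s", "1-3s"),
    action = c("suspend_testing", "recalibration"),
    note = c(NA_character_, NA_character_)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(events, path)
  back <- read_events(path)
  expect_equal(back, events)
})
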