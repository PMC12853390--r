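test_that("streams are reproducible from the seed and distinct across seeds", {
  sc <- scenario_spec(n_samples = 500, seed = 42)
  a <- simulate_patient_stream(sc)
  b <- simulate_patient_stream(sc)
  expect_identical(a$stream$value, b$stream$value)
  expect_identical(a$labels, b$labels)
  c <- simulate_patient_stream(scenario_spec(n_samples = 500, seed = 43))
  expect_false(identical(a$stream$value, c$stream$value))
})

test_that("stream shape: count, strictly increasing timestamps, hour scaling", {
  sim <- simulate_patient_stream(scenario_spec(n_samples = 500, seed = 1, sampling_rate = 20))
  expect_equal(nrow(sim$stream), 500)
  expect_true(all(diff(as.numeric(sim$stream$timestamp)) > 0))
  expect_equal(
    as.numeric(difftime(sim$stream$timestamp[21], sim$stream$timestamp[1], units = "hours")),
    1
  )
})

test_that("a step shift moves the post-onset mean by its stated magnitude", {
  spec <- plt_spec()
  sc <- scenario_spec(
    n_samples = 500, seed = 10, flag_rate = 0, outlier_rate = 0,
    errors = list(error_spec("step_shift", onset = 250, magnitude = 1, duration = 251))
  )
  sim <- simulate_patient_stream(sc)
  shift <- mean(sim$stream$value[250:500]) - mean(sim$stream$value[1:249])
  expect_lt(abs(shift - spec$target_sd), 0.2 * spec$target_sd)
})

test_that("generated CV matches the requested CV within sampling error", {
  for (seed in 1:3) {
    sim <- simulate_patient_stream(scenario_spec(
      n_samples = 2000, seed = seed, baseline_cv = 2.8,
      flag_rate = 0, outlier_rate = 0
    ))
    se <- 2.8 / sqrt(2 * 2000)
    expect_lt(abs(compute_cv(sim$stream$value) - 2.8), 3 * se)
  }
})

test_that("both distribution families reproduce the target mean and CV", {
  for (dist in c("normal", "lognormal")) {
    sim <- simulate_patient_stream(scenario_spec(
      n_samples = 20000, seed = 5, distribution = dist,
      flag_rate = 0, outlier_rate = 0
    ))
    expect_lt(abs(mean(sim$stream$value) - 250) / 250, 0.005)
    expect_lt(abs(compute_cv(sim$stream$value) - 2.8), 0.15)
  }
})

test_that("labels conserve the injected error durations", {
  sc <- scenario_spec(
    n_samples = 800, seed = 2,
    errors = list(
      error_spec("step_shift", onset = 100, magnitude = 1, duration = 50),
      error_spec("linear_drift", onset = 400, magnitude = 0.2, duration = 120)
    )
  )
  sim <- simulate_patient_stream(sc)
  expect_equal(sum(sim$labels$in_error), 170)
  expect_equal(sum(sim$labels$error_kind == "linear_drift", na.rm = TRUE), 120)
  expect_error(
    scenario_spec(n_samples = 100, errors = list(
      error_spec("step_shift", onset = 90, magnitude = 1, duration = 20)
    )),
    "beyond the stream"
  )
})

test_that("cv inflation widens the noise without moving the mean", {
  sc <- scenario_spec(
    n_samples = 3000, seed = 9, flag_rate = 0, outlier_rate = 0,
    errors = list(error_spec("cv_inflation", onset = 1501, magnitude = 3, duration = 1500))
  )
  sim <- simulate_patient_stream(sc)
  pre <- sim$stream$value[1:1500]
  post <- sim$stream$value[1501:3000]
  expect_gt(sd(post) / sd(pre), 2)
  expect_lt(abs(mean(post) - mean(pre)), 2) # means stay comparable
})

test_that("QC streams honour levels, runs, bias and noise", {
  spec <- plt_spec()
  qc <- simulate_qc_stream(spec, levels = 2, runs = 180, bias_pct = 0, cv_pct = 1e-9, seed = 1)
  expect_equal(nrow(qc), 360)
  expect_true(all(abs(qc$value - 250) < 1e-4))
  expect_setequal(unique(qc$qc_level), c("L1", "L2"))
  expect_equal(as.numeric(difftime(qc$timestamp[3], qc$timestamp[1], units = "hours")), 12)

  biased <- simulate_qc_stream(spec, levels = 2, runs = 1000, bias_pct = 5, cv_pct = 2, seed = 2)
  expect_lt(abs(compute_bias(mean(biased$value), spec$reference_value) - 5), 0.1)
})

test_that("the benchmark suite lays out the full factorial grid with a manifest", {
  suite <- make_benchmark_suite(replicates = 2)
  expect_equal(length(suite$scenarios), 4 * 3 * 2)
  expect_equal(nrow(suite$manifest), 24)
  expect_setequal(unique(suite$manifest$window), c(50, 100, 150))
  expect_setequal(unique(suite$manifest$shift_sd), c(0.1, 0.25, 0.5, 1.0))
  # manifest identifies its scenario exactly
  row <- suite$manifest[7, ]
  sc <- suite$scenarios[[row$id]]
  expect_equal(sc$seed, row$seed)
  expect_equal(sc$errors[[1]]$magnitude, row$shift_sd)
  # the same manifest rebuilds the same grid
  suite2 <- make_benchmark_suite(replicates = 2)
  expect_identical(suite$manifest, suite2$manifest)
})
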