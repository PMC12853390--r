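spec <- default_analyte_specs("PLT")

# a degenerate forecaster whose prediction is the constant `dev` (analyte
# units); exercises the warning rule independently of training
constant_forecaster <- function(dev, spec) {
  h <- 4L
  structure(
    list(
      weights = list(
        Wx = matrix(0, 1, 4 * h), Wh = matrix(0, h, 4 * h),
        b = rep(0, 4 * h), Wy = rep(0, h), by = dev / spec$target_sd
      ),
      config = forecaster_config(hidden_units = h),
      analyte = spec$name, target_mean = spec$target_mean,
      target_sd = spec$target_sd
    ),
    class = "qc_forecaster"
  )
}

test_that("window construction counts pairs and computes targets exactly", {
  cfg <- forecaster_config()
  w <- build_windows(rep(250, 110), spec, cfg)
  expect_equal(nrow(w$x), 1)
  expect_error(build_windows(rep(250, 109), spec, cfg), "too short")
  expect_equal(nrow(build_windows(rep(250, 120), spec, cfg)$x), 11)

  series <- seq(240, by = 0.5, length.out = 115)
  w <- build_windows(series, spec, cfg)
  # inputs standardized by the analyte constants
  expect_equal(w$x[1, ], (series[1:100] - 250) / 7)
  # target is the mean deviation of the next horizon samples
  expect_equal(w$y[1], mean(series[101:110]) - 250)
  expect_equal(w$y[6], mean(series[106:115]) - 250)
})

test_that("red alert uses a strict threshold at the configured TEa fraction", {
  tea <- tea_units(spec)
  win <- rep(spec$target_mean, 100)
  expect_true(predict_and_warn(constant_forecaster(0.6 * tea, spec), win, spec)$red_alert)
  expect_false(predict_and_warn(constant_forecaster(0.4 * tea, spec), win, spec)$red_alert)
  # exactly 50% of TEa does not alert: the deviation must exceed the threshold
  expect_false(predict_and_warn(constant_forecaster(0.5 * tea, spec), win, spec)$red_alert)
  # symmetric for negative deviations
  expect_true(predict_and_warn(constant_forecaster(-0.6 * tea, spec), win, spec)$red_alert)

  f <- predict_and_warn(constant_forecaster(0.6 * tea, spec), win, spec)
  expect_equal(f$deviation_fraction_tea, 0.6, tolerance = 1e-9)
  expect_error(
    predict_and_warn(constant_forecaster(1, spec), rep(250, 99), spec),
    "input_len"
  )
})

test_that("training is deterministic given data and seed", {
  set.seed(5)
  series <- rnorm(400, 250, 7)
  w <- build_windows(series, spec, forecaster_config())
  cfg <- forecaster_config(max_epochs = 4, cv_folds = 0, seed = 99)
  f1 <- train_forecaster(w, spec, cfg)
  f2 <- train_forecaster(w, spec, cfg)
  expect_identical(f1$val_mae, f2$val_mae)
  expect_identical(f1$weights, f2$weights)
  f3 <- train_forecaster(w, spec, forecaster_config(max_epochs = 4, cv_folds = 0, seed = 100))
  expect_false(identical(f3$weights, f1$weights))
})

test_that("a noiseless constant series is learned to near-zero error", {
  series <- rep(spec$target_mean, 400)
  w <- build_windows(series, spec, forecaster_config())
  fit <- train_forecaster(
    w, spec,
    forecaster_config(max_epochs = 60, patience = 60, cv_folds = 0, seed = 3)
  )
  expect_lte(fit$val_mae, 0.01 * spec$target_sd)
})

test_that("on a pure drift the predicted deviation carries the drift sign", {
  for (sgn in c(1, -1)) {
    series <- spec$target_mean + sgn * 0.35 * seq_len(400)
    w <- build_windows(series, spec, forecaster_config())
    fit <- train_forecaster(
      w, spec,
      forecaster_config(max_epochs = 25, patience = 25, cv_folds = 0, seed = 17)
    )
    preds <- sigmaqc:::lstm_predict_cpp(fit$weights, w$x)
    expect_gte(mean(sign(preds) == sgn), 0.95)
  }
})

test_that("no spurious skill: white-noise validation MAE matches the noise floor", {
  set.seed(21)
  series <- rnorm(1500, spec$target_mean, spec$target_sd)
  w <- build_windows(series, spec, forecaster_config())
  fit <- train_forecaster(
    w, spec,
    forecaster_config(max_epochs = 12, patience = 12, cv_folds = 0, seed = 8)
  )
  # target = mean of 10 iid draws: E|dev| = sd * sqrt(2/(10*pi))
  floor_mae <- spec$target_sd * sqrt(2 / (10 * pi))
  expect_lt(abs(fit$val_mae - floor_mae) / floor_mae, 0.2)
})

test_that("cross-validation reports one MAE per fold and respects preconditions", {
  set.seed(9)
  series <- rnorm(400, 250, 7)
  w <- build_windows(series, spec, forecaster_config())
  fit <- train_forecaster(
    w, spec,
    forecaster_config(max_epochs = 3, cv_folds = 3, seed = 2)
  )
  expect_length(fit$fold_maes, 3)
  expect_true(all(is.finite(fit$fold_maes)))
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(glance(fit)$n_pairs, nrow(w$x))

  short <- build_windows(rnorm(140, 250, 7), spec, forecaster_config())
  expect_error(
    train_forecaster(short, spec, forecaster_config(cv_folds = 5)),
    "too few"
  )
})

test_that("forecast_stream strides along the accepted series", {
  f <- constant_forecaster(8, spec) # 0.8 x TEa: always red
  fc <- forecast_stream(f, rnorm(160, 250, 7), spec, stride = 10)
  expect_equal(fc$index, c(100, 110, 120, 130, 140, 150, 160))
  expect_true(all(fc$red_alert))
  expect_equal(nrow(forecast_stream(f, rnorm(50, 250, 7), spec)), 0)
})
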