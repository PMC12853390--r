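#' Forecaster configuration
#'
#' Parameters of the LSTM deviation forecaster. Defaults follow the adopted
#' architecture: 100 consecutive accepted patient values in, a single
#' recurrent layer of 64 tanh units, a linear head predicting the mean
#' deviation of the next 10 samples, MAE loss, an 8:2 train/validation
#' split with five-fold cross-validation inside the training portion, early
#' stopping, and a red-alert threshold at 50% of TEa (strict inequality:
#' the predicted deviation must exceed the threshold).
#'
#' @param input_len Input window length in samples.
#' @param horizon Forecast horizon in samples (target = mean deviation of
#'   these samples from the target mean).
#' @param hidden_units LSTM hidden width.
#' @param activation Recurrent activation (`"tanh"`; informational — the
#'   implementation is a standard tanh LSTM).
#' @param split_ratio Training fraction of the supervised pairs (default 0.8).
#' @param cv_folds Folds of cross-validation run inside the training portion
#'   (default 5; set 0 to skip).
#' @param warn_fraction_of_tea Red-alert threshold as a fraction of TEa.
#' @param max_epochs,patience Optimizer budget and early-stopping patience.
#' @param batch_size,learning_rate Minibatch size and Adam learning rate.
#' @param seed Integer seed governing weight initialization, the split, fold
#'   assignment and minibatch order.
#' @return A list of class `forecaster_config`.
#' @export
forecaster_config <- function(input_len = 100L, horizon = 10L,
                              hidden_units = 64L, activation = "tanh",
                              split_ratio = 0.8, cv_folds = 5L,
                              warn_fraction_of_tea = 0.5,
                              max_epochs = 200L, patience = 10L,
                              batch_size = 128L, learning_rate = 0.005,
                              seed = 1L) {
  stopifnot(
    input_len > horizon, horizon >= 1,
    warn_fraction_of_tea > 0, warn_fraction_of_tea < 1,
    split_ratio > 0, split_ratio < 1,
    hidden_units >= 1, max_epochs >= 1, patience >= 1
  )
  structure(
    list(
      input_len = as.integer(input_len), horizon = as.integer(horizon),
      hidden_units = as.integer(hidden_units), activation = activation,
      split_ratio = split_ratio, cv_folds = as.integer(cv_folds),
      warn_fraction_of_tea = warn_fraction_of_tea,
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      seed = as.integer(seed)
    ),
    class = "forecaster_config"
  )
}

#' Build supervised windows from an accepted patient series
#'
#' Slides a stride-1 window over the accepted series: each pair maps
#' `input_len` consecutive values (standardized by the analyte target mean
#' and SD) to a scalar target, the mean of the following `horizon` values
#' minus the target mean, in analyte units.
#'
#' @param series Numeric vector of accepted (post-preprocessing) values.
#' @param spec An [analyte_spec()].
#' @param config A [forecaster_config()].
#' @return List with `x` (pairs x input_len matrix, standardized), `y`
#'   (deviations, analyte units), and `index` (position of the last input
#'   sample of each window within `series`).
#' @examples
#' spec <- default_analyte_specs("PLT")
#' w <- build_windows(rnorm(120, 250, 7), spec, forecaster_config())
#' dim(w$x) # 11 x 100
#' @export
build_windows <- function(series, spec, config = forecaster_config()) {
  stopifnot(inherits(spec, "analyte_spec"))
  len <- config$input_len + config$horizon
  n_pairs <- length(series) - len + 1
  if (n_pairs < 1) {
    stop(
      "series too short: need at least input_len + horizon = ", len,
      " values, got ", length(series),
      call. = FALSE
    )
  }
  idx <- outer(seq_len(n_pairs) - 1L, seq_len(len), `+`)
  m <- matrix(series[idx], nrow = n_pairs)
  x <- (m[, seq_len(config$input_len), drop = FALSE] - spec$target_mean) /
    spec$target_sd
  y <- rowMeans(m[, config$input_len + seq_len(config$horizon), drop = FALSE]) -
    spec$target_mean
  list(x = x, y = y, index = seq_len(n_pairs) + config$input_len - 1L)
}

init_lstm_weights <- function(hidden) {
  r <- 1 / sqrt(hidden)
  w <- list(
    Wx = matrix(stats::runif(4 * hidden, -r, r), nrow = 1),
    Wh = matrix(stats::runif(4 * hidden * hidden, -r, r), nrow = hidden),
    b = rep(0, 4 * hidden),
    Wy = stats::runif(hidden, -r, r),
    by = 0
  )
  w$b[hidden + seq_len(hidden)] <- 1 # forget-gate bias
  w
}

fit_lstm <- function(x_train, y_train, x_val, y_val, config) {
  n <- nrow(x_train)
  order <- vapply(
    seq_len(config$max_epochs), function(e) sample.int(n),
    integer(n)
  )
  w0 <- init_lstm_weights(config$hidden_units)
  lstm_train_cpp(
    x_train, y_train, x_val, y_val, w0,
    max_epochs = config$max_epochs, patience = config$patience,
    batch_size = min(config$batch_size, n), lr = config$learning_rate,
    order = order
  )
}

#' Train the deviation forecaster
#'
#' Splits the supervised pairs 8:2 into training and held-out validation
#' (random split, deterministic from the config seed), optionally runs
#' k-fold cross-validation inside the training portion (each fold trained
#' with early stopping against the fold itself), then trains the final
#' model on the full training portion with early stopping against the
#' held-out 20%, whose MAE is the reported validation error. Targets are
#' standardized by the analyte target SD during optimization; all reported
#' MAEs are in analyte units.
#'
#' @param windows Output of [build_windows()].
#' @param spec The [analyte_spec()] the windows were built against.
#' @param config A [forecaster_config()].
#' @return Object of class `qc_forecaster`: weights, config, analyte
#'   constants, `val_mae` (analyte units), `fold_maes`, training history.
#'   Supports [tidy()], [glance()], [predict_and_warn()],
#'   [forecast_stream()].
#' @export
train_forecaster <- function(windows, spec, config = forecaster_config()) {
  stopifnot(inherits(spec, "analyte_spec"))
  x <- windows$x
  y_std <- windows$y / spec$target_sd
  n <- nrow(x)
  if (config$cv_folds >= 2 && n < config$cv_folds * 10) {
    stop(
      "too few pairs for ", config$cv_folds, "-fold cross-validation: ", n,
      call. = FALSE
    )
  }
  if (n < 20) stop("too few supervised pairs to train: ", n, call. = FALSE)

  restore <- set_local_seed(config$seed)
  on.exit(restore(), add = TRUE)

  perm <- sample.int(n)
  n_train <- max(2L, floor(config$split_ratio * n))
  train_idx <- perm[seq_len(n_train)]
  val_idx <- perm[seq.int(n_train + 1L, n)]

  fold_maes <- numeric(0)
  if (config$cv_folds >= 2) {
    fold_of <- rep_len(seq_len(config$cv_folds), n_train)
    fold_maes <- vapply(seq_len(config$cv_folds), function(k) {
      tr <- train_idx[fold_of != k]
      va <- train_idx[fold_of == k]
      fit <- fit_lstm(x[tr, , drop = FALSE], y_std[tr],
        x[va, , drop = FALSE], y_std[va], config
      )
      fit$val_mae * spec$target_sd
    }, numeric(1))
  }

  fit <- fit_lstm(
    x[train_idx, , drop = FALSE], y_std[train_idx],
    x[val_idx, , drop = FALSE], y_std[val_idx], config
  )

  structure(
    list(
      weights = fit$weights,
      config = config,
      analyte = spec$name,
      target_mean = spec$target_mean,
      target_sd = spec$target_sd,
      val_mae = fit$val_mae * spec$target_sd,
      fold_maes = fold_maes,
      best_epoch = fit$best_epoch,
      history = tibble::tibble(
        epoch = seq_along(fit$history_val),
        train_mae = fit$history_train * spec$target_sd,
        val_mae = fit$history_val * spec$target_sd
      ),
      n_pairs = n, n_train = n_train, n_val = length(val_idx)
    ),
    class = "qc_forecaster"
  )
}

#' @export
print.qc_forecaster <- function(x, ...) {
  cat(sprintf(
    "<qc_forecaster> %s: LSTM %d -> %d (hidden %d), val MAE %.3f (%d+%d pairs)\n",
    x$analyte, x$config$input_len, x$config$horizon, x$config$hidden_units,
    x$val_mae, x$n_train, x$n_val
  ))
  invisible(x)
}

#' @export
glance.qc_forecaster <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte, n_pairs = x$n_pairs, n_train = x$n_train,
    n_val = x$n_val, val_mae = x$val_mae, best_epoch = x$best_epoch,
    epochs_run = nrow(x$history), cv_folds = x$config$cv_folds
  )
}

#' @export
tidy.qc_forecaster <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_maes), mae = x$fold_maes)
}

#' Plot forecaster training history
#' @param object A `qc_forecaster`.
#' @param ... Unused.
#' @return A ggplot of train/validation MAE per epoch.
#' @export
autoplot.qc_forecaster <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "series", values_to = "mae"
  )
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$mae, color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      y = paste0("MAE (analyte units)"),
      title = paste("Forecaster training:", object$analyte)
    ) +
    ggplot2::theme_minimal()
}

#' Forecast the upcoming mean deviation and decide on a red alert
#'
#' Feeds the last `input_len` accepted values through the trained model and
#' converts the predicted mean deviation of the next `horizon` samples into
#' a fraction of TEa. A red alert is raised when the absolute fraction
#' strictly exceeds `warn_fraction_of_tea` (a prediction of exactly the
#' threshold does not alert).
#'
#' @param model A [train_forecaster()] fit.
#' @param last_window Numeric vector of exactly `input_len` accepted values.
#' @param spec The [analyte_spec()] (supplies TEa).
#' @param issued_at Optional timestamp to stamp on the forecast.
#' @return One-row tibble: `predicted_deviation` (analyte units),
#'   `deviation_fraction_tea`, `red_alert`, `issued_at`.
#' @export
predict_and_warn <- function(model, last_window, spec, issued_at = NA) {
  stopifnot(inherits(model, "qc_forecaster"), inherits(spec, "analyte_spec"))
  if (length(last_window) != model$config$input_len) {
    stop(
      "window must have exactly input_len = ", model$config$input_len,
      " values, got ", length(last_window),
      call. = FALSE
    )
  }
  x <- matrix((last_window - model$target_mean) / model$target_sd, nrow = 1)
  dev_units <- as.numeric(lstm_predict_cpp(model$weights, x)) * model$target_sd
  frac <- dev_units / tea_units(spec)
  tibble::tibble(
    predicted_deviation = dev_units,
    deviation_fraction_tea = frac,
    red_alert = abs(frac) > model$config$warn_fraction_of_tea,
    issued_at = issued_at
  )
}

#' Forecast along an accepted stream
#'
#' Slides the trained forecaster along an accepted series, re-forecasting
#' every `stride` accepted samples (default from the orchestrator config:
#' every 10), and applies the red-alert rule at each forecast.
#'
#' @param model A [train_forecaster()] fit.
#' @param stream Accepted result tibble (or numeric vector) in time order.
#' @param spec The [analyte_spec()].
#' @param stride Accepted samples between forecasts.
#' @return Tibble with one row per forecast: `index` (position of the last
#'   input sample), `issued_at`, `predicted_deviation`,
#'   `deviation_fraction_tea`, `red_alert`.
#' @export
forecast_stream <- function(model, stream, spec, stride = 10L) {
  if (is.numeric(stream)) {
    values <- stream
    timestamps <- seq_along(values)
  } else {
    values <- stream$value
    timestamps <- stream$timestamp
  }
  len <- model$config$input_len
  if (length(values) < len) {
    return(tibble::tibble(
      index = integer(0), issued_at = timestamps[0],
      predicted_deviation = numeric(0), deviation_fraction_tea = numeric(0),
      red_alert = logical(0)
    ))
  }
  at <- seq.int(len, length(values), by = stride)
  x <- t(vapply(at, function(i) {
    (values[(i - len + 1):i] - model$target_mean) / model$target_sd
  }, numeric(len)))
  dev_units <- as.numeric(lstm_predict_cpp(model$weights, x)) * model$target_sd
  frac <- dev_units / tea_units(spec)
  tibble::tibble(
    index = at,
    issued_at = timestamps[at],
    predicted_deviation = dev_units,
    deviation_fraction_tea = frac,
    red_alert = abs(frac) > model$config$warn_fraction_of_tea
  )
}
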