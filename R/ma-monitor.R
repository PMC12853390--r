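#' Preprocess a patient-result stream for monitoring
#'
#' Applies the exclusion rules used before any patient-based monitoring:
#' samples carrying pre-analytical flags (hemolysis, lipemia, clot) are
#' dropped when `drop_flagged` is set, and gross outliers beyond
#' `outlier_sd` target SDs from the target mean are removed. The outlier
#' reference is the fixed analyte target, not a rolling statistic, so a
#' genuine sustained shift is not masked by its own effect on the estimate.
#' A sample that is both flagged and an outlier counts once, as flagged.
#'
#' @param points Result tibble (see [read_results()]), patient stream,
#'   time-ordered.
#' @param spec An [analyte_spec()].
#' @param config A [run_config()]; uses `config$preprocessing`.
#' @return List with `stream` (the filtered tibble) and `report`, a one-row
#'   tibble with counts `n_in`, `n_flag_removed`, `n_outlier_removed`,
#'   `n_out` satisfying `n_in = n_out + n_flag_removed + n_outlier_removed`.
#' @export
preprocess_stream <- function(points, spec, config = run_config()) {
  stopifnot(inherits(spec, "analyte_spec"))
  pp <- config$preprocessing
  n_in <- nrow(points)
  flagged <- if (pp$drop_flagged && "flags" %in% names(points)) {
    vapply(points$flags, function(f) length(f) > 0, logical(1))
  } else {
    rep(FALSE, n_in)
  }
  outlier <- abs(points$value - spec$target_mean) > pp$outlier_sd * spec$target_sd
  outlier <- outlier & !flagged
  keep <- !flagged & !outlier
  list(
    stream = points[keep, ],
    report = tibble::tibble(
      n_in = n_in,
      n_flag_removed = sum(flagged),
      n_outlier_removed = sum(outlier),
      n_out = sum(keep)
    )
  )
}

#' Adaptive window choice from real-time vs historical CV
#'
#' The monitor shrinks its window to react faster when short-term variability
#' rises, and widens it to suppress spurious alarms when the stream is quiet:
#' the window drops to `min_window` (50) when the real-time CV exceeds the
#' historical CV, grows to `max_window` (150) when it does not, and stays at
#' `baseline_window` (100) while either CV is still unavailable (warm-up).
#'
#' @param realtime_cv Percent CV over the current buffer (or `NA`).
#' @param historical_cv Percent CV over the trailing horizon (or `NA`).
#' @param config A [run_config()]; uses `config$ma`.
#' @return The window size to use, one of min/baseline/max.
#' @examples
#' adapt_window(3.6, 2.8) # 50
#' adapt_window(2.8, 2.8) # 150
#' adapt_window(NA, NA)   # 100
#' @export
adapt_window <- function(realtime_cv, historical_cv, config = run_config()) {
  ma <- config$ma
  if (is.na(realtime_cv) || is.na(historical_cv)) {
    return(ma$baseline_window)
  }
  if (realtime_cv > historical_cv) ma$min_window else ma$max_window
}

#' Escalation decision from the monitor state
#'
#' Testing is suspended for investigation when the MA breaches the alert
#' limit on three consecutive evaluations, or breaches the out-of-control
#' limit once; otherwise testing continues. ("Three consecutive runs" is
#' implemented as three consecutive evaluated samples; the stream carries no
#' batch structure.)
#'
#' @param status Current status, one of `"in_control"`, `"alert"`,
#'   `"out_of_control"`.
#' @param consecutive_alerts Current count of consecutive alert evaluations.
#' @return `"suspend_and_investigate"` or `"continue"`.
#' @export
escalation_decision <- function(status, consecutive_alerts) {
  if (identical(status, "out_of_control") || consecutive_alerts >= 3) {
    "suspend_and_investigate"
  } else {
    "continue"
  }
}

#' Adaptive-window moving-average monitor of a patient stream
#'
#' Runs the full MA monitor over a preprocessed (accepted) patient series:
#' a sliding mean over the last `W` accepted values, re-evaluated at every
#' sample, with `W` adapted between 50/100/150 by [adapt_window()] and
#' status derived from dynamic control limits
#' `target_mean +/- k * SD_limit` (`k_alert` = 1.5, `k_ooc` = 2.5).
#'
#' `SD_limit` depends on `config$ma$sd_mode`:
#' * `"ma_statistic"` (default): the sampling SD of the MA statistic,
#'   `sd_baseline / sqrt(W)`, where `sd_baseline` is the empirical SD of the
#'   first `calibration_n` accepted values (frozen once available;
#'   `target_sd` is used until then). Limits on an averaged statistic must
#'   reflect its own sampling variability, otherwise a +/- 1.5 SD limit on a
#'   100-sample mean would essentially never fire. The baseline-value route
#'   estimates that variability far more stably than the SD of the (heavily
#'   autocorrelated) MA series itself.
#' * `"population"`: the raw `target_sd`. This literal reading makes the MA
#'   a detector of only gross sustained shifts.
#'
#' No status is emitted until the buffer first reaches the baseline window
#' (warm-up). On window shrink, the most recent `min_window` values are
#' kept; on growth the buffer extends to `max_window`.
#'
#' @param stream Accepted patient result tibble (output of
#'   [preprocess_stream()]), or a bare numeric vector of accepted values.
#' @param spec An [analyte_spec()].
#' @param config A [run_config()].
#' @return Object of class `ma_monitor`: a list with `trace` (one row per
#'   accepted sample: `index`, `timestamp`, `value`, `window`, `ma`,
#'   `realtime_cv`, `historical_cv`, `sd_limit`, `z`, `status`,
#'   `consecutive_alerts`, `decision`), `spec`, and `config`.
#' @examples
#' spec <- default_analyte_specs("PLT")
#' sim <- simulate_patient_stream(scenario_spec(n_samples = 300, seed = 7))
#' mon <- ma_monitor(sim$stream$value, spec)
#' table(mon$trace$status)
#' @export
ma_monitor <- function(stream, spec, config = run_config()) {
  stopifnot(inherits(spec, "analyte_spec"))
  if (is.numeric(stream)) {
    values <- stream
    timestamps <- seq_along(values)
  } else {
    values <- stream$value
    timestamps <- stream$timestamp
  }
  ma_cfg <- config$ma
  n <- length(values)
  target <- spec$target_mean

  # O(1) rolling statistics via cumulative sums over the accepted series
  cs <- c(0, cumsum(values))
  cs2 <- c(0, cumsum(values^2))
  win_stats <- function(i, w) {
    s <- cs[i + 1] - cs[i + 1 - w]
    s2 <- cs2[i + 1] - cs2[i + 1 - w]
    m <- s / w
    var <- max((s2 - w * m^2) / (w - 1), 0)
    c(mean = m, cv = 100 * sqrt(var) / m)
  }

  window <- integer(n)
  ma <- rt_cv <- hist_cv <- sd_lim <- z <- rep(NA_real_, n)
  status <- decision <- rep(NA_character_, n)
  consec <- integer(n)

  w_cur <- ma_cfg$baseline_window
  consec_alerts <- 0L
  # frozen baseline-value SD for "ma_statistic" limits
  sd_base <- if (ma_cfg$calibration_n > 0 && n >= ma_cfg$calibration_n) {
    stats::sd(values[seq_len(ma_cfg$calibration_n)])
  } else {
    NA_real_
  }

  for (i in seq_len(n)) {
    if (i < ma_cfg$baseline_window) {
      window[i] <- ma_cfg$baseline_window
      next # warm-up: no MA, no status
    }
    # historical CV over the trailing horizon (needs history beyond warm-up)
    h <- min(ma_cfg$historical_cv_horizon, i)
    hs <- win_stats(i, h)
    hist_cv[i] <- hs[["cv"]]
    # real-time CV over the current buffer
    w_eff <- min(w_cur, i)
    rs <- win_stats(i, w_eff)
    rt_cv[i] <- rs[["cv"]]
    # adapt, then evaluate the MA over the adapted window
    w_cur <- adapt_window(rt_cv[i], hist_cv[i], config)
    w_eff <- min(w_cur, i)
    window[i] <- w_cur
    st <- win_stats(i, w_eff)
    ma[i] <- st[["mean"]]

    if (ma_cfg$sd_mode == "population") {
      sd_lim[i] <- spec$target_sd
    } else if (!is.na(sd_base) && i >= ma_cfg$calibration_n) {
      sd_lim[i] <- sd_base / sqrt(w_eff)
    } else {
      sd_lim[i] <- spec$target_sd / sqrt(w_eff)
    }

    z[i] <- (ma[i] - target) / sd_lim[i]
    status[i] <- if (abs(z[i]) > ma_cfg$k_ooc) {
      "out_of_control"
    } else if (abs(z[i]) > ma_cfg$k_alert) {
      "alert"
    } else {
      "in_control"
    }
    consec_alerts <- if (status[i] == "alert") consec_alerts + 1L else 0L
    consec[i] <- consec_alerts
    decision[i] <- escalation_decision(status[i], consec_alerts)
  }

  trace <- tibble::tibble(
    index = seq_len(n), timestamp = timestamps, value = values,
    window = window, ma = ma, realtime_cv = rt_cv, historical_cv = hist_cv,
    sd_limit = sd_lim, z = z, status = status,
    consecutive_alerts = consec, decision = decision
  )
  structure(list(trace = trace, spec = spec, config = config),
    class = "ma_monitor"
  )
}

#' @export
print.ma_monitor <- function(x, ...) {
  tr <- x$trace
  evald <- tr[!is.na(tr$status), ]
  cat(sprintf(
    "<ma_monitor> %s: %d samples (%d evaluated); alerts %d, out-of-control %d\n",
    x$spec$name, nrow(tr), nrow(evald),
    sum(evald$status == "alert"), sum(evald$status == "out_of_control")
  ))
  invisible(x)
}

#' Plot an MA monitor trace
#'
#' Moving-average trajectory with the dynamic alert and out-of-control
#' limits, colored by status.
#'
#' @param object An `ma_monitor` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ma_monitor <- function(object, ...) {
  tr <- object$trace[!is.na(object$trace$ma), ]
  k_a <- object$config$ma$k_alert
  k_o <- object$config$ma$k_ooc
  target <- object$spec$target_mean
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$index, y = .data$ma)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = target - k_o * .data$sd_limit,
        ymax = target + k_o * .data$sd_limit
      ),
      fill = "grey85"
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = target - k_a * .data$sd_limit,
        ymax = target + k_a * .data$sd_limit
      ),
      fill = "grey95"
    ) +
    ggplot2::geom_hline(yintercept = target, linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(color = .data$status, group = 1)) +
    ggplot2::scale_color_manual(values = c(
      in_control = "#2c7fb8", alert = "#fe9929", out_of_control = "#d7301f"
    )) +
    ggplot2::labs(
      x = "accepted sample", y = paste0("moving average (", object$spec$units, ")"),
      color = "status",
      title = paste("Adaptive MA monitor:", object$spec$name)
    ) +
    ggplot2::theme_minimal()
}
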