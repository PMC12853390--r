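#' Monitoring run configuration
#'
#' Bundles the tunable parameters of the whole pipeline: preprocessing,
#' moving-average (MA) monitoring, Westgard rule selection, and the LSTM
#' forecaster. Defaults reproduce the adopted study settings: baseline MA
#' window of 100 consecutive patient samples adapting to 50/150 on the
#' real-time-vs-historical CV comparison, alert limit at +/- 1.5 SD and
#' out-of-control limit at +/- 2.5 SD, +/- 3 SD outlier exclusion, and an
#' LSTM reading 100 samples to predict the mean deviation of the next 10,
#' warning at 50% of TEa.
#'
#' @param preprocessing List: `outlier_sd` (exclude values beyond this many
#'   target SDs from the target mean; default 3) and `drop_flagged` (drop
#'   samples with pre-analytical flags; default `TRUE`).
#' @param ma List of MA-monitor parameters:
#'   * `baseline_window`, `min_window`, `max_window`: window sizes in samples
#'     (defaults 100, 50, 150);
#'   * `k_alert`, `k_ooc`: alert and out-of-control multipliers of the limit
#'     SD (defaults 1.5 and 2.5);
#'   * `historical_cv_horizon`: trailing accepted samples over which the
#'     historical CV is computed (default 1000);
#'   * `sd_mode`: `"ma_statistic"` scales the control limits by the sampling
#'     SD of the MA statistic itself (baseline value SD / sqrt(window),
#'     with `target_sd` in place of the baseline SD until calibrated);
#'     `"population"` uses the raw target SD;
#'   * `calibration_n`: number of initial accepted values whose SD calibrates
#'     the `"ma_statistic"` limits (default 500).
#' @param westgard List: `rules` (character vector of enabled rule names, see
#'   [evaluate_westgard()]), `sole_rule_rejects` (when a single 1-2s rule is
#'   configured, treat it as a rejection rather than a warning; default
#'   `TRUE`).
#' @param lstm A [forecaster_config()] list.
#' @param orchestrator List: `forecast_stride` (re-forecast every this many
#'   accepted samples, default 10), `episode_horizon_hours` (window used to
#'   pair upstream alerts with downstream confirmations, default 24).
#'
#' @return An object of class `run_config` (nested named list).
#' @examples
#' cfg <- run_config(ma = list(k_alert = 1.2))
#' cfg$ma$k_alert
#' @export
run_config <- function(preprocessing = list(), ma = list(), westgard = list(),
                       lstm = list(), orchestrator = list()) {
  cfg <- list(
    preprocessing = utils::modifyList(
      list(outlier_sd = 3, drop_flagged = TRUE), preprocessing
    ),
    ma = utils::modifyList(
      list(
        baseline_window = 100L, min_window = 50L, max_window = 150L,
        k_alert = 1.5, k_ooc = 2.5,
        historical_cv_horizon = 1000L,
        sd_mode = "ma_statistic", calibration_n = 500L
      ), ma
    ),
    westgard = utils::modifyList(
      list(
        rules = c("1-2s", "1-3s", "2-2s", "R-4s", "4-1s", "10x"),
        sole_rule_rejects = TRUE
      ), westgard
    ),
    lstm = do.call(forecaster_config, lstm),
    orchestrator = utils::modifyList(
      list(forecast_stride = 10L, episode_horizon_hours = 24), orchestrator
    )
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  ma <- cfg$ma
  if (!(ma$min_window <= ma$baseline_window && ma$baseline_window <= ma$max_window)) {
    stop("require min_window <= baseline_window <= max_window", call. = FALSE)
  }
  if (!(ma$k_alert < ma$k_ooc)) stop("require k_alert < k_ooc", call. = FALSE)
  if (!ma$sd_mode %in% c("ma_statistic", "population")) {
    stop("ma$sd_mode must be 'ma_statistic' or 'population'", call. = FALSE)
  }
  if (cfg$preprocessing$outlier_sd <= 0) stop("outlier_sd must be > 0", call. = FALSE)
  known <- c("1-2s", "1-3s", "2-2s", "R-4s", "4-1s", "10x")
  bad <- setdiff(cfg$westgard$rules, known)
  if (length(bad)) {
    stop("unknown Westgard rule(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf(
    "  preprocessing: outlier_sd=%g, drop_flagged=%s\n",
    x$preprocessing$outlier_sd, x$preprocessing$drop_flagged
  ))
  cat(sprintf(
    "  ma: windows {%d,%d,%d}, k_alert=%g, k_ooc=%g, sd_mode=%s\n",
    x$ma$min_window, x$ma$baseline_window, x$ma$max_window,
    x$ma$k_alert, x$ma$k_ooc, x$ma$sd_mode
  ))
  cat("  westgard:", paste(x$westgard$rules, collapse = " "), "\n")
  cat(sprintf(
    "  lstm: input %d -> horizon %d, hidden %d, warn at %g x TEa\n",
    x$lstm$input_len, x$lstm$horizon, x$lstm$hidden_units,
    x$lstm$warn_fraction_of_tea
  ))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- unclass(config)
  plain$lstm <- unclass(plain$lstm)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(
    preprocessing = raw$preprocessing %||% list(),
    ma = raw$ma %||% list(),
    westgard = raw$westgard %||% list(),
    lstm = raw$lstm %||% list(),
    orchestrator = raw$orchestrator %||% list()
  )
}
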