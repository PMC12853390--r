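#' Train the forecaster under the canonical drift protocol
#'
#' Convenience wrapper for the pinned lead-time study: simulates the
#' canonical training stream, preprocesses it under
#' [canonical_drift_config()], trims the accepted series to yield exactly
#' 5000 supervised windows, and trains the forecaster (100 epochs max,
#' patience 20, no inner cross-validation — the study needs one
#' well-converged model, not a model-selection estimate).
#'
#' @param scenario_seed Seed of the training stream.
#' @param model_seed Seed of the forecaster (init, split, batch order).
#' @param max_epochs,patience Optimizer budget.
#' @param cv_folds Inner cross-validation folds (default 0).
#' @return A [train_forecaster()] fit.
#' @export
canonical_forecaster <- function(scenario_seed = 11L, model_seed = 7L,
                                 max_epochs = 100L, patience = 20L,
                                 cv_folds = 0L) {
  spec <- default_analyte_specs("PLT")
  cfg <- canonical_drift_config()
  sim <- simulate_patient_stream(canonical_drift_scenario("train", seed = scenario_seed))
  acc <- preprocess_stream(sim$stream, spec, cfg)$stream$value
  acc <- acc[seq_len(min(length(acc), 5109L))]
  windows <- build_windows(acc, spec, forecaster_config())
  train_forecaster(
    windows, spec,
    forecaster_config(
      max_epochs = max_epochs, patience = patience,
      cv_folds = cv_folds, seed = model_seed
    )
  )
}

#' Forecaster-vs-monitor lead-time study on the canonical drift
#'
#' For each seeded replicate of the canonical test stream, runs the
#' forecaster (re-forecasting at every accepted sample, the same cadence at
#' which the MA is evaluated) and the MA monitor under
#' [canonical_drift_config()], and records the first red alert and the
#' first MA out-of-control onset at or after the drift onset. The lead is
#' their difference in hours (positive = the forecaster warned first).
#'
#' @param model A trained [qc_forecaster][train_forecaster()], e.g. from
#'   [canonical_forecaster()].
#' @param n_replicates Number of seeded test streams.
#' @param base_seed Replicate seeds are `base_seed + 1:n_replicates`.
#' @return Tibble with one row per replicate: `seed`, `red_alert_time`,
#'   `ma_ooc_time`, `lead_hours`.
#' @export
drift_lead_study <- function(model, n_replicates = 20, base_seed = 1000L) {
  spec <- default_analyte_specs("PLT")
  cfg <- canonical_drift_config()
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    sc <- canonical_drift_scenario("test", seed = base_seed + r)
    sim <- simulate_patient_stream(sc)
    accepted <- preprocess_stream(sim$stream, spec, cfg)$stream
    onset_time <- sim$stream$timestamp[sc$errors[[1]]$onset]

    fc <- forecast_stream(model, accepted, spec, stride = 1L)
    red <- fc$issued_at[fc$red_alert & fc$issued_at >= onset_time]

    tr <- ma_monitor(accepted, spec, cfg)$trace
    st <- ifelse(is.na(tr$status), "warmup", tr$status)
    edge <- st == "out_of_control" &
      dplyr::lag(st, default = "warmup") != "out_of_control"
    ooc <- tr$timestamp[edge & tr$timestamp >= onset_time]

    tibble::tibble(
      seed = base_seed + r,
      red_alert_time = red[1],
      ma_ooc_time = ooc[1],
      lead_hours = as.numeric(difftime(ooc[1], red[1], units = "hours"))
    )
  })
}
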