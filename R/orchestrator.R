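#' Classify a QC event by its trigger and Westgard verification outcome
#'
#' An event detected by the patient-data tiers (MA or forecaster) is an
#' *alerting* event until a Westgard failure confirms it, at which point it
#' is recorded under both classifications (a *dual* record). A Westgard
#' failure itself is an *out-of-control* event.
#'
#' @param trigger One of `"lstm_warning"`, `"ma_alert"`, `"ma_ooc"`,
#'   `"westgard_violation"`.
#' @param westgard_result One of `"violation"`, `"pass"`, `"pending"`.
#' @return Character vector of classifications: `"alerting"`,
#'   `"out_of_control"`, or both.
#' @examples
#' classify_event("ma_alert", "violation") # dual
#' @export
classify_event <- function(trigger, westgard_result = c("pending", "pass", "violation")) {
  trigger <- match.arg(trigger, c("lstm_warning", "ma_alert", "ma_ooc", "westgard_violation"))
  westgard_result <- match.arg(westgard_result)
  if (trigger == "westgard_violation") {
    return("out_of_control")
  }
  if (westgard_result == "violation") {
    c("alerting", "out_of_control")
  } else {
    "alerting"
  }
}

plan_row <- function(plan) {
  if (is.data.frame(plan)) {
    stopifnot(nrow(plan) == 1)
    list(
      tier = plan$tier, rules = plan$rules[[1]], ma_enabled = plan$ma_enabled,
      qc_frequency = plan$qc_frequency
    )
  } else {
    plan
  }
}

#' Run the three-tier monitoring pipeline over paired streams
#'
#' Integrates the tiers the QC plan enables: (1) the LSTM forecaster
#' re-forecasts along the accepted patient stream and raises red alerts;
#' (2) the adaptive MA monitor tracks the accepted stream against dynamic
#' limits; (3) the Westgard engine evaluates the control stream under the
#' plan's rule set. Patient-tier alerts are then verified: an alert followed
#' (within the episode horizon) by a Westgard rejection becomes a dual
#' alerting/out-of-control record with `t_confirmed` and `confirmed_by`
#' set. Patient samples are processed before QC samples at equal
#' timestamps.
#'
#' MA and LSTM events are emitted on rising edges (entry into alert or
#' out-of-control state), not at every affected sample. Escalation is
#' recorded on the event as `action = "suspend_testing"` when the MA breaches
#' the out-of-control limit or stays in alert for three consecutive
#' evaluations; confirmed Westgard rejections carry `action =
#' "recalibration"`.
#'
#' @param patient_stream Patient result tibble, time-ordered.
#' @param qc_stream Control result tibble (may have zero rows).
#' @param spec An [analyte_spec()].
#' @param plan One-row tibble from [stratify_plan()] (or an equivalent
#'   list). `ma_enabled` gates the MA tier; `rules` select the Westgard set.
#' @param config A [run_config()].
#' @param forecaster Optional [train_forecaster()] fit; when supplied the
#'   forecast tier is active.
#' @return Object of class `qc_run`: list with `events` (the ordered event
#'   log), `ma` (the [ma_monitor()] result or `NULL`), `forecasts`,
#'   `preprocess` (exclusion report), `plan`, `spec`, `config`.
#' @export
run_monitoring <- function(patient_stream, qc_stream, spec, plan,
                           config = run_config(), forecaster = NULL) {
  stopifnot(inherits(spec, "analyte_spec"))
  plan <- plan_row(plan)
  pp <- preprocess_stream(patient_stream, spec, config)
  accepted <- pp$stream
  center <- if (nrow(patient_stream)) patient_stream$center_id[1] else "C1"

  events <- list()
  ev <- function(kind, t_trigger, classification = "alerting",
                 t_confirmed = NA, confirmed_by = NA_character_,
                 action = "none") {
    tibble::tibble(
      kind = kind, classification = classification, analyte = spec$name,
      center_id = center, t_trigger = t_trigger,
      t_confirmed = as.POSIXct(
        if (is.na(t_confirmed)) NA_real_ else as.numeric(t_confirmed),
        origin = "1970-01-01", tz = "UTC"
      ),
      confirmed_by = confirmed_by, action = action, note = NA_character_
    )
  }

  # ---- tier 1: forecaster ----------------------------------------------
  forecasts <- NULL
  if (!is.null(forecaster) && nrow(accepted) >= forecaster$config$input_len) {
    forecasts <- forecast_stream(
      forecaster, accepted, spec,
      stride = config$orchestrator$forecast_stride
    )
    edge <- forecasts$red_alert & !dplyr::lag(forecasts$red_alert, default = FALSE)
    for (i in which(edge)) {
      events[[length(events) + 1]] <- ev("lstm_warning", forecasts$issued_at[i])
    }
  }

  # ---- tier 2: adaptive MA monitor -------------------------------------
  ma_fit <- NULL
  if (isTRUE(plan$ma_enabled) && nrow(accepted) > 0) {
    ma_fit <- ma_monitor(accepted, spec, config)
    tr <- ma_fit$trace[!is.na(ma_fit$trace$status), ]
    if (nrow(tr)) {
      prev <- dplyr::lag(tr$status, default = "in_control")
      alert_edge <- which(tr$status == "alert" & prev != "alert")
      ooc_edge <- which(tr$status == "out_of_control" & prev != "out_of_control")
      for (i in alert_edge) {
        # did this alert episode escalate to three consecutive alerts?
        j <- i
        while (j <= nrow(tr) && tr$status[j] == "alert") j <- j + 1
        escalated <- any(tr$consecutive_alerts[i:(j - 1)] >= 3)
        events[[length(events) + 1]] <- ev(
          "ma_alert", tr$timestamp[i],
          action = if (escalated) "suspend_testing" else "none"
        )
      }
      for (i in ooc_edge) {
        events[[length(events) + 1]] <- ev(
          "ma_ooc", tr$timestamp[i],
          action = "suspend_testing"
        )
      }
    }
  }

  # ---- tier 3: Westgard verification of the control stream -------------
  westgard_rej <- NULL
  if (nrow(qc_stream) > 0) {
    run_id <- match(qc_stream$timestamp, unique(qc_stream$timestamp))
    pts <- tibble::tibble(
      z = (qc_stream$value - spec$target_mean) / spec$target_sd,
      run_id = run_id,
      level = qc_stream$qc_level,
      timestamp = qc_stream$timestamp
    )
    viol <- evaluate_westgard(pts, plan$rules, config$westgard$sole_rule_rejects)
    westgard_rej <- viol[viol$severity == "rejection", ]
    for (i in seq_len(nrow(westgard_rej))) {
      events[[length(events) + 1]] <- ev(
        "westgard_violation", westgard_rej$timestamp[i],
        classification = "out_of_control",
        t_confirmed = westgard_rej$timestamp[i],
        confirmed_by = westgard_rej$rule[i],
        action = "recalibration"
      )
    }
  }

  log <- if (length(events)) dplyr::bind_rows(events) else as_event_log(
    tibble::tibble(
      kind = character(0), classification = character(0),
      analyte = character(0), center_id = character(0),
      t_trigger = as.POSIXct(character(0), tz = "UTC")
    )
  )

  # ---- verification pass: confirm patient-tier alerts -------------------
  if (nrow(log)) {
    horizon <- config$orchestrator$episode_horizon_hours * 3600
    rej_times <- if (!is.null(westgard_rej) && nrow(westgard_rej)) {
      westgard_rej$timestamp
    } else {
      NULL
    }
    for (i in seq_len(nrow(log))) {
      if (log$kind[i] == "westgard_violation" || is.null(rej_times)) next
      dt <- as.numeric(rej_times) - as.numeric(log$t_trigger[i])
      hit <- which(dt >= 0 & dt <= horizon)
      if (length(hit)) {
        k <- hit[which.min(dt[hit])]
        log$classification[i] <- "dual"
        log$t_confirmed[i] <- rej_times[k]
        log$confirmed_by[i] <- westgard_rej$rule[k]
      }
    }
    kind_order <- c("lstm_warning", "ma_alert", "ma_ooc", "westgard_violation")
    log <- log[order(log$t_trigger, match(log$kind, kind_order)), ]
  }

  structure(
    list(
      events = log, ma = ma_fit, forecasts = forecasts,
      preprocess = pp$report, plan = plan, spec = spec, config = config
    ),
    class = "qc_run"
  )
}

#' @export
print.qc_run <- function(x, ...) {
  cat(sprintf(
    "<qc_run> %s: %d events (%s)\n", x$spec$name, nrow(x$events),
    paste(names(table(x$events$kind)), table(x$events$kind),
      sep = "=", collapse = ", "
    )
  ))
  invisible(x)
}

#' Tally an event log by classification
#'
#' Counts alerting, out-of-control and dual records. A dual record counts
#' under both tallies, so `n_alerting >= n_dual` and `n_ooc >= n_dual`
#' always hold (the event-log conservation property).
#'
#' @param events Event tibble.
#' @return One-row tibble: `n_events`, `n_alerting`, `n_ooc`, `n_dual`.
#' @export
event_counts <- function(events) {
  tibble::tibble(
    n_events = nrow(events),
    n_alerting = sum(events$classification %in% c("alerting", "dual")),
    n_ooc = sum(events$classification %in% c("out_of_control", "dual")),
    n_dual = sum(events$classification == "dual")
  )
}

#' Lead times between monitoring tiers
#'
#' Summarizes, per episode, how far the upstream warning preceded the
#' downstream signal: forecaster red alerts vs the first subsequent MA
#' anomaly, and MA anomalies vs their Westgard confirmation. An episode
#' opens at an upstream event and is closed by the first downstream event
#' at or after it within the horizon; the next upstream event after the
#' closing downstream event opens the next episode. When no downstream
#' event arrives within the horizon the episode counts as unconfirmed
#' (excluded from the averages) and the scan resumes at the first upstream
#' event beyond the horizon.
#'
#' @param events Event tibble from [run_monitoring()].
#' @param horizon_hours Pairing horizon (default 24 h).
#' @return Tibble with one row per pair type (`lstm_to_ma`,
#'   `ma_to_westgard`): `n_episodes`, `n_paired`, `n_unconfirmed`,
#'   `mean_hours`, `median_hours`.
#' @export
compute_lead_times <- function(events, horizon_hours = 24) {
  horizon <- horizon_hours * 3600
  pair_summary <- function(pair, up_times, down_times) {
    up <- sort(as.numeric(up_times))
    down <- sort(as.numeric(down_times))
    leads <- numeric(0)
    n_episodes <- 0L
    n_unconfirmed <- 0L
    i <- 1L
    while (i <= length(up)) {
      t0 <- up[i]
      n_episodes <- n_episodes + 1L
      d <- down[down >= t0]
      if (length(d) && d[1] - t0 <= horizon) {
        leads <- c(leads, (d[1] - t0) / 3600)
        nxt <- which(up > d[1])
      } else {
        n_unconfirmed <- n_unconfirmed + 1L
        nxt <- which(up > t0 + horizon)
      }
      if (length(nxt) == 0) break
      i <- nxt[1]
    }
    tibble::tibble(
      pair = pair,
      n_episodes = n_episodes,
      n_paired = length(leads),
      n_unconfirmed = n_unconfirmed,
      mean_hours = if (length(leads)) mean(leads) else NA_real_,
      median_hours = if (length(leads)) stats::median(leads) else NA_real_
    )
  }
  lstm_t <- events$t_trigger[events$kind == "lstm_warning"]
  ma_t <- events$t_trigger[events$kind %in% c("ma_alert", "ma_ooc")]
  conf <- events[events$kind %in% c("ma_alert", "ma_ooc") &
    !is.na(events$t_confirmed), ]
  dplyr::bind_rows(
    pair_summary("lstm_to_ma", lstm_t, ma_t),
    pair_summary("ma_to_westgard", ma_t, conf$t_confirmed)
  )
}
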