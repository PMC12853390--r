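#' Describe an injectable error regime
#'
#' @param kind `"step_shift"` (additive shift of `magnitude` target SDs),
#'   `"linear_drift"` (additive ramp of `magnitude` analyte units per
#'   sample), or `"cv_inflation"` (noise SD multiplied by `magnitude`).
#' @param onset 1-based sample index at which the error starts.
#' @param magnitude Effect size; units depend on `kind` (see above).
#' @param duration Number of affected samples; the effect is active on
#'   samples `onset, ..., onset + duration - 1` and absent afterwards.
#' @return A list of class `error_spec`.
#' @examples
#' error_spec("step_shift", onset = 250, magnitude = 1, duration = 250)
#' @export
error_spec <- function(kind = c("step_shift", "linear_drift", "cv_inflation"),
                       onset, magnitude, duration) {
  kind <- match.arg(kind)
  stopifnot(onset >= 1, duration >= 1, is.finite(magnitude))
  structure(
    list(kind = kind, onset = as.integer(onset),
         magnitude = magnitude, duration = as.integer(duration)),
    class = "error_spec"
  )
}

#' Describe a synthetic patient-stream scenario
#'
#' A scenario is the complete recipe for one simulated stationary patient
#' stream: the analyte, its sample count and arrival rate, the baseline
#' analytical+biological CV, the rates of pre-analytical flags and gross
#' outliers, and any injected error regimes. Defaults describe the PLT
#' stream the monitoring framework targets: 250 x 10^9/L with 2.8% baseline
#' CV, 20 samples/hour (so a 100-sample window spans ~5 h and lead times are
#' naturally expressed in hours), sparse flags (1% per flag type) and gross
#' outliers (0.5%).
#'
#' @param analyte An [analyte_spec()]; default the PLT spec.
#' @param n_samples Number of patient samples.
#' @param sampling_rate Samples per hour.
#' @param baseline_cv Percent CV of the in-control stream; default the
#'   spec's `target_sd / target_mean`.
#' @param flag_rate Per-sample probability of each pre-analytical flag.
#' @param outlier_rate Per-sample probability of a gross (> 3 SD) error.
#' @param errors List of [error_spec()]s.
#' @param distribution `"normal"` or `"lognormal"` baseline distribution,
#'   parameterized to the target mean and CV. Defaults to log-normal for the
#'   count-type analytes (WBC, PLT), normal otherwise.
#' @param seed Integer seed; the stream is fully reproducible from it.
#' @param start Timestamp of the first sample (POSIXct, UTC).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(analyte = default_analyte_specs("PLT"),
                          n_samples = 1000,
                          sampling_rate = 20,
                          baseline_cv = NULL,
                          flag_rate = 0.01,
                          outlier_rate = 0.005,
                          errors = list(),
                          distribution = NULL,
                          seed = 1L,
                          start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(analyte, "analyte_spec"), n_samples > 0, sampling_rate > 0)
  stopifnot(flag_rate >= 0, flag_rate <= 1, outlier_rate >= 0, outlier_rate <= 1)
  if (is.null(baseline_cv)) {
    baseline_cv <- 100 * analyte$target_sd / analyte$target_mean
  }
  if (is.null(distribution)) {
    distribution <- if (analyte$name %in% c("WBC", "PLT")) "lognormal" else "normal"
  }
  distribution <- match.arg(distribution, c("normal", "lognormal"))
  if (inherits(errors, "error_spec")) errors <- list(errors)
  for (e in errors) {
    stopifnot(inherits(e, "error_spec"))
    if (e$onset + e$duration - 1 > n_samples) {
      stop("error regime extends beyond the stream (onset + duration > n_samples)",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      analyte = analyte, n_samples = as.integer(n_samples),
      sampling_rate = sampling_rate, baseline_cv = baseline_cv,
      flag_rate = flag_rate, outlier_rate = outlier_rate,
      errors = errors, distribution = distribution,
      seed = as.integer(seed), start = start
    ),
    class = "scenario_spec"
  )
}

#' Simulate a patient result stream with ground truth
#'
#' Draws an in-control stream from the analyte's baseline distribution
#' (normal, or log-normal matched to the target mean and CV for count-type
#' analytes), stamps arrivals at the scenario's sampling rate, then injects,
#' in order: the scenario's error regimes (step shifts, linear drifts, CV
#' inflation), gross outliers at 3.5-6 SD from target, and pre-analytical
#' flags. Ground-truth labels mark which samples are affected by an injected
#' error regime (outliers and flags are labelled separately; they are
#' preprocessing fodder, not systematic error).
#'
#' @param scenario A [scenario_spec()].
#' @return List with `stream` (result tibble, see [read_results()]), and
#'   `labels`: tibble with `index`, `in_error`, `error_kind`, `is_outlier`,
#'   `is_flagged`.
#' @examples
#' sim <- simulate_patient_stream(scenario_spec(n_samples = 200, seed = 42))
#' sim$stream
#' @export
simulate_patient_stream <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  sc <- scenario
  spec <- sc$analyte
  n <- sc$n_samples
  sd_base <- sc$baseline_cv / 100 * spec$target_mean

  withr_seed <- set_local_seed(sc$seed)
  on.exit(withr_seed(), add = TRUE)

  values <- draw_baseline(n, spec$target_mean, sd_base, sc$distribution)

  in_error <- rep(FALSE, n)
  error_kind <- rep(NA_character_, n)
  for (e in sc$errors) {
    idx <- seq(e$onset, e$onset + e$duration - 1)
    if (e$kind == "step_shift") {
      values[idx] <- values[idx] + e$magnitude * spec$target_sd
    } else if (e$kind == "linear_drift") {
      values[idx] <- values[idx] + e$magnitude * seq_along(idx)
    } else { # cv_inflation
      values[idx] <- spec$target_mean +
        (values[idx] - spec$target_mean) * e$magnitude
    }
    in_error[idx] <- TRUE
    error_kind[idx] <- e$kind
  }

  is_outlier <- stats::runif(n) < sc$outlier_rate
  n_out <- sum(is_outlier)
  if (n_out > 0) {
    mag <- stats::runif(n_out, 3.5, 6) * spec$target_sd
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    values[is_outlier] <- spec$target_mean + sgn * mag
  }

  flags <- lapply(seq_len(n), function(i) {
    FLAG_LEVELS[stats::runif(length(FLAG_LEVELS)) < sc$flag_rate]
  })
  is_flagged <- vapply(flags, function(f) length(f) > 0, logical(1))

  timestamps <- sc$start + (seq_len(n) - 1) * 3600 / sc$sampling_rate

  stream <- tibble::tibble(
    timestamp = timestamps,
    center_id = "C1",
    analyte = spec$name,
    value = values,
    flags = flags,
    stream = "patient",
    qc_level = NA_character_
  )
  labels <- tibble::tibble(
    index = seq_len(n), in_error = in_error, error_kind = error_kind,
    is_outlier = is_outlier, is_flagged = is_flagged
  )
  list(stream = stream, labels = labels)
}

draw_baseline <- function(n, mean, sd, distribution) {
  if (distribution == "normal") {
    stats::rnorm(n, mean, sd)
  } else {
    cv2 <- (sd / mean)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(mean) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  }
}

# set.seed locally, restoring the caller's RNG state on exit
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Simulate an internal-QC result stream
#'
#' Draws per-run control results for each QC level around
#' `target * (1 + bias_pct/100)` with the stated CV, at a fixed run
#' interval (default twice daily). Used to exercise the Westgard tier.
#'
#' @param spec An [analyte_spec()].
#' @param levels Number of QC levels per run.
#' @param runs Number of runs.
#' @param bias_pct Percent systematic bias of the control results.
#' @param cv_pct Percent CV of the control results (> 0).
#' @param seed Integer seed.
#' @param start Timestamp of the first run (POSIXct, UTC).
#' @param interval_hours Hours between runs (default 12, i.e. twice daily).
#' @return Result tibble (stream type `"qc"`, `qc_level` `"L1"`, `"L2"`, ...).
#' @examples
#' simulate_qc_stream(default_analyte_specs("PLT"), levels = 2, runs = 3,
#'                    bias_pct = 0, cv_pct = 2.8, seed = 1)
#' @export
simulate_qc_stream <- function(spec, levels = 2, runs, bias_pct = 0, cv_pct,
                               seed = 1L,
                               start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
                               interval_hours = 12) {
  stopifnot(inherits(spec, "analyte_spec"), cv_pct > 0, levels >= 1, runs >= 1)
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  center_mean <- spec$target_mean * (1 + bias_pct / 100)
  sd_qc <- cv_pct / 100 * center_mean
  grid <- expand.grid(level = seq_len(levels), run = seq_len(runs))
  grid <- grid[order(grid$run, grid$level), ]
  tibble::tibble(
    timestamp = start + (grid$run - 1) * interval_hours * 3600,
    center_id = "C1",
    analyte = spec$name,
    value = stats::rnorm(nrow(grid), center_mean, sd_qc),
    flags = replicate(nrow(grid), character(0), simplify = FALSE),
    stream = "qc",
    qc_level = paste0("L", grid$level)
  )
}

#' Factorial benchmark suite of shift-detection scenarios
#'
#' Reconstructs, at desk scale, the window-selection experiment: a grid of
#' step-shift magnitudes crossed with fixed MA window settings, each cell
#' replicated under distinct fixed seeds. Returns the scenario objects plus
#' a manifest tibble that round-trips the grid.
#'
#' @param shift_sd Step-shift magnitudes in target-SD multiples.
#' @param windows Fixed MA window sizes to compare.
#' @param replicates Seeded replicates per cell.
#' @param n_samples Stream length per scenario.
#' @param onset Shift onset index.
#' @param analyte An [analyte_spec()].
#' @param base_seed Base of the per-cell seed arithmetic.
#' @return List with `scenarios` (named list of [scenario_spec()]s) and
#'   `manifest` (tibble: `id`, `shift_sd`, `window`, `replicate`, `seed`).
#' @export
make_benchmark_suite <- function(shift_sd = c(0.1, 0.25, 0.5, 1.0),
                                 windows = c(50, 100, 150),
                                 replicates = 3,
                                 n_samples = 1200,
                                 onset = 701,
                                 analyte = default_analyte_specs("PLT"),
                                 base_seed = 20240101L) {
  grid <- expand.grid(
    shift_sd = shift_sd, window = windows, replicate = seq_len(replicates),
    KEEP.OUT.ATTRS = FALSE
  )
  grid$seed <- (base_seed + 1000L * seq_len(nrow(grid))) %% .Machine$integer.max
  grid$id <- sprintf(
    "shift%s_w%d_r%d", format(grid$shift_sd), grid$window, grid$replicate
  )
  scenarios <- lapply(seq_len(nrow(grid)), function(i) {
    scenario_spec(
      analyte = analyte, n_samples = n_samples, seed = grid$seed[i],
      errors = list(error_spec(
        "step_shift", onset = onset, magnitude = grid$shift_sd[i],
        duration = n_samples - onset + 1
      ))
    )
  })
  names(scenarios) <- grid$id
  list(
    scenarios = scenarios,
    manifest = tibble::as_tibble(grid[c("id", "shift_sd", "window", "replicate", "seed")])
  )
}

#' Canonical drift scenario for forecaster lead-time studies
#'
#' The pinned scenario pair used to study how far ahead of the MA monitor
#' the forecaster warns. The training stream mixes upward and downward
#' linear drift episodes of varying slope (0.03-0.08 target-SD per sample)
#' and duration (40-80 samples, peaking at 2.4-3.2 SD) between in-control
#' stretches, so the model learns ramps of both signs across the deviation
#' range where the red-alert threshold lives. The test stream holds 1000
#' in-control samples (warm-up, limit calibration, history) followed by one
#' 150-sample drift episode at 0.05 SD/sample, which the MA monitor is
#' guaranteed to flag.
#'
#' The companion [canonical_drift_config()] pins the monitor semantics of
#' the lead-time study: control limits on the population-SD scale (the
#' literal "target mean +/- k SD" reading, under which MA out-of-control
#' events are rare, decisive breaches rather than sampling noise of the MA
#' statistic) and preprocessing that removes only gross extremes (6 SD).
#' Under MA-statistic-scaled limits the out-of-control threshold
#' (2.5 sigma/sqrt(W), about 0.2 SD) lies far below the red-alert threshold
#' (50% of TEa, 0.71 SD for the default PLT spec) and carries a per-sample
#' false rate near 0.5%, so a first-event comparison measures the monitor's
#' noise rather than the forecaster's anticipation; and under
#' population-scale limits a 3 SD exclusion band around target would cap
#' the accepted moving average below the 2.5 SD limit, making a breach
#' impossible. The pinned pair is the configuration under which the
#' three-tier cascade (forecast, monitor, verify) is well ordered.
#'
#' @param part `"train"` or `"test"`.
#' @param seed Integer seed (for `"test"`, vary it across replicates).
#' @param n_accepted_train Length to which the accepted training series is
#'   trimmed after preprocessing (default 5109 raw samples simulated with
#'   margin, yielding 5000 supervised windows at input 100 / horizon 10).
#' @return A [scenario_spec()].
#' @export
canonical_drift_scenario <- function(part = c("train", "test"), seed = 1L,
                                     n_accepted_train = 5109L) {
  part <- match.arg(part)
  spec <- default_analyte_specs("PLT")
  slope <- 0.05 * spec$target_sd # analyte units per sample
  if (part == "train") {
    n <- as.integer(ceiling(n_accepted_train * 1.12)) # margin for exclusions
    episodes <- tibble::tibble(
      onset = c(500L, 1100L, 1700L, 2300L, 2900L, 3500L, 4100L, 4700L),
      sign = c(1, -1, 1, -1, 1, -1, 1, -1),
      slope_sd = c(0.05, 0.05, 0.08, 0.03, 0.03, 0.08, 0.05, 0.05),
      duration = c(50L, 50L, 40L, 80L, 80L, 40L, 60L, 60L)
    )
    errs <- purrr::pmap(episodes, function(onset, sign, slope_sd, duration) {
      error_spec("linear_drift",
        onset = onset, magnitude = sign * slope_sd * spec$target_sd,
        duration = duration
      )
    })
    scenario_spec(
      analyte = spec, n_samples = n, seed = seed, errors = errs
    )
  } else {
    scenario_spec(
      analyte = spec, n_samples = 2000L, seed = seed,
      errors = list(
        error_spec("linear_drift", onset = 1001L, magnitude = slope, duration = 150L)
      )
    )
  }
}

#' @rdname canonical_drift_scenario
#' @export
canonical_drift_config <- function() {
  run_config(
    ma = list(sd_mode = "population"),
    preprocessing = list(outlier_sd = 6)
  )
}
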