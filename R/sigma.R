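#' Round half away from zero
#'
#' Reporting in laboratory QC conventionally rounds halves up (away from
#' zero), unlike [round()]'s round-half-to-even. Used everywhere a value is
#' reported "to n decimals".
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.545, 2) # 2.55, where round() gives 2.54
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Percent bias of a laboratory mean against a reference value
#'
#' Bias (%) = |(laboratory mean - reference value) / reference value| x 100.
#'
#' @param lab_mean Laboratory mean, analyte units.
#' @param reference_value Assigned peer-group (EQA median) value; must be > 0.
#' @return Absolute percent bias.
#' @examples
#' compute_bias(105, 100) # 5
#' @export
compute_bias <- function(lab_mean, reference_value) {
  if (any(!is.finite(reference_value)) || any(reference_value <= 0)) {
    stop("`reference_value` must be > 0", call. = FALSE)
  }
  abs((lab_mean - reference_value) / reference_value) * 100
}

#' Percent coefficient of variation
#'
#' CV (%) = SD / mean x 100 with the sample SD (n - 1 denominator), the
#' convention for period imprecision statistics.
#'
#' @param values Numeric vector of at least 2 measurements.
#' @return CV in percent.
#' @examples
#' compute_cv(c(98, 100, 102)) # 2
#' @export
compute_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values to compute a CV", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Sigma metric of analytical performance
#'
#' sigma = (TEa - Bias) / CV with all three terms in percent. A negative
#' sigma (bias exceeding TEa) is returned as-is with a warning; it signals an
#' assay that fails its allowable error outright.
#'
#' @param tea_pct Total allowable error, percent of target.
#' @param bias_pct Absolute percent bias.
#' @param cv_pct Percent CV; must be > 0.
#' @return The sigma metric (dimensionless).
#' @examples
#' compute_sigma(25, 5, 4) # 5
#' @export
compute_sigma <- function(tea_pct, bias_pct, cv_pct) {
  if (any(!is.finite(cv_pct)) || any(cv_pct <= 0)) {
    stop("`cv_pct` must be > 0", call. = FALSE)
  }
  sigma <- (tea_pct - bias_pct) / cv_pct
  if (any(sigma < 0)) {
    warning("bias exceeds TEa for at least one assay: sigma is negative",
      call. = FALSE
    )
  }
  sigma
}

#' Grade a sigma metric
#'
#' sigma >= 6 is world-class ("high"), 3 <= sigma < 6 acceptable
#' ("moderate"), sigma < 3 high-risk ("low"). Boundaries are inclusive on the
#' upper tier (sigma = 6 is high, sigma = 3 is moderate).
#'
#' @param sigma Numeric vector of sigma metrics.
#' @return Character vector in `c("high", "moderate", "low")`.
#' @examples
#' grade_sigma(c(6.71, 4.72, 2.55))
#' @export
grade_sigma <- function(sigma) {
  if (any(!is.finite(sigma))) stop("sigma must be finite", call. = FALSE)
  dplyr::case_when(
    sigma >= 6 ~ "high",
    sigma >= 3 ~ "moderate",
    TRUE ~ "low"
  )
}

#' Matrix correction factor from patient and control CVs
#'
#' F = CV_patient / CV_IQC compensates sigma metrics for matrix and biological
#' variability differences between control materials and patient specimens.
#'
#' @param cv_iqc Percent CV from internal QC materials (> 0).
#' @param cv_patient Percent CV from patient results (> 0).
#' @param digits Reporting precision; `NULL` returns full precision. Default 2
#'   decimals, half-up, matching laboratory reporting practice.
#' @return The correction factor F.
#' @examples
#' matrix_correction_factor(2.8, 3.5) # 1.25
#' @export
matrix_correction_factor <- function(cv_iqc, cv_patient, digits = 2) {
  if (any(!is.finite(cv_iqc)) || any(cv_iqc <= 0) ||
    any(!is.finite(cv_patient)) || any(cv_patient <= 0)) {
    stop("both CVs must be > 0", call. = FALSE)
  }
  f <- cv_patient / cv_iqc
  if (is.null(digits)) f else round_half_up(f, digits)
}

#' Matrix-corrected sigma
#'
#' Divides a sigma metric by the correction factor F (equivalently,
#' recomputes sigma with the patient-inflated CV). In `mode = "reported"` the
#' division uses F at 2-decimal reporting precision and returns the quotient
#' at 2 decimals — the convention under which published corrected values are
#' reproduced exactly. `mode = "exact"` divides at full precision.
#'
#' @param sigma Sigma metric.
#' @param factor Correction factor F (> 0).
#' @param mode `"reported"` (default) or `"exact"`.
#' @return Corrected sigma.
#' @examples
#' adjusted_sigma(3.19, matrix_correction_factor(2.8, 3.5)) # 2.55
#' @export
adjusted_sigma <- function(sigma, factor, mode = c("reported", "exact")) {
  mode <- match.arg(mode)
  if (any(!is.finite(factor)) || any(factor <= 0)) {
    stop("`factor` must be > 0", call. = FALSE)
  }
  if (mode == "reported") {
    round_half_up(sigma / round_half_up(factor, 2), 2)
  } else {
    sigma / factor
  }
}

#' Mean sigma across centers, with its grade
#'
#' @param sigmas Numeric vector of per-center sigma metrics (>= 1 value).
#' @param digits Reporting precision of the mean (default 2, half-up).
#' @return One-row tibble with `mean_sigma` and `grade`.
#' @examples
#' summarize_centers(c(6.72, 6.91, 6.55, 6.33, 7.05, 6.68)) # 6.71, high
#' @export
summarize_centers <- function(sigmas, digits = 2) {
  sigmas <- sigmas[is.finite(sigmas)]
  if (length(sigmas) == 0) stop("need at least one sigma value", call. = FALSE)
  m <- round_half_up(mean(sigmas), digits)
  tibble::tibble(mean_sigma = m, grade = grade_sigma(m))
}

#' Sigma performance assessment from per-center QC summaries
#'
#' Data-frame-first entry point for the sigma engine. Takes one row per
#' analyte x center with the period mean and SD of the QC material, the
#' reference value and TEa (percent of target), and optionally the patient
#' CV, and returns the full assessment: bias, CV, sigma, grade, and — when a
#' patient CV is supplied — the matrix correction factor and corrected sigma.
#'
#' @param data Tibble with columns `analyte`, `center_id`, `mean`, `sd`,
#'   `reference_value`, `tea_pct`, and optionally `cv_patient_pct`.
#' @param mode Correction reporting mode passed to [adjusted_sigma()].
#' @return Tibble with one row per input row plus `bias_pct`, `cv_pct`,
#'   `sigma`, `grade`, `correction_factor`, `sigma_adjusted`,
#'   `grade_adjusted`.
#' @examples
#' qc <- tibble::tibble(
#'   analyte = "PLT", center_id = "A", mean = 251, sd = 7.03,
#'   reference_value = 250, tea_pct = 25, cv_patient_pct = 3.5
#' )
#' assess_performance(qc)
#' @export
assess_performance <- function(data, mode = c("reported", "exact")) {
  mode <- match.arg(mode)
  need <- c("analyte", "center_id", "mean", "sd", "reference_value", "tea_pct")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data |>
    dplyr::mutate(
      bias_pct = compute_bias(.data$mean, .data$reference_value),
      cv_pct = 100 * .data$sd / .data$mean,
      sigma = compute_sigma(.data$tea_pct, .data$bias_pct, .data$cv_pct),
      grade = grade_sigma(.data$sigma)
    )
  if ("cv_patient_pct" %in% names(out)) {
    ok <- !is.na(out$cv_patient_pct)
    f <- s_adj <- rep(NA_real_, nrow(out))
    g_adj <- rep(NA_character_, nrow(out))
    if (any(ok)) {
      f[ok] <- matrix_correction_factor(out$cv_pct[ok], out$cv_patient_pct[ok])
      s_adj[ok] <- adjusted_sigma(out$sigma[ok], f[ok], mode = mode)
      g_adj[ok] <- grade_sigma(s_adj[ok])
    }
    out$correction_factor <- f
    out$sigma_adjusted <- s_adj
    out$grade_adjusted <- g_adj
  } else {
    out$correction_factor <- NA_real_
    out$sigma_adjusted <- NA_real_
    out$grade_adjusted <- NA_character_
  }
  out
}

#' Sigma-stratified QC plan
#'
#' Maps graded sigma performance onto the differentiated QC plan: high
#' (sigma >= 6) runs QC once daily under a single 1-2s rule; moderate
#' (3 <= sigma < 6) runs QC per analytical batch under a multirule set
#' (1-2s + R-4s); low (sigma < 3) runs QC every 4 hours under a dual
#' rejection rule set (1-3s + 2-2s) with MA-based patient monitoring
#' enabled. When a matrix-corrected sigma is available it overrides the raw
#' sigma for tiering.
#'
#' @param assessment Tibble as returned by [assess_performance()] (columns
#'   `analyte`, `sigma`, optionally `sigma_adjusted`), or a bare numeric
#'   vector of sigma values.
#' @return Tibble with one row per assessment row: `analyte`, `sigma_used`,
#'   `tier`, `qc_frequency`, `rules` (list-column), `ma_enabled`.
#' @examples
#' stratify_plan(c(6.71, 4.72, 2.55))
#' @export
stratify_plan <- function(assessment) {
  if (is.numeric(assessment)) {
    assessment <- tibble::tibble(
      analyte = paste0("analyte", seq_along(assessment)),
      sigma = assessment
    )
  }
  sigma_used <- if ("sigma_adjusted" %in% names(assessment)) {
    dplyr::coalesce(assessment$sigma_adjusted, assessment$sigma)
  } else {
    assessment$sigma
  }
  tier <- grade_sigma(sigma_used)
  rules <- lapply(tier, function(t) {
    switch(t,
      high = "1-2s",
      moderate = c("1-2s", "R-4s"),
      low = c("1-3s", "2-2s")
    )
  })
  tibble::tibble(
    analyte = assessment$analyte,
    sigma_used = sigma_used,
    tier = tier,
    qc_frequency = dplyr::case_when(
      tier == "high" ~ "once_daily",
      tier == "moderate" ~ "per_batch",
      TRUE ~ "every_4h"
    ),
    rules = rules,
    ma_enabled = tier == "low"
  )
}
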