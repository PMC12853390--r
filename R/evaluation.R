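#' Diagnostic metrics from an alert-verification table
#'
#' Operates on the tallies produced by verifying alerts against the
#' reference mechanism: of `n_alerts` raised, `n_confirmed` proved truly
#' out of control; of `n_nonalerts` quiet periods audited,
#' `n_verified_normal` proved genuinely normal. Under these verification
#' denominators sensitivity coincides with PPV (`confirmed / alerts`) and
#' specificity with NPV (`verified normal / non-alerts`); that is the
#' convention in which published alert-verification tables are reported,
#' and [confusion_metrics()] provides the standard TP/FP/TN/FN definitions
#' alongside.
#'
#' @param n_alerts,n_confirmed Alerts raised and alerts confirmed
#'   out-of-control (`n_confirmed <= n_alerts`).
#' @param n_nonalerts,n_verified_normal Audited non-alert periods and those
#'   verified normal (`n_verified_normal <= n_nonalerts`).
#' @param digits Reporting precision in percent (default 1, half-up);
#'   `NULL` for full precision.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`, in
#'   percent.
#' @examples
#' alert_verification_metrics(69, 57, 104, 96) # 82.6 / 92.3
#' @export
alert_verification_metrics <- function(n_alerts, n_confirmed,
                                       n_nonalerts, n_verified_normal,
                                       digits = 1) {
  if (n_alerts <= 0 || n_nonalerts <= 0) {
    stop("denominators must be positive", call. = FALSE)
  }
  if (n_confirmed > n_alerts || n_verified_normal > n_nonalerts) {
    stop("confirmed counts cannot exceed their denominators", call. = FALSE)
  }
  pos <- 100 * n_confirmed / n_alerts
  neg <- 100 * n_verified_normal / n_nonalerts
  if (!is.null(digits)) {
    pos <- round_half_up(pos, digits)
    neg <- round_half_up(neg, digits)
  }
  tibble::tibble(sensitivity = pos, specificity = neg, ppv = pos, npv = neg)
}

#' Diagnostic metrics from a standard confusion matrix
#'
#' @param tp,fp,tn,fn True/false positives and negatives.
#' @param digits Reporting precision in percent (default 1); `NULL` for
#'   full precision.
#' @return One-row tibble: `sensitivity` (= tp/(tp+fn)), `specificity`
#'   (= tn/(tn+fp)), `ppv` (= tp/(tp+fp)), `npv` (= tn/(tn+fn)), percent.
#' @export
confusion_metrics <- function(tp, fp, tn, fn, digits = 1) {
  rat <- function(num, den) {
    if (den <= 0) stop("zero denominator in confusion matrix", call. = FALSE)
    v <- 100 * num / den
    if (is.null(digits)) v else round_half_up(v, digits)
  }
  tibble::tibble(
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn)
  )
}

#' Detection sensitivity of one mechanism against a shared event pool
#'
#' When several trigger mechanisms are compared against the same pool of
#' confirmed out-of-control events, each mechanism's sensitivity is the
#' fraction of the pool it detected. The denominator is passed explicitly
#' because comparative tables may use different pools per row.
#'
#' @param detected_true Confirmed events the mechanism detected.
#' @param total_true Total confirmed events in the pool (> 0).
#' @param digits Reporting precision (default 1); `NULL` for full precision.
#' @return Sensitivity in percent.
#' @examples
#' cross_mechanism_sensitivity(39, 57) # 68.4
#' @export
cross_mechanism_sensitivity <- function(detected_true, total_true, digits = 1) {
  if (total_true <= 0) stop("`total_true` must be > 0", call. = FALSE)
  if (detected_true > total_true) {
    stop("`detected_true` cannot exceed `total_true`", call. = FALSE)
  }
  v <- 100 * detected_true / total_true
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' kappa = (p_o - p_e) / (1 - p_e) with the asymptotic standard-error CI.
#' Agreement bands: kappa > 0.75 strong, 0.40-0.75 moderate, < 0.40 poor.
#'
#' @param table 2x2 numeric matrix (or a tibble/data.frame coercible to
#'   one): rows one rater/occasion, columns the other, diagonal =
#'   agreement.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return One-row tibble: `kappa`, `conf_low`, `conf_high`, `p_observed`,
#'   `p_expected`, `band`.
#' @examples
#' cohens_kappa(matrix(c(40, 5, 10, 45), 2)) # kappa 0.70, moderate
#' @export
cohens_kappa <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0)) {
    stop("`table` must be a nonnegative 2x2 matrix", call. = FALSE)
  }
  n <- sum(m)
  if (n <= 0) stop("table total must be > 0", call. = FALSE)
  p_o <- sum(diag(m)) / n
  row_p <- rowSums(m) / n
  col_p <- colSums(m) / n
  p_e <- sum(row_p * col_p)
  if (abs(1 - p_e) < 1e-12) {
    stop("degenerate marginals: expected agreement is 1, kappa undefined",
      call. = FALSE
    )
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  band <- if (kappa > 0.75) "strong" else if (kappa >= 0.40) "moderate" else "poor"
  tibble::tibble(
    kappa = kappa,
    conf_low = kappa - zq * se, conf_high = kappa + zq * se,
    p_observed = p_o, p_expected = p_e, band = band
  )
}

#' Relative change between a pre and a post value
#'
#' 100 x (post - pre) / pre, reported to 1 decimal by default.
#'
#' @param pre Baseline value (nonzero).
#' @param post Follow-up value.
#' @param digits Reporting precision (default 1); `NULL` for full precision.
#' @return Signed percent change.
#' @examples
#' relative_change(3.9, 1.8) # -53.8
#' @export
relative_change <- function(pre, post, digits = 1) {
  if (any(pre == 0)) stop("`pre` must be nonzero", call. = FALSE)
  v <- 100 * (post - pre) / pre
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Classify pre/post indicator changes as improved or not
#'
#' Applies the improvement criteria used to judge a QC-strategy rollout:
#' a bias detection rate counts as improved when it rises by at least 2
#' percentage points, a response time when it falls by at least 1 hour, and
#' an intervention rate when it rises by at least 10 percentage points.
#' Rate thresholds are percentage-point differences, not relative changes.
#'
#' @param data Tibble with columns `indicator`, `pre`, `post`. Recognized
#'   indicators: `"bias_detection_rate"` (pp), `"response_time_h"` (hours),
#'   `"intervention_rate"` (pp). Unknown indicators error.
#' @return Input with `delta`, `threshold`, `direction`, and `improved`
#'   columns appended.
#' @examples
#' improvement_classification(tibble::tibble(
#'   indicator = c("bias_detection_rate", "response_time_h"),
#'   pre = c(14.2, 3.9), post = c(17.7, 1.8)
#' ))
#' @export
improvement_classification <- function(data) {
  rules <- tibble::tibble(
    indicator = c("bias_detection_rate", "response_time_h", "intervention_rate"),
    threshold = c(2, 1, 10),
    direction = c("increase", "decrease", "increase")
  )
  unknown <- setdiff(data$indicator, rules$indicator)
  if (length(unknown)) {
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::left_join(rules, by = "indicator") |>
    dplyr::mutate(
      delta = .data$post - .data$pre,
      improved = ifelse(.data$direction == "increase",
        .data$delta >= .data$threshold,
        -.data$delta >= .data$threshold
      )
    )
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC of a score against binary labels, with midranks for
#' ties: the probability that a randomly chosen positive scores above a
#' randomly chosen negative, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return The AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
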