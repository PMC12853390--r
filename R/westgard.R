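#' Evaluate Westgard multirules on a z-scored control series
#'
#' Applies the classic multirule criteria to an ordered series of control
#' observations expressed as signed deviations from target in SD units.
#' Supported rules and their semantics (evaluated at every index, so a
#' violation is reported at each point that completes it):
#'
#' * `1-2s` — |z| > 2 (warning in a multirule cascade; see below);
#' * `1-3s` — |z| > 3;
#' * `2-2s` — two consecutive observations on the same side with |z| > 2;
#' * `R-4s` — within one run, the range of z exceeds 4 (reported at the
#'   observation that first completes the range);
#' * `4-1s` — four consecutive observations beyond 1 SD on the same side;
#' * `10x` — ten consecutive observations on the same side of target.
#'
#' Consecutive-count rules (`2-2s`, `4-1s`, `10x`) are evaluated across runs
#' in sequence order; `R-4s` is evaluated within run only. `1-2s` is a
#' warning when it is part of a multirule set, but when it is the only
#' configured rule (the once-daily plan for world-class assays) it is the
#' sole failure criterion and is treated as a rejection when
#' `sole_rule_rejects` is `TRUE`.
#'
#' @param points Tibble with column `z` (finite, signed SD deviations) and
#'   optional `run_id` (defaults to a single run), `level`, `timestamp`
#'   (defaults to the index). Rows must be in time order.
#' @param rules Character vector of enabled rule names.
#' @param sole_rule_rejects Logical; see above. Default `TRUE`.
#' @return Tibble of violations, earliest first: `rule`, `index`,
#'   `timestamp`, `severity` (`"warning"` or `"rejection"`).
#' @examples
#' pts <- tibble::tibble(z = c(1.0, 2.2, 2.4))
#' evaluate_westgard(pts, c("1-2s", "2-2s"))
#' @export
evaluate_westgard <- function(points,
                              rules = c("1-2s", "1-3s", "2-2s", "R-4s", "4-1s", "10x"),
                              sole_rule_rejects = TRUE) {
  known <- c("1-2s", "1-3s", "2-2s", "R-4s", "4-1s", "10x")
  bad <- setdiff(rules, known)
  if (length(bad)) {
    stop("unknown Westgard rule(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.numeric(points)) points <- tibble::tibble(z = points)
  z <- points$z
  n <- length(z)
  if (n == 0) {
    return(empty_violations())
  }
  if (any(!is.finite(z))) stop("control z-scores must be finite", call. = FALSE)
  run_id <- if ("run_id" %in% names(points)) as.character(points$run_id) else rep("run1", n)
  timestamp <- if ("timestamp" %in% names(points)) points$timestamp else seq_len(n)

  hits <- list()
  add <- function(rule, idx) {
    if (length(idx)) {
      hits[[length(hits) + 1]] <<- tibble::tibble(rule = rule, index = idx)
    }
  }

  side <- sign(z)
  if ("1-2s" %in% rules) add("1-2s", which(abs(z) > 2))
  if ("1-3s" %in% rules) add("1-3s", which(abs(z) > 3))
  if ("2-2s" %in% rules && n >= 2) {
    i <- 2:n
    add("2-2s", i[abs(z[i]) > 2 & abs(z[i - 1]) > 2 & side[i] == side[i - 1] & side[i] != 0])
  }
  if ("4-1s" %in% rules && n >= 4) {
    idx <- which(vapply(4:n, function(i) {
      w <- z[(i - 3):i]
      all(w > 1) || all(w < -1)
    }, logical(1)))
    add("4-1s", idx + 3L)
  }
  if ("10x" %in% rules && n >= 10) {
    idx <- which(vapply(10:n, function(i) {
      w <- side[(i - 9):i]
      all(w == 1) || all(w == -1)
    }, logical(1)))
    add("10x", idx + 9L)
  }
  if ("R-4s" %in% rules) {
    for (r in unique(run_id)) {
      pos <- which(run_id == r)
      zr <- z[pos]
      if (length(zr) >= 2) {
        rng <- cummax(zr) - cummin(zr)
        over <- rng > 4
        first <- which(over & !dplyr::lag(over, default = FALSE))
        add("R-4s", pos[first])
      }
    }
  }

  if (length(hits) == 0) {
    return(empty_violations())
  }
  out <- dplyr::bind_rows(hits)
  sole_12s <- identical(sort(unique(rules)), "1-2s") && sole_rule_rejects
  out$severity <- ifelse(out$rule == "1-2s" & !sole_12s, "warning", "rejection")
  out$timestamp <- timestamp[out$index]
  out <- dplyr::arrange(out, .data$index, .data$rule)
  out[c("rule", "index", "timestamp", "severity")]
}

empty_violations <- function() {
  tibble::tibble(
    rule = character(0), index = integer(0),
    timestamp = numeric(0), severity = character(0)
  )
}

#' First rejection-severity Westgard violation
#'
#' @inheritParams evaluate_westgard
#' @return One-row tibble (`rule`, `index`, `timestamp`) of the earliest
#'   rejection, or a zero-row tibble when the series never rejects.
#' @examples
#' first_rejection(tibble::tibble(z = c(1.0, 2.2, 2.4)), c("1-2s", "2-2s"))
#' @export
first_rejection <- function(points,
                            rules = c("1-2s", "1-3s", "2-2s", "R-4s", "4-1s", "10x"),
                            sole_rule_rejects = TRUE) {
  v <- evaluate_westgard(points, rules, sole_rule_rejects)
  v <- v[v$severity == "rejection", c("rule", "index", "timestamp")]
  if (nrow(v) == 0) {
    return(v)
  }
  v[1, ]
}
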