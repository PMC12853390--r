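# Independent brute-force oracles used by the property tests. These stay
# deliberately naive (direct definition, no shared code with the package
# internals they check).

# every-rule-at-every-index Westgard check
oracle_westgard <- function(z, run_id = rep("run1", length(z)), rules) {
  hits <- list()
  n <- length(z)
  for (i in seq_len(n)) {
    if ("1-2s" %in% rules && abs(z[i]) > 2) {
      hits[[length(hits) + 1]] <- list(rule = "1-2s", index = i)
    }
    if ("1-3s" %in% rules && abs(z[i]) > 3) {
      hits[[length(hits) + 1]] <- list(rule = "1-3s", index = i)
    }
    if ("2-2s" %in% rules && i >= 2) {
      if (z[i] > 2 && z[i - 1] > 2 || z[i] < -2 && z[i - 1] < -2) {
        hits[[length(hits) + 1]] <- list(rule = "2-2s", index = i)
      }
    }
    if ("4-1s" %in% rules && i >= 4) {
      w <- z[(i - 3):i]
      if (all(w > 1) || all(w < -1)) {
        hits[[length(hits) + 1]] <- list(rule = "4-1s", index = i)
      }
    }
    if ("10x" %in% rules && i >= 10) {
      w <- z[(i - 9):i]
      if (all(w > 0) || all(w < 0)) {
        hits[[length(hits) + 1]] <- list(rule = "10x", index = i)
      }
    }
    if ("R-4s" %in% rules) {
      same <- which(run_id == run_id[i] & seq_len(n) <= i)
      if (length(same) >= 2) {
        now <- max(z[same]) - min(z[same]) > 4
        before <- max(z[setdiff(same, i)]) - min(z[setdiff(same, i)]) > 4
        if (now && !before) {
          hits[[length(hits) + 1]] <- list(rule = "R-4s", index = i)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(rule = character(0), index = integer(0)))
  }
  out <- do.call(rbind, lapply(hits, as.data.frame))
  out[order(out$index, out$rule), ]
}

# brute-force kappa from first principles
oracle_kappa <- function(m) {
  n <- sum(m)
  p_o <- (m[1, 1] + m[2, 2]) / n
  p_e <- (sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])) / n^2
  (p_o - p_e) / (1 - p_e)
}

# pairwise-concordance AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# a tiny in-control PLT stream helper
plt_spec <- function() default_analyte_specs("PLT")
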