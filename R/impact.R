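#' Classify a trough concentration against the therapeutic range
#'
#' The clinical target for adalimumab troughs in inflammatory bowel
#' disease is 8-12 mg/L (mucosal healing / endoscopic remission range).
#' The "within" interval is closed on both boundaries.
#'
#' @param c Concentration(s), mg/L, >= 0.
#' @param low,high Range bounds (default 8 and 12 mg/L).
#' @return Factor with levels `below`, `within`, `above`.
#' @export
classify_range <- function(c, low = 8, high = 12) {
  if (any(c < 0)) stop("validation error: concentrations must be >= 0",
                       call. = FALSE)
  factor(ifelse(c < low, "below", ifelse(c <= high, "within", "above")),
         levels = c("below", "within", "above"))
}

#' True/false-positive table of range predictions
#'
#' Treats the observed last trough as the reference: for each range,
#' true positives are subjects whose observation and prediction both
#' fall in the range, false positives those predicted in the range but
#' observed elsewhere. `tp + fp` of a range equals the number of
#' predictions in it; `obs_n` sums to the number of subjects.
#'
#' @param pairs Prediction pairs (`y_obs`, `y_pred`), as from
#'   [leave_last_out()].
#' @param low,high Therapeutic range (default 8-12 mg/L).
#' @return Data frame of class `pk_impact` with one row per range:
#'   `range`, `obs_n`, `tp`, `fp`.
#' @export
impact_table <- function(pairs, low = 8, high = 12) {
  .check_pairs(pairs)
  obs <- classify_range(pairs$y_obs, low, high)
  pred <- classify_range(pairs$y_pred, low, high)
  out <- data.frame(
    range = levels(obs),
    obs_n = as.vector(table(obs)),
    tp = vapply(levels(obs), function(r) sum(obs == r & pred == r),
                numeric(1)),
    fp = vapply(levels(obs), function(r) sum(obs != r & pred == r),
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pk_impact", "data.frame")
  out
}

#' Bootstrap confidence intervals for the clinical-impact table
#'
#' Resamples subjects with replacement and recomputes the
#' true/false-positive table per replicate. Reports the raw integer
#' counts alongside bootstrap means and percentile 95% intervals
#' (published impact tables report the bootstrap means, which is why
#' they need not be integers). When a second model's pairs are given,
#' paired differences (`model1 - model2`) per cell get their own
#' intervals.
#'
#' @param pairs Prediction pairs for the model of interest.
#' @param pairs2 Optional pairs for a comparator model on the same
#'   subjects in the same order.
#' @param n_reps Bootstrap replicates (default 500).
#' @param seed Integer seed (mandatory).
#' @param low,high Therapeutic range (default 8-12 mg/L).
#' @return Object of class `pk_impact_boot`: `table` (per range: raw
#'   counts, bootstrap means, 95% CIs), `differences` (or `NULL`),
#'   `n_reps`, `seed`.
#' @export
bootstrap_impact <- function(pairs, pairs2 = NULL, n_reps = 500L, seed,
                             low = 8, high = 12) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  .check_pairs(pairs)
  if (!is.null(pairs2)) {
    .check_pairs(pairs2)
    if (nrow(pairs2) != nrow(pairs)) {
      stop("validation error: models must share the same subjects",
           call. = FALSE)
    }
  }
  set.seed(seed)
  n <- nrow(pairs)
  idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), n, n_reps)
  cell <- function(p, i) {
    tb <- impact_table(p[i, , drop = FALSE], low, high)
    c(tb$tp, tb$fp)
  }
  ranges <- c("below", "within", "above")
  reps1 <- t(vapply(seq_len(n_reps), function(r) cell(pairs, idx[, r]),
                    numeric(6)))
  colnames(reps1) <- c(paste0("tp_", ranges), paste0("fp_", ranges))
  point <- impact_table(pairs, low, high)
  ci <- apply(reps1, 2, stats::quantile, c(0.025, 0.975))
  tab <- data.frame(
    range = ranges, obs_n = point$obs_n, tp = point$tp, fp = point$fp,
    tp_boot = colMeans(reps1)[1:3], tp_lo = ci[1, 1:3], tp_hi = ci[2, 1:3],
    fp_boot = colMeans(reps1)[4:6], fp_lo = ci[1, 4:6], fp_hi = ci[2, 4:6],
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  differences <- NULL
  if (!is.null(pairs2)) {
    reps2 <- t(vapply(seq_len(n_reps), function(r) cell(pairs2, idx[, r]),
                      numeric(6)))
    d <- reps1 - reps2
    dci <- apply(d, 2, stats::quantile, c(0.025, 0.975))
    differences <- data.frame(
      range = ranges,
      tp_diff = colMeans(d)[1:3], tp_lo = dci[1, 1:3], tp_hi = dci[2, 1:3],
      fp_diff = colMeans(d)[4:6], fp_lo = dci[1, 4:6], fp_hi = dci[2, 4:6],
      stringsAsFactors = FALSE)
    rownames(differences) <- NULL
  }
  structure(list(table = tab, differences = differences,
                 n_reps = n_reps, seed = seed),
            class = "pk_impact_boot")
}

#' @export
print.pk_impact_boot <- function(x, ...) {
  cat("Clinical impact vs 8-12 mg/L target (bootstrap, n =",
      x$n_reps, "replicates)\n")
  print(x$table, digits = 3, row.names = FALSE)
  if (!is.null(x$differences)) {
    cat("Between-model differences:\n")
    print(x$differences, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
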