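#' Leave-last-observation-out individual predictions
#'
#' For every subject, re-estimates the empirical Bayes random effects
#' using only the non-held-out observations (the population parameters
#' stay fixed at the fitted values) and predicts the held-out last
#' trough. This mimics prospective model-informed dosing: the model sees
#' a patient's history and forecasts the next measured trough.
#'
#' @param cohort A [pk_cohort] processed by [hold_out_last()]; defaults
#'   to the fitted cohort.
#' @param fit A `pkfit` (or a bare [pk_pop_params] to evaluate a
#'   literature model without refitting).
#' @return Data frame with one row per subject: `id`, `time` (h of the
#'   held-out trough), `y_obs`, `y_pred` (mg/L). Subjects whose
#'   empirical Bayes solve fails are excluded with a warning.
#' @export
leave_last_out <- function(cohort, fit) {
  pop <- if (inherits(fit, "pkfit")) fit$estimates else fit
  stopifnot(inherits(pop, "pk_pop_params"))
  if (is.null(cohort) && inherits(fit, "pkfit")) cohort <- fit$cohort
  stopifnot(inherits(cohort, "pk_cohort"))
  if (is.null(cohort$data$HELD) || !any(cohort$data$HELD)) {
    stop("validation error: cohort has no held-out observations; run ",
         "hold_out_last() first", call. = FALSE)
  }
  subjects <- cohort_subjects(cohort)
  flat <- .flatten_cohort(cohort, use_held_out = FALSE)
  cl_typ <- .typical_cl(flat, pop)
  sol <- .ebe_solve(flat, pop, cl_typ)
  bad <- !sol$converged
  if (any(bad)) {
    warning(sum(bad), " subject(s) excluded: empirical Bayes solve did ",
            "not converge (", paste(flat$ids[bad], collapse = ", "), ")",
            call. = FALSE)
  }
  out <- lapply(which(!bad), function(i) {
    s <- subjects[[flat$ids[i]]]
    held <- s$obs[s$obs$held_out, , drop = FALSE]
    p <- .indiv_params_ext(pop, sol$eta[i, ], s)
    data.frame(id = s$id, time = held$time, y_obs = held$dv,
               y_pred = conc_profile(held$time, s$doses, p$cl, p$v, p$ka),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("y_obs", "y_pred") %in% names(pairs))) {
    stop("pairs must be a data frame with y_obs and y_pred columns",
         call. = FALSE)
  }
  if (nrow(pairs) == 0L) {
    stop("validation error: no prediction pairs", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bias and imprecision of individual predictions
#'
#' `mpe()` is the mean prediction error (bias),
#' \eqn{\mathrm{MPE} = \sum(\hat Y - Y)/n}; `rmspe()` the root mean
#' square prediction error (imprecision),
#' \eqn{\mathrm{RMSPE} = \sqrt{\sum(\hat Y - Y)^2/n}}, both in mg/L.
#'
#' @param pairs Data frame with columns `y_obs` and `y_pred` (one row
#'   per subject), as from [leave_last_out()].
#' @return Scalar (mg/L).
#' @export
mpe <- function(pairs) {
  .check_pairs(pairs)
  mean(pairs$y_pred - pairs$y_obs)
}

#' @rdname mpe
#' @export
rmspe <- function(pairs) {
  .check_pairs(pairs)
  sqrt(mean((pairs$y_pred - pairs$y_obs)^2))
}

#' Bootstrap comparison of predictive performance between models
#'
#' Resamples subjects with replacement, recomputes bias (MPE) and
#' imprecision (RMSPE) for each model on every replicate, and reports
#' percentile 95% intervals - for each model and, when several models
#' are given, for all pairwise differences. A difference interval that
#' excludes zero flags a statistically significant difference.
#'
#' @param pairs A prediction-pair data frame, or a named list of them
#'   (one per model) computed on the same subjects in the same order.
#' @param n_reps Bootstrap replicates (default 500).
#' @param seed Integer seed (mandatory).
#' @return Object of class `pk_performance`: `models` (per-model point
#'   estimates, bootstrap means and CIs), `differences` (pairwise, or
#'   `NULL`), `n_reps`, `seed`.
#' @export
bootstrap_performance <- function(pairs, n_reps = 500L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.data.frame(pairs)) pairs <- list(model = pairs)
  lapply(pairs, .check_pairs)
  n <- nrow(pairs[[1]])
  if (any(vapply(pairs, nrow, integer(1)) != n)) {
    stop("validation error: models must share the same subjects",
         call. = FALSE)
  }
  if (n < 2L) {
    stop("validation error: at least 2 subjects required", call. = FALSE)
  }
  if (is.null(names(pairs))) {
    names(pairs) <- paste0("model", seq_along(pairs))
  }
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), n, n_reps)
  m <- length(pairs)
  mpe_rep <- rmspe_rep <- array(NA_real_, c(n_reps, m),
                                dimnames = list(NULL, names(pairs)))
  for (r in seq_len(n_reps)) {
    for (j in seq_len(m)) {
      pj <- pairs[[j]][idx[, r], , drop = FALSE]
      mpe_rep[r, j] <- mpe(pj)
      rmspe_rep[r, j] <- rmspe(pj)
    }
  }
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  models <- do.call(rbind, lapply(seq_len(m), function(j) {
    data.frame(model = names(pairs)[j],
               mpe = mpe(pairs[[j]]), rmspe = rmspe(pairs[[j]]),
               mpe_boot = mean(mpe_rep[, j]),
               mpe_lo = ci(mpe_rep[, j])[1], mpe_hi = ci(mpe_rep[, j])[2],
               rmspe_boot = mean(rmspe_rep[, j]),
               rmspe_lo = ci(rmspe_rep[, j])[1],
               rmspe_hi = ci(rmspe_rep[, j])[2],
               stringsAsFactors = FALSE)
  }))
  differences <- NULL
  if (m >= 2L) {
    combs <- utils::combn(m, 2)
    differences <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      a <- combs[1, k]; b <- combs[2, k]
      dm <- mpe_rep[, a] - mpe_rep[, b]
      dr <- rmspe_rep[, a] - rmspe_rep[, b]
      data.frame(comparison = paste(names(pairs)[a], "-", names(pairs)[b]),
                 mpe_diff = mean(dm), mpe_lo = ci(dm)[1], mpe_hi = ci(dm)[2],
                 mpe_significant = ci(dm)[1] > 0 | ci(dm)[2] < 0,
                 rmspe_diff = mean(dr), rmspe_lo = ci(dr)[1],
                 rmspe_hi = ci(dr)[2],
                 rmspe_significant = ci(dr)[1] > 0 | ci(dr)[2] < 0,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(models = models, differences = differences,
                 n_reps = n_reps, seed = seed),
            class = "pk_performance")
}

#' @export
print.pk_performance <- function(x, ...) {
  cat("Predictive performance (bootstrap, n =", x$n_reps, "replicates)\n")
  print(x$models, digits = 3, row.names = FALSE)
  if (!is.null(x$differences)) {
    cat("Pairwise differences:\n")
    print(x$differences, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

## shared simulation setup for the predictive checks
.check_setup <- function(cohort, pop, include_induction, maintenance_start = 672) {
  flat <- .flatten_cohort(cohort, use_held_out = TRUE)
  keep <- rep(TRUE, length(flat$y))
  if (!include_induction) keep <- flat$obs_time >= maintenance_start
  ## population predictions (eta = 0) and time after previous dose
  cl_typ <- .typical_cl(flat, pop)
  pred <- .conc_all(flat, cl_typ, rep(pop$v_pop, flat$n), pop$ka_pop)
  tapd <- rep(NA_real_, length(flat$y))
  if (length(flat$pair_obs)) {
    mins <- tapply(flat$pair_tau, flat$pair_obs, min)
    tapd[as.integer(names(mins))] <- mins
  }
  list(flat = flat, keep = keep, pred = pred, tapd = tapd)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model simulations are rescaled by the ratio of the
#' bin-median population prediction to each point's own population
#' prediction (multiplicative correction, appropriate for a
#' proportional-error model), removing the variability injected by
#' covariates and uneven dose histories. Observed 5th/50th/95th
#' percentiles per bin are then compared with 95% confidence bands for
#' the same percentiles obtained from `n_sim` simulated replicates of
#' the cohort at its own design points.
#'
#' @param cohort A [pk_cohort].
#' @param pop A [pk_pop_params] (or `pkfit`, whose estimates are used).
#' @param n_sim Simulated cohort replicates (default 500).
#' @param bins Number of quantile bins on time-after-previous-dose
#'   (default 4).
#' @param seed Integer seed (mandatory).
#' @param include_induction Include induction-phase observations
#'   (default `TRUE`).
#' @return Object of class `pk_vpc`: a per-bin table of observed
#'   percentiles with simulated 95% bands, plus the corrected
#'   observations in `attr(, "points")`.
#' @export
pcvpc <- function(cohort, pop, n_sim = 500L, bins = 4L, seed,
                  include_induction = TRUE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (inherits(pop, "pkfit")) pop <- pop$estimates
  stopifnot(inherits(cohort, "pk_cohort"), inherits(pop, "pk_pop_params"))
  set.seed(seed)
  su <- .check_setup(cohort, pop, include_induction)
  keep <- su$keep & su$pred > 0
  if (any(su$keep & su$pred <= 0)) {
    warning(sum(su$keep & su$pred <= 0),
            " observation(s) with zero population prediction excluded",
            call. = FALSE)
  }
  y <- su$flat$y[keep]; pred <- su$pred[keep]; tapd <- su$tapd[keep]
  if (length(y) == 0L) stop("no usable observations", call. = FALSE)
  brk <- unique(stats::quantile(tapd, probs = seq(0, 1, length.out = bins + 1)))
  if (length(brk) < 2L) brk <- range(tapd) + c(-1, 1)
  bin <- cut(tapd, brk, include.lowest = TRUE)
  med_bin <- tapply(pred, bin, stats::median)
  corr <- as.vector(med_bin[bin]) / pred
  pcy <- y * corr
  sims <- .sim_matrix(su$flat, pop, n_sim)[keep, , drop = FALSE] * corr
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(levels(bin), function(b) {
    stats::quantile(pcy[bin == b], probs, names = FALSE)
  }, numeric(3)))
  sim_pct <- array(NA_real_, c(nlevels(bin), 3, n_sim))
  for (r in seq_len(n_sim)) {
    sim_pct[, , r] <- t(vapply(levels(bin), function(b) {
      stats::quantile(sims[bin == b, r], probs, names = FALSE)
    }, numeric(3)))
  }
  lo <- apply(sim_pct, c(1, 2), stats::quantile, 0.025)
  hi <- apply(sim_pct, c(1, 2), stats::quantile, 0.975)
  out <- data.frame(bin = levels(bin),
                    t_mid = as.vector(tapply(tapd, bin, stats::median)),
                    n = as.vector(table(bin)),
                    obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2],
                    obs_p95 = obs_pct[, 3],
                    p5_lo = lo[, 1], p5_hi = hi[, 1],
                    p50_lo = lo[, 2], p50_hi = hi[, 2],
                    p95_lo = lo[, 3], p95_hi = hi[, 3],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "points") <- data.frame(tapd = tapd, pcy = pcy, bin = bin)
  class(out) <- c("pk_vpc", "data.frame")
  out
}

#' @export
plot.pk_vpc <- function(x, ...) {
  pts <- attr(x, "points")
  graphics::plot(pts$tapd, pts$pcy, pch = 16, col = "grey60",
                 xlab = "Time after previous dose (h)",
                 ylab = "Prediction-corrected concentration (mg/L)", ...)
  for (i in seq_len(nrow(x))) {
    graphics::segments(x$t_mid[i], x$p50_lo[i], x$t_mid[i], x$p50_hi[i],
                       col = "pink", lwd = 8)
  }
  graphics::lines(x$t_mid, x$obs_p50, col = "blue", lwd = 2)
  graphics::lines(x$t_mid, x$obs_p5, col = "blue", lty = 2)
  graphics::lines(x$t_mid, x$obs_p95, col = "blue", lty = 2)
  invisible(x)
}

#' Numerical predictive check
#'
#' For each observation the model-simulated predictive distribution at
#' its own design point defines central prediction intervals (50%, 80%,
#' 90%, 95% by default). The fraction of observations falling inside
#' each interval is compared with the nominal coverage, with a 95%
#' band derived from the simulated replicates themselves; fractions
#' outside the band are flagged as outliers.
#'
#' @inheritParams pcvpc
#' @param intervals Nominal central-interval coverages.
#' @return Data frame of class `pk_npc` with columns `interval`, `n`,
#'   `expected`, `observed`, `lo95`, `hi95`, `outlier`. Zero usable
#'   observations give an empty table.
#' @export
npc <- function(cohort, pop, intervals = c(0.5, 0.8, 0.9, 0.95),
                n_sim = 500L, seed, include_induction = TRUE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (inherits(pop, "pkfit")) pop <- pop$estimates
  if (n_sim < 100L) {
    warning("n_sim < 100 gives unstable simulated percentiles",
            call. = FALSE)
  }
  set.seed(seed)
  su <- .check_setup(cohort, pop, include_induction)
  keep <- su$keep
  y <- su$flat$y[keep]
  empty <- data.frame(interval = numeric(0), n = integer(0),
                      expected = numeric(0), observed = numeric(0),
                      lo95 = numeric(0), hi95 = numeric(0),
                      outlier = logical(0))
  class(empty) <- c("pk_npc", "data.frame")
  if (length(y) == 0L) return(empty)
  sims <- .sim_matrix(su$flat, pop, n_sim)[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(intervals, function(p) {
    a <- (1 - p) / 2
    lo <- apply(sims, 1, stats::quantile, a)
    hi <- apply(sims, 1, stats::quantile, 1 - a)
    inside <- mean(y >= lo & y <= hi)
    sim_frac <- colMeans(sims >= lo & sims <= hi)
    band <- stats::quantile(sim_frac, c(0.025, 0.975), names = FALSE)
    data.frame(interval = p, n = length(y), expected = p,
               observed = inside, lo95 = band[1], hi95 = band[2],
               outlier = inside < band[1] | inside > band[2])
  }))
  rownames(out) <- NULL
  class(out) <- c("pk_npc", "data.frame")
  out
}

#' Normalized prediction distribution errors
#'
#' Simulates `n_sim` replicates of each subject's observation vector,
#' decorrelates observed and simulated vectors with the simulated mean
#' and Cholesky factor of the simulated covariance, and rank-transforms
#' the observed decorrelated values to normal quantiles using
#' `(rank - 0.5) / n_sim` with the midrank convention for ties. Under a
#' correct model the resulting values are approximately standard
#' normal; the summary reports their mean and variance with a t-test of
#' mean zero.
#'
#' @inheritParams pcvpc
#' @param n_sim Simulated replicates (default 1000).
#' @return Object of class `pk_npde`: `values` (data frame `id`,
#'   `time`, `npde`) and `summary` (mean, variance, t-test p-value, n).
#' @export
npde <- function(cohort, pop, n_sim = 1000L, seed,
                 include_induction = TRUE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (inherits(pop, "pkfit")) pop <- pop$estimates
  set.seed(seed)
  su <- .check_setup(cohort, pop, include_induction)
  flat <- su$flat
  sims <- .sim_matrix(flat, pop, n_sim)
  vals <- list()
  for (i in seq_len(flat$n)) {
    rows <- which(flat$obs_subj == i & su$keep)
    if (length(rows) == 0L) next
    yi <- flat$y[rows]
    si <- sims[rows, , drop = FALSE]
    m <- rowMeans(si)
    if (length(rows) == 1L) {
      ystar <- yi - m
      sstar <- si - m
    } else {
      S <- stats::cov(t(si))
      L <- tryCatch(t(chol(S)), error = function(e) NULL)
      if (is.null(L)) {
        warning("singular simulated covariance for subject ", flat$ids[i],
                "; ridge regularization applied", call. = FALSE)
        S <- S + diag(1e-8 * max(diag(S), 1), nrow(S))
        L <- t(chol(S))
      }
      ystar <- forwardsolve(L, yi - m)
      sstar <- forwardsolve(L, si - m)
      sstar <- matrix(sstar, nrow = length(rows))
    }
    u <- vapply(seq_along(ystar), function(j) {
      cnt <- sum(sstar[j, ] < ystar[j]) + 0.5 * sum(sstar[j, ] == ystar[j])
      min((cnt + 0.5) / n_sim, (n_sim - 0.5) / n_sim)
    }, numeric(1))
    vals[[length(vals) + 1L]] <- data.frame(
      id = flat$ids[i], time = flat$obs_time[rows],
      npde = stats::qnorm(u), stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, vals)
  t_p <- if (nrow(values) > 1L) stats::t.test(values$npde)$p.value
         else NA_real_
  structure(list(values = values,
                 summary = c(mean = mean(values$npde),
                             variance = stats::var(values$npde),
                             t_pvalue = t_p,
                             n = nrow(values))),
            class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  s <- x$summary
  cat(sprintf("NPDE over %d observations: mean %.3f, variance %.3f (t-test p = %.3g)\n",
              as.integer(s["n"]), s["mean"], s["variance"], s["t_pvalue"]))
  invisible(x)
}
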