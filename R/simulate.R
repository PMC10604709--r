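#' Study design specification for synthetic cohorts
#'
#' Encodes the therapeutic-drug-monitoring design the generator
#' emulates: subcutaneous induction (160 mg at week 0 and 80 mg at week
#' 2 for most subjects, 80/40 mg for a small fraction), 40 mg
#' every-other-week maintenance, and sparse pre-dose trough sampling
#' (2-4 troughs per subject, drawn just before distinct maintenance
#' doses, with a fraction of subjects contributing an induction-phase
#' trough). Albumin is drawn from a truncated normal and antibody
#' status from a Bernoulli.
#'
#' @param n_subjects Number of subjects (default 54).
#' @param induction_amt Standard induction doses in mg at
#'   `induction_times` (default 160/80 at 0 h and 336 h).
#' @param variant_amt Induction doses for the variant fraction (default
#'   80/40).
#' @param variant_frac Fraction of subjects on the variant induction
#'   (default 2/54).
#' @param induction_times Times of the induction doses (h).
#' @param maintenance_amt Maintenance dose (mg, default 40).
#' @param maintenance_interval Dosing interval (h, default 336 = 2
#'   weeks).
#' @param n_maintenance Number of maintenance doses simulated (default
#'   24, about one year of treatment).
#' @param n_troughs Integer range of troughs per subject (default 2:4).
#' @param induction_trough_prob Probability that a subject contributes
#'   one induction-phase trough (default 0.35, reproducing roughly the
#'   observed 19/148 split of induction vs maintenance samples).
#' @param alb_mean,alb_sd,alb_range Truncated-normal albumin generator
#'   (g/dL); defaults 3.77, 0.55, 1.97-4.96.
#' @param aaa_prevalence Antibody-positive prevalence (default 0.167).
#' @param trough_jitter Troughs are drawn at dose time minus
#'   `U(0, trough_jitter)` hours (default 24, clinic-visit jitter).
#' @param rich_design If `TRUE`, replaces sparse troughs with a fixed
#'   8-point schedule including absorption-phase samples (used for
#'   identifiability and parameter-recovery experiments).
#' @param seed Default seed consumed by [simulate_cohort()].
#' @return A list of class `pk_design`.
#' @export
cohort_design <- function(n_subjects = 54L,
                          induction_amt = c(160, 80),
                          variant_amt = c(80, 40),
                          variant_frac = 2 / 54,
                          induction_times = c(0, 336),
                          maintenance_amt = 40,
                          maintenance_interval = 336,
                          n_maintenance = 24L,
                          n_troughs = 2:4,
                          induction_trough_prob = 0.35,
                          alb_mean = 3.77, alb_sd = 0.55,
                          alb_range = c(1.97, 4.96),
                          aaa_prevalence = 0.167,
                          trough_jitter = 24,
                          rich_design = FALSE,
                          seed = NULL) {
  if (n_subjects < 1L) {
    stop("validation error: n_subjects must be >= 1", call. = FALSE)
  }
  if (aaa_prevalence < 0 || aaa_prevalence > 1 ||
      variant_frac < 0 || variant_frac > 1 ||
      induction_trough_prob < 0 || induction_trough_prob > 1) {
    stop("validation error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (alb_range[1] >= alb_range[2] || alb_range[1] <= 0) {
    stop("validation error: alb_range must be ordered and positive",
         call. = FALSE)
  }
  if (any(n_troughs < 1)) {
    stop("validation error: n_troughs must be >= 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "pk_design")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

#' Generate a synthetic cohort with known individual parameters
#'
#' Draws covariates, random effects, dose histories and noisy trough
#' observations according to a [cohort_design()] and a
#' [pk_pop_params()] set. Observations are
#' `C * (1 + err_prop * eps) + err_add * eps'`, floored at zero. The
#' generating truth (per-subject random effects and individual
#' parameters) is returned as a sidecar table, never embedded in the
#' dataset itself.
#'
#' @param design A [cohort_design()].
#' @param pop A [pk_pop_params()] used as generating truth.
#' @param seed Integer seed; defaults to `design$seed`. The generator is
#'   a pure function of (design, pop, seed).
#' @return List with `cohort` (a [pk_cohort]) and `truth` (data frame
#'   `id, alb, aaa, eta_cl, eta_v, cl, v`).
#' @export
simulate_cohort <- function(design, pop, seed = design$seed) {
  stopifnot(inherits(design, "pk_design"), inherits(pop, "pk_pop_params"))
  if (is.null(seed)) {
    stop("validation error: a seed is required (pass seed= or set it in ",
         "the design)", call. = FALSE)
  }
  set.seed(seed)
  n <- design$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  alb <- .rtruncnorm(n, design$alb_mean, design$alb_sd,
                     design$alb_range[1], design$alb_range[2])
  aaa <- stats::rbinom(n, 1, design$aaa_prevalence)
  eta_cl <- stats::rnorm(n, 0, pop$omega_cl)
  eta_v <- stats::rnorm(n, 0, pop$omega_v)
  n_variant <- round(n * design$variant_frac)
  variant <- seq_len(n) %in% sample.int(n, n_variant)
  maint_times <- design$induction_times[2] + design$maintenance_interval *
    seq_len(design$n_maintenance)
  rows <- vector("list", n)
  truth <- data.frame(id = ids, alb = alb, aaa = aaa,
                      eta_cl = eta_cl, eta_v = eta_v,
                      cl = NA_real_, v = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ind_amt <- if (variant[i]) design$variant_amt else design$induction_amt
    doses <- data.frame(time = c(design$induction_times, maint_times),
                        amt = c(ind_amt,
                                rep(design$maintenance_amt,
                                    design$n_maintenance)))
    if (design$rich_design) {
      obs_t <- c(48, 168, 335, 500, 671, 1000, 1343, 2015)
    } else {
      k <- if (length(design$n_troughs) == 1L) design$n_troughs
           else sample(design$n_troughs, 1)
      ind_trough <- stats::runif(1) < design$induction_trough_prob
      k_maint <- max(k - ind_trough, 1L)
      which_dose <- sort(sample.int(design$n_maintenance,
                                    min(k_maint, design$n_maintenance)))
      obs_t <- maint_times[which_dose] -
        stats::runif(length(which_dose), 0, design$trough_jitter)
      if (ind_trough) {
        t_ind <- sample(c(design$induction_times[2],
                          design$induction_times[2] +
                            design$maintenance_interval), 1) -
          stats::runif(1, 0, design$trough_jitter)
        obs_t <- sort(c(t_ind, obs_t))
      }
    }
    p <- individual_params(pop, c(eta_cl[i], eta_v[i]), alb[i], aaa[i])
    truth$cl[i] <- p$cl; truth$v[i] <- p$v
    f <- conc_profile(obs_t, doses, p$cl, p$v, p$ka)
    dv <- f * (1 + pop$err_prop * stats::rnorm(length(f))) +
      pop$err_add * stats::rnorm(length(f))
    dv <- pmax(dv, 0)
    rows[[i]] <- data.frame(
      ID = ids[i],
      TIME = c(doses$time, obs_t),
      AMT = c(doses$amt, rep(NA_real_, length(obs_t))),
      DV = c(rep(NA_real_, nrow(doses)), dv),
      EVID = c(rep(1, nrow(doses)), rep(0, length(obs_t))),
      ALB = alb[i], AAA = aaa[i], stringsAsFactors = FALSE)
  }
  cohort <- pk_cohort(do.call(rbind, rows),
                      meta = list(generator = "simulate_cohort", seed = seed,
                                  assay_range = c(0.1, 16),
                                  rich_design = design$rich_design))
  list(cohort = cohort, truth = truth)
}

#' Handle observations below the limit of quantification
#'
#' The assay quantifies 0.1-16 mg/L; values below 0.1 mg/L can be kept
#' as reported (default, matching the main analysis), dropped, or
#' floored at the limit.
#'
#' @param cohort A [pk_cohort].
#' @param loq Limit of quantification (mg/L, default 0.1).
#' @param policy `"keep"`, `"drop"` or `"floor"`.
#' @return The adjusted [pk_cohort].
#' @export
apply_loq <- function(cohort, loq = 0.1, policy = c("keep", "drop", "floor")) {
  stopifnot(inherits(cohort, "pk_cohort"))
  if (!is.character(policy) ||
      !policy[1] %in% c("keep", "drop", "floor")) {
    stop("configuration error: unknown LOQ policy '", policy[1], "'",
         call. = FALSE)
  }
  policy <- policy[1]
  if (policy == "keep") return(cohort)
  data <- cohort$data
  low <- data$EVID == 0 & !is.na(data$DV) & data$DV < loq
  if (policy == "drop") {
    data <- data[!low, , drop = FALSE]
  } else {
    data$DV[low] <- loq
  }
  pk_cohort(data, meta = cohort$meta)
}
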