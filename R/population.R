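#' Population parameter set
#'
#' Container for the fixed effects, interindividual variability (IIV)
#' standard deviations and residual-error coefficients of the population
#' model. IIV is lognormal; `omega_cl` and `omega_v` are the standard
#' deviations of the log-scale random effects on clearance and volume.
#' The residual error SD for a prediction `f` is `err_add + err_prop * f`
#' (a "combined1"-style model; the proportional model is the
#' `err_add = 0` case).
#'
#' @param cl_pop Population apparent clearance CL/F (L/h).
#' @param v_pop Population apparent volume V/F (L).
#' @param ka_pop Absorption rate constant (1/h); default 0.00625.
#' @param cov_aaa Proportional clearance shift for antibody-positive
#'   subjects; default 4.5.
#' @param cov_alb Albumin power exponent on clearance; default 0 (no
#'   albumin effect).
#' @param m_alb Albumin centering constant (g/dL); default 3.77.
#' @param omega_cl,omega_v IIV standard deviations (log scale), > 0.
#' @param err_add Additive residual SD (mg/L), >= 0.
#' @param err_prop Proportional residual coefficient, >= 0. `err_add`
#'   and `err_prop` must not both be 0.
#' @return An object of class `pk_pop_params`.
#' @seealso [final_params()], [reference_params()]
#' @export
pk_pop_params <- function(cl_pop, v_pop, ka_pop = 0.00625, cov_aaa = 4.5,
                          cov_alb = 0, m_alb = 3.77,
                          omega_cl, omega_v, err_add = 0, err_prop) {
  for (nm in c("cl_pop", "v_pop", "ka_pop", "omega_cl", "omega_v", "m_alb")) {
    .check_pos(get(nm), nm)
  }
  if (err_add < 0 || err_prop < 0) {
    stop("validation error: error coefficients must be >= 0", call. = FALSE)
  }
  if (err_add == 0 && err_prop == 0) {
    stop("validation error: err_add and err_prop cannot both be 0 ",
         "(degenerate likelihood)", call. = FALSE)
  }
  if (cov_aaa <= -1) {
    stop("validation error: cov_aaa must exceed -1", call. = FALSE)
  }
  structure(list(cl_pop = cl_pop, v_pop = v_pop, ka_pop = ka_pop,
                 cov_aaa = cov_aaa, cov_alb = cov_alb, m_alb = m_alb,
                 omega_cl = omega_cl, omega_v = omega_v,
                 err_add = err_add, err_prop = err_prop),
            class = "pk_pop_params")
}

#' Published parameter sets
#'
#' `reference_params()` returns the literature model this work starts
#' from: combined residual error, no albumin effect on clearance.
#' `final_params()` returns the re-estimated model for the inflammatory
#' bowel disease population: albumin as a power covariate on clearance
#' and a proportional-only residual error. In both, `ka` (0.00625 1/h)
#' and the antibody shift on clearance (4.5) are fixed.
#'
#' @return A [pk_pop_params] object.
#' @export
reference_params <- function() {
  pk_pop_params(cl_pop = 0.0175, v_pop = 13.5, ka_pop = 0.00625,
                cov_aaa = 4.5, cov_alb = 0, m_alb = 3.77,
                omega_cl = 0.65, omega_v = 0.48,
                err_add = 1.8, err_prop = 0.15)
}

#' @rdname reference_params
#' @export
final_params <- function() {
  pk_pop_params(cl_pop = 0.0312, v_pop = 7.76, ka_pop = 0.00625,
                cov_aaa = 4.5, cov_alb = -2.33, m_alb = 3.77,
                omega_cl = 0.667, omega_v = 0.477,
                err_add = 0, err_prop = 0.547)
}

#' @export
print.pk_pop_params <- function(x, ...) {
  cat("Population PK parameters (1-cmt, first-order absorption)\n")
  cat(sprintf("  CL/F %.4g L/h   V/F %.4g L   ka %.4g 1/h\n",
              x$cl_pop, x$v_pop, x$ka_pop))
  cat(sprintf("  covariates on CL/F: AAA shift %.3g; albumin exponent %.3g (centred at %.3g g/dL)\n",
              x$cov_aaa, x$cov_alb, x$m_alb))
  cat(sprintf("  IIV (SD of log): omega_CL %.3g, omega_V %.3g\n",
              x$omega_cl, x$omega_v))
  cat(sprintf("  residual SD: %.3g + %.3g * pred mg/L\n",
              x$err_add, x$err_prop))
  invisible(x)
}

#' Residual-error standard deviation
#'
#' SD of an observation around its model prediction `pred`:
#' `a + b * pred`. An SD of exactly zero (proportional-only model at a
#' zero prediction) is returned as-is; likelihood code treats such
#' observations as degenerate and errors out.
#'
#' @param pred Model-predicted concentration (mg/L), >= 0.
#' @param a Additive component (mg/L), >= 0.
#' @param b Proportional component (dimensionless), >= 0.
#' @return SD in mg/L, same length as `pred`.
#' @export
residual_sd <- function(pred, a, b) {
  if (any(pred < 0)) stop("validation error: pred must be >= 0", call. = FALSE)
  if (a < 0 || b < 0) stop("validation error: a, b must be >= 0", call. = FALSE)
  if (a == 0 && b == 0) {
    stop("validation error: a and b cannot both be 0", call. = FALSE)
  }
  a + b * pred
}

#' Joint log-likelihood of one subject's data and random effects
#'
#' Sum of Gaussian observation log-densities (mean from the structural
#' model with the subject's individual parameters, SD from
#' [residual_sd()]) plus the log-density of `eta` under
#' `N(0, diag(omega_cl^2, omega_v^2))`. This is the objective maximised
#' over `eta` to obtain empirical Bayes estimates.
#'
#' @param subject A `pk_subject` (see [cohort_subjects()]).
#' @param pop A [pk_pop_params] object.
#' @param eta Length-2 numeric `c(eta_cl, eta_v)`.
#' @param use_held_out Include held-out observations in the data term?
#'   Default `TRUE`.
#' @return Scalar log-likelihood.
#' @export
individual_loglik <- function(subject, pop, eta, use_held_out = TRUE) {
  stopifnot(inherits(subject, "pk_subject"), inherits(pop, "pk_pop_params"))
  p <- individual_params(pop, eta, subject$alb, subject$aaa)
  obs <- subject$obs
  if (!use_held_out) obs <- obs[!obs$held_out, , drop = FALSE]
  ll <- stats::dnorm(eta[1], 0, pop$omega_cl, log = TRUE) +
        stats::dnorm(eta[2], 0, pop$omega_v, log = TRUE)
  if (nrow(obs) > 0L) {
    f <- conc_profile(obs$time, subject$doses, p$cl, p$v, p$ka)
    s <- residual_sd(f, pop$err_add, pop$err_prop)
    if (any(s <= 0)) {
      stop("zero residual SD at an observation (prediction 0 under a ",
           "proportional-only error model)", call. = FALSE)
    }
    ll <- ll + sum(stats::dnorm(obs$dv, f, s, log = TRUE))
  }
  ll
}

#' Prior specification for maximum a posteriori estimation
#'
#' One row per parameter carrying a prior mean and a relative standard
#' error (fraction, not percent). Estimation treats an informative prior
#' as a Gaussian penalty on the log parameter:
#' `log theta ~ N(log prior_mean, prior_rse^2)` (RSE approximates the
#' coefficient of variation for small RSE, and the log-scale form keeps
#' positive parameters positive). Parameters without a row, or with
#' `informative = FALSE`, contribute nothing.
#'
#' @param param Character vector of parameter names (any of `cl_pop`,
#'   `v_pop`, `omega_cl`, `omega_v`, `err_add`, `err_prop`, `ka_pop`).
#' @param mean Prior means, same length.
#' @param rse Prior relative standard errors as fractions (> 0), same
#'   length.
#' @param informative Logical, recycled; default `TRUE`.
#' @return A data frame of class `pk_priors`.
#' @export
pk_priors <- function(param, mean, rse, informative = TRUE) {
  stopifnot(length(param) == length(mean), length(param) == length(rse))
  if (any(informative & (rse <= 0 | mean <= 0))) {
    stop("validation error: informative priors need mean > 0 and rse > 0",
         call. = FALSE)
  }
  out <- data.frame(param = as.character(param), mean = mean, rse = rse,
                    informative = rep_len(informative, length(param)),
                    stringsAsFactors = FALSE)
  class(out) <- c("pk_priors", "data.frame")
  out
}

#' @details `reference_priors()` encodes the literature model's estimates
#' and relative standard errors, the natural informative prior when
#' re-fitting on a new sparse dataset.
#' @rdname pk_priors
#' @export
reference_priors <- function() {
  pk_priors(param = c("cl_pop", "v_pop", "omega_cl", "omega_v",
                      "err_prop", "err_add"),
            mean  = c(0.0175, 13.5, 0.65, 0.48, 0.15, 1.8),
            rse   = c(0.09, 0.10, 0.10, 0.19, 0.16, 0.08))
}

#' Prior penalty on the -2 log-likelihood scale
#'
#' For each informative prior, adds
#' `((log theta - log prior_mean) / prior_rse)^2` to the objective, i.e.
#' minus twice the Gaussian log-density of the log parameter up to an
#' additive constant. The penalty is zero at the prior mean and each
#' parameter's contribution vanishes as its `rse` grows (noninformative
#' limit).
#'
#' @param pop A [pk_pop_params] holding the candidate parameter values.
#' @param priors A [pk_priors] table, or `NULL` for no penalty.
#' @param fixed Character vector of parameter names fixed during
#'   estimation; an informative prior on a fixed parameter is a
#'   configuration error.
#' @return Scalar penalty (>= 0).
#' @export
prior_penalty <- function(pop, priors, fixed = character()) {
  if (is.null(priors)) return(0)
  stopifnot(inherits(pop, "pk_pop_params"))
  pr <- priors[priors$informative, , drop = FALSE]
  if (nrow(pr) == 0L) return(0)
  clash <- intersect(pr$param, fixed)
  if (length(clash) > 0L) {
    stop("configuration error: informative prior on fixed parameter(s): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(pr$param, names(pop))
  if (length(unknown) > 0L) {
    stop("configuration error: prior on unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(pop[pr$param])
  if (any(vals <= 0)) {
    stop("validation error: lognormal prior needs positive parameter values",
         call. = FALSE)
  }
  sum(((log(vals) - log(pr$mean)) / pr$rse)^2)
}
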