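#' Control parameters for population fitting
#'
#' @param outer_reltol Relative objective-change tolerance of the outer
#'   optimizer (default 1e-8).
#' @param outer_maxit Maximum outer iterations (default 300).
#' @param grad_tol Infinity-norm gradient tolerance on the -2LL scale
#'   declaring outer convergence (default 1e-4).
#' @param inner_tol Gradient tolerance of the inner empirical Bayes
#'   solves (default 1e-8).
#' @param inner_maxit Maximum inner Newton iterations (default 100).
#' @param hess_step Relative finite-difference step for Hessians
#'   (default 1e-4).
#' @param polish_maxit Newton polish steps after the quasi-Newton stage
#'   (default 5).
#' @param compute_rse Compute standard errors from the objective
#'   curvature (default `TRUE`; bootstrap replicates switch it off).
#' @return A list of class `pk_control`.
#' @export
pk_control <- function(outer_reltol = 1e-8, outer_maxit = 300L,
                       grad_tol = 1e-4, inner_tol = 1e-8,
                       inner_maxit = 100L, hess_step = 1e-4,
                       polish_maxit = 5L, compute_rse = TRUE) {
  structure(list(outer_reltol = outer_reltol, outer_maxit = outer_maxit,
                 grad_tol = grad_tol, inner_tol = inner_tol,
                 inner_maxit = inner_maxit, hess_step = hess_step,
                 polish_maxit = polish_maxit, compute_rse = compute_rse),
            class = "pk_control")
}

#' Declare an additional covariate effect on clearance
#'
#' Used by [pkfit()] and [stepwise_covariate_search()] to extend the
#' clearance model with one parameter per effect: a power term
#' `(x/ref)^beta` for continuous covariates or a proportional shift
#' `1 + beta * x` for 0/1 covariates. The covariate must be present as an
#' extra column of the dataset (constant per subject).
#'
#' @param name Column name of the covariate.
#' @param form `"power"` (continuous) or `"linear"` (categorical shift).
#' @param ref Centering value for the power form; defaults to the cohort
#'   mean of the covariate.
#' @param start Starting value of the effect parameter (default 0, the
#'   null effect).
#' @return A list of class `pk_covariate`.
#' @export
pk_covariate <- function(name, form = c("power", "linear"), ref = NULL,
                         start = 0) {
  form <- match.arg(form)
  structure(list(name = name, form = form, ref = ref, start = start),
            class = "pk_covariate")
}

.log_pars <- c("cl_pop", "v_pop", "ka_pop", "omega_cl", "omega_v",
               "err_add", "err_prop")
.all_pars <- c("cl_pop", "v_pop", "ka_pop", "cov_aaa", "cov_alb",
               "omega_cl", "omega_v", "err_add", "err_prop")

.theta_of <- function(pop, free) {
  vapply(free, function(nm) {
    v <- if (startsWith(nm, "beta_")) pop$betas[[nm]] else pop[[nm]]
    if (nm %in% .log_pars) log(v) else v
  }, numeric(1))
}

.pop_with <- function(pop, free, theta) {
  for (i in seq_along(free)) {
    nm <- free[i]
    v <- if (nm %in% .log_pars) exp(theta[i]) else theta[i]
    if (startsWith(nm, "beta_")) pop$betas[[nm]] <- v else pop[[nm]] <- v
  }
  pop
}

.fd_grad <- function(fn, theta, h = NULL) {
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(theta))
  vapply(seq_along(theta), function(i) {
    tp <- tm <- theta; tp[i] <- tp[i] + h[i]; tm[i] <- tm[i] - h[i]
    (fn(tp) - fn(tm)) / (2 * h[i])
  }, numeric(1))
}

.fd_hess <- function(fn, theta, h = NULL) {
  k <- length(theta)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(theta))
  f0 <- fn(theta)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    tp <- tm <- theta; tp[i] <- tp[i] + h[i]; tm[i] <- tm[i] - h[i]
    H[i, i] <- (fn(tp) - 2 * f0 + fn(tm)) / h[i]^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      tpp <- tpm <- tmp <- tmm <- theta
      tpp[c(i, j)] <- tpp[c(i, j)] + h[c(i, j)]
      tmm[c(i, j)] <- tmm[c(i, j)] - h[c(i, j)]
      tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
      tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
      H[i, j] <- H[j, i] <- (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Empirical Bayes estimate of one subject's random effects
#'
#' Maximises [individual_loglik()] over `(eta_cl, eta_v)` (the posterior
#' mode given the population parameters) by Newton iteration, restarting
#' from a small grid if the start at the population mode (0, 0) does not
#' converge. A subject with no usable observations shrinks fully to the
#' population: `eta = (0, 0)`.
#'
#' @param subject A `pk_subject` (see [cohort_subjects()]).
#' @param pop A [pk_pop_params] object.
#' @param use_held_out Include held-out observations? Default `TRUE`;
#'   set `FALSE` for leave-last-out prediction.
#' @param tol Gradient tolerance (default 1e-8).
#' @return List with `eta` (named length-2), `loglik`, `grad_norm`,
#'   `hessian` (expected-information curvature at the mode) and
#'   `converged`.
#' @export
estimate_ebe <- function(subject, pop, use_held_out = TRUE, tol = 1e-8) {
  stopifnot(inherits(subject, "pk_subject"), inherits(pop, "pk_pop_params"))
  flat <- .flatten_subjects(list(subject), use_held_out = use_held_out)
  cl_typ <- .typical_cl(flat, pop)
  starts <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1.5, 1.5), c(-1.5, -1.5))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    sol <- .ebe_solve(flat, pop, cl_typ,
                      eta_init = starts[k, , drop = FALSE], tol = tol)
    if (is.null(best) || (sol$converged && !best$converged) ||
        (sol$converged == best$converged && sol$ll > best$ll)) {
      best <- sol
    }
    if (best$converged) break
  }
  if (!best$converged) {
    warning("EBE solve did not reach gradient tolerance for subject ",
            subject$id, " (|grad| = ", format(max(abs(best$grad))), ")",
            call. = FALSE)
  }
  list(eta = c(eta_cl = unname(best$eta[1, 1]), eta_v = unname(best$eta[1, 2])),
       loglik = best$ll[1],
       grad_norm = max(abs(best$grad[1, ])),
       hessian = matrix(c(best$hess[1, "a11"], best$hess[1, "a12"],
                          best$hess[1, "a12"], best$hess[1, "a22"]), 2, 2),
       converged = best$converged[1])
}

.flatten_subjects <- function(subjects, use_held_out = TRUE) {
  .flatten_from_subjects(subjects, use_held_out)
}

#' Laplace-approximate -2 log-likelihood of a cohort
#'
#' Marginalises the random effects of every subject by Laplace
#' approximation at the empirical Bayes mode and returns the total
#' -2 log-likelihood (OFV). Deterministic given data and parameters.
#'
#' @param cohort A [pk_cohort].
#' @param pop A [pk_pop_params].
#' @param use_held_out Include held-out observations (default `TRUE`).
#' @return Scalar OFV.
#' @export
laplace_ofv <- function(cohort, pop, use_held_out = TRUE) {
  stopifnot(inherits(cohort, "pk_cohort"), inherits(pop, "pk_pop_params"))
  flat <- .flatten_cohort(cohort, use_held_out = use_held_out)
  .laplace_ofv_flat(flat, pop)$ofv
}

#' Fit the population model by Laplace-approximate maximum likelihood
#'
#' Estimates the free population parameters of the one-compartment
#' adalimumab model by minimising the Laplace-approximate -2
#' log-likelihood, optionally penalised by informative lognormal priors
#' (maximum a posteriori estimation). Positive parameters are optimised
#' on the log scale; covariate exponents are unconstrained. Standard
#' errors come from the inverse curvature of the objective at the
#' optimum (delta method back to the natural scale).
#'
#' By default `ka_pop` and `cov_aaa` are fixed (trough-only data carry
#' no absorption information and few subjects are antibody-positive),
#' and an error component whose starting value is 0 is fixed at 0.
#'
#' @param cohort A [pk_cohort] with complete covariates.
#' @param start A [pk_pop_params] with starting values; defaults to the
#'   published final-model estimates.
#' @param priors A [pk_priors] table or `NULL` (plain maximum
#'   likelihood).
#' @param fixed Character vector of parameter names to fix.
#' @param covariates List of [pk_covariate()] effects extending the
#'   clearance model (each adds one free parameter `beta_<name>`).
#' @param use_held_out Include held-out observations in the fit
#'   (default `TRUE`).
#' @param control A [pk_control()] list.
#' @return An object of class `pkfit` with components `estimates`
#'   ([pk_pop_params]), `rse` (percent, free parameters), `ci` (95%
#'   intervals), `ofv`, `converged`, `ebes` (per-subject random-effect
#'   modes), `n_subjects`, `n_obs`, and the fit configuration. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `vcov`, `confint`, `predict`,
#'   `residuals`, `simulate`, `plot`.
#' @examples
#' \donttest{
#' design <- cohort_design(n_subjects = 20, seed = 1)
#' cohort <- simulate_cohort(design, final_params())$cohort
#' fit <- pkfit(cohort, control = pk_control(compute_rse = FALSE))
#' fit
#' }
#' @export
pkfit <- function(cohort, start = final_params(), priors = NULL,
                  fixed = c("ka_pop", "cov_aaa"), covariates = list(),
                  use_held_out = TRUE, control = pk_control()) {
  stopifnot(inherits(cohort, "pk_cohort"), inherits(start, "pk_pop_params"))
  flat <- .flatten_cohort(cohort, use_held_out = use_held_out)
  fit <- .fit_engine(flat, start, priors, fixed, covariates, control)
  fit$cohort <- cohort
  fit$use_held_out <- use_held_out
  fit$call <- match.call()
  fit
}

.fit_engine <- function(flat, start, priors, fixed, covariates, control,
                        weights = NULL, eta_init = NULL) {
  pop <- unclass(start)
  class(pop) <- "pk_pop_params"
  if (length(covariates)) {
    pop$cov_effects <- lapply(covariates, function(eff) {
      stopifnot(inherits(eff, "pk_covariate"))
      if (!eff$name %in% colnames(flat$extras)) {
        stop("configuration error: covariate column '", eff$name,
             "' not in the dataset", call. = FALSE)
      }
      if (eff$form == "power" && is.null(eff$ref)) {
        eff$ref <- mean(flat$extras[, eff$name])
      }
      eff
    })
    pop$betas <- stats::setNames(
      vapply(covariates, function(e) e$start, numeric(1)),
      paste0("beta_", vapply(covariates, function(e) e$name, character(1))))
  }
  par_names <- c(.all_pars, names(pop$betas))
  ## an error component starting at 0 cannot be estimated on the log scale
  for (nm in c("err_add", "err_prop")) {
    if (pop[[nm]] == 0 && !(nm %in% fixed)) fixed <- c(fixed, nm)
  }
  bad <- setdiff(fixed, par_names)
  if (length(bad)) {
    stop("configuration error: unknown parameter(s) in fixed: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  free <- setdiff(par_names, fixed)
  prior_penalty(pop, priors, fixed)   # validates prior/fixed clashes
  theta0 <- .theta_of(pop, free)
  k <- length(free)
  ## inner solves start from a FIXED init (eta = 0, or a supplied
  ## reference such as the original fit's EBEs): the objective is then a
  ## deterministic function of theta. A path-dependent warm start can
  ## hand a subject with a multimodal joint likelihood to a different
  ## mode, which the outer optimizer sees as a cliff.
  obj <- function(theta) {
    p <- .pop_with(pop, free, theta)
    res <- tryCatch(
      suppressWarnings(.laplace_ofv_flat(flat, p, eta_init = eta_init,
                                         weights = weights,
                                         tol = control$inner_tol,
                                         maxit = control$inner_maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) {
      ## failed evaluation: a large value sloped back towards the
      ## start, so the region repels rather than strands the optimizer
      return(1e9 * (1 + sum((theta - theta0)^2)))
    }
    res$ofv + prior_penalty(p, priors, fixed)
  }
  if (k == 0L) {
    ofv <- obj(numeric(0))
    sol <- .laplace_ofv_flat(flat, pop, weights = weights,
                             tol = control$inner_tol)$sol
    return(.fit_result(pop, free, numeric(0), ofv, TRUE, 0, NULL, flat,
                       sol, priors, fixed, control))
  }
  ## optimize in prior-scaled coordinates: a tight informative prior
  ## puts a curvature of 2/rse^2 on its parameter, and without scaling
  ## that conditioning (1e12 at rse = 1e-6) defeats both quasi-Newton
  ## line searches and the polish solve
  ps <- rep(1, k)
  if (!is.null(priors)) {
    pr_inf <- priors[priors$informative, , drop = FALSE]
    for (j in seq_len(nrow(pr_inf))) {
      i <- match(pr_inf$param[j], free)
      if (!is.na(i)) ps[i] <- min(1, pr_inf$rse[j])
    }
  }
  obj_u <- function(u) obj(u * ps)
  u0 <- theta0 / ps
  if (control$polish_maxit > 0L) {
    opt <- stats::optim(u0, obj_u, method = "BFGS",
                        control = list(maxit = control$outer_maxit,
                                       reltol = control$outer_reltol,
                                       ndeps = rep(1e-4, k)))
  } else {
    ## replicate fits: box-constrained search around the original
    ## optimum (5 log units is an ~150-fold range on positive
    ## parameters) so a degenerate resample pins at a boundary instead
    ## of running away; forward-difference gradient with a cached
    ## centre value keeps the cost at k+1 evaluations
    last <- new.env(parent = emptyenv())
    fn_cached <- function(u) {
      v <- obj_u(u)
      last$u <- u; last$f <- v
      v
    }
    gr_fwd <- function(u) {
      f0 <- if (!is.null(last$u) && identical(u, last$u))
        last$f else obj_u(u)
      h <- 1e-4 * pmax(1, abs(u))
      vapply(seq_along(u), function(i) {
        up <- u; up[i] <- up[i] + h[i]
        (obj_u(up) - f0) / h[i]
      }, numeric(1))
    }
    opt <- stats::optim(u0, fn_cached, gr_fwd, method = "L-BFGS-B",
                        lower = u0 - 5, upper = u0 + 5,
                        control = list(maxit = control$outer_maxit,
                                       factr = 1e11))
  }
  u <- opt$par; fval <- opt$value
  g <- .fd_grad(obj_u, u)
  gnorm <- max(abs(g))
  H <- NULL
  for (it in seq_len(control$polish_maxit)) {
    if (gnorm <= control$grad_tol) break
    H <- .fd_hess(obj_u, u, h = control$hess_step * pmax(1, abs(u)))
    d <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(d) || !all(is.finite(d))) break
    improved <- FALSE
    for (s in c(1, 0.5, 0.25, 0.1)) {
      cand <- u - s * d
      fc <- obj_u(cand)
      if (fc <= fval + 1e-9) {
        gc_ <- .fd_grad(obj_u, cand)
        if (max(abs(gc_)) < gnorm || fc < fval - 1e-9) {
          u <- cand; fval <- fc; g <- gc_; gnorm <- max(abs(g))
          improved <- TRUE; H <- NULL
          break
        }
      }
    }
    if (!improved) break
  }
  if (control$compute_rse && is.null(H)) {
    H <- .fd_hess(obj_u, u, h = control$hess_step * pmax(1, abs(u)))
  }
  theta <- u * ps
  ## curvature back on the theta scale for uncertainty reporting
  if (!is.null(H)) H <- H / outer(ps, ps)
  ## with polish the contract is the gradient tolerance; without it
  ## (bootstrap replicates) the optimizer's relative-change criterion
  ## decides: case-resampled sparse likelihoods can be only piecewise
  ## smooth (a subject's inner mode switching between local optima puts
  ## a kink in the profile), and a gradient gate would misclassify a
  ## kink minimum as failure
  converged <- if (control$polish_maxit > 0L) {
    gnorm <= max(control$grad_tol, 1e-2) &&
      (opt$convergence == 0L || gnorm <= control$grad_tol)
  } else {
    ## a replicate that ran away (transformed parameters far from the
    ## start) converged onto an error plateau, not onto an optimum
    opt$convergence == 0L && is.finite(fval) &&
      max(abs(theta - theta0)) <= 7
  }
  pop_hat <- .pop_with(pop, free, theta)
  sol <- suppressWarnings(
    .laplace_ofv_flat(flat, pop_hat, eta_init = eta_init,
                      weights = weights, tol = control$inner_tol)$sol)
  res <- .fit_result(pop_hat, free, theta, fval, converged, gnorm,
                     if (control$compute_rse) H else NULL,
                     flat, sol, priors, fixed, control)
  res$optim <- list(counts = opt$counts, convergence = opt$convergence)
  res
}

.fit_result <- function(pop, free, theta, ofv, converged, gnorm, H,
                        flat, sol, priors, fixed, control) {
  k <- length(free)
  rse <- se <- stats::setNames(rep(NA_real_, k), free)
  ci <- matrix(NA_real_, k, 2, dimnames = list(free, c("2.5%", "97.5%")))
  vcov_theta <- NULL
  if (!is.null(H) && k > 0) {
    vcov_theta <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vcov_theta) && all(diag(vcov_theta) > 0)) {
      se_theta <- sqrt(diag(vcov_theta))
      est <- vapply(free, function(nm) {
        if (startsWith(nm, "beta_")) pop$betas[[nm]] else pop[[nm]]
      }, numeric(1))
      for (i in seq_len(k)) {
        if (free[i] %in% .log_pars) {
          rse[i] <- 100 * se_theta[i]
          se[i] <- est[i] * se_theta[i]
          ci[i, ] <- est[i] * exp(c(-1, 1) * 1.959964 * se_theta[i])
        } else {
          se[i] <- se_theta[i]
          rse[i] <- 100 * se_theta[i] / abs(est[i])
          ci[i, ] <- est[i] + c(-1, 1) * 1.959964 * se_theta[i]
        }
      }
      dimnames(vcov_theta) <- list(free, free)
    } else {
      vcov_theta <- NULL
      warning("objective curvature not positive definite; ",
              "standard errors unavailable", call. = FALSE)
    }
  }
  ebes <- sol$eta
  rownames(ebes) <- flat$ids
  structure(list(estimates = pop, free = free, fixed = fixed,
                 theta = stats::setNames(theta, free),
                 rse = rse, se = se, ci = ci, vcov_theta = vcov_theta,
                 ofv = ofv, converged = converged, grad_norm = gnorm,
                 ebes = ebes, ebe_converged = sol$converged,
                 n_subjects = flat$n, n_obs = length(flat$y),
                 priors = priors, control = control),
            class = "pkfit")
}

#' @export
print.pkfit <- function(x, ...) {
  cat("Population PK fit (Laplace",
      if (!is.null(x$priors) && any(x$priors$informative)) "MAP" else "ML",
      "estimation)\n")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f; %s\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  print(.param_table(x), digits = 4)
  invisible(x)
}

.param_table <- function(x) {
  pop <- x$estimates
  nm <- c(.all_pars, names(pop$betas))
  est <- vapply(nm, function(n) {
    if (startsWith(n, "beta_")) pop$betas[[n]] else pop[[n]]
  }, numeric(1))
  i <- match(nm, x$free)
  data.frame(estimate = est,
             rse_pct = x$rse[i],
             lo95 = x$ci[i, 1],
             hi95 = x$ci[i, 2],
             fixed = nm %in% x$fixed,
             row.names = nm)
}

#' @export
summary.pkfit <- function(object, ...) {
  out <- list(table = .param_table(object), ofv = object$ofv,
              converged = object$converged, grad_norm = object$grad_norm,
              n_subjects = object$n_subjects, n_obs = object$n_obs,
              map = !is.null(object$priors) && any(object$priors$informative),
              ebe_shrinkage = .ebe_shrinkage(object))
  class(out) <- "summary.pkfit"
  out
}

.ebe_shrinkage <- function(fit) {
  ## 1 - SD(EBE)/omega, the usual eta-shrinkage diagnostic
  c(eta_cl = 1 - stats::sd(fit$ebes[, 1]) / fit$estimates$omega_cl,
    eta_v = 1 - stats::sd(fit$ebes[, 2]) / fit$estimates$omega_v)
}

#' @export
print.summary.pkfit <- function(x, ...) {
  cat("Population PK model,", if (x$map) "MAP" else "ML",
      "Laplace estimation\n")
  cat(sprintf("  n = %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  cat(sprintf("  OFV (-2 log-likelihood) = %.3f; gradient norm %.2g; %s\n",
              x$ofv, x$grad_norm,
              if (x$converged) "converged" else "NOT converged"))
  print(x$table, digits = 4)
  cat(sprintf("  eta-shrinkage: CL %.1f%%, V %.1f%%\n",
              100 * x$ebe_shrinkage[1], 100 * x$ebe_shrinkage[2]))
  invisible(x)
}

#' @export
coef.pkfit <- function(object, ...) {
  pop <- object$estimates
  nm <- c(.all_pars, names(pop$betas))
  vapply(nm, function(n) {
    if (startsWith(n, "beta_")) pop$betas[[n]] else pop[[n]]
  }, numeric(1))
}

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$free),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.pkfit <- function(object, ...) {
  if (is.null(object$vcov_theta)) return(NULL)
  est <- vapply(object$free, function(nm) {
    pop <- object$estimates
    if (startsWith(nm, "beta_")) pop$betas[[nm]] else pop[[nm]]
  }, numeric(1))
  D <- diag(ifelse(object$free %in% .log_pars, est, 1),
            nrow = length(est))
  V <- D %*% object$vcov_theta %*% D
  dimnames(V) <- list(object$free, object$free)
  V
}

#' @export
confint.pkfit <- function(object, parm, level = 0.95, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Model predictions for a fitted population PK model
#'
#' `type = "individual"` uses each subject's empirical Bayes random
#' effects; `type = "population"` sets the random effects to zero
#' (typical-subject prediction given the covariates).
#'
#' @param object A `pkfit`.
#' @param newdata Optional [pk_cohort]; defaults to the fitted cohort.
#' @param type `"individual"` or `"population"`.
#' @param ... Unused.
#' @return Data frame with `id`, `time`, `dv` (observed), `pred` and
#'   `held_out`.
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("individual", "population"), ...) {
  type <- match.arg(type)
  cohort <- if (is.null(newdata)) object$cohort else newdata
  pop <- object$estimates
  subjects <- cohort_subjects(cohort)
  out <- lapply(subjects, function(s) {
    eta <- c(0, 0)
    if (type == "individual") {
      if (is.null(newdata) && s$id %in% rownames(object$ebes)) {
        eta <- object$ebes[s$id, ]
      } else {
        eta <- estimate_ebe(s, pop)$eta
      }
    }
    p <- .indiv_params_ext(pop, eta, s)
    data.frame(id = s$id, time = s$obs$time, dv = s$obs$dv,
               pred = conc_profile(s$obs$time, s$doses, p$cl, p$v, p$ka),
               held_out = s$obs$held_out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## individual parameters honouring any extra covariate effects on CL
.indiv_params_ext <- function(pop, eta, subject) {
  p <- individual_params(pop, eta, subject$alb, subject$aaa)
  if (!is.null(pop$cov_effects)) {
    for (eff in pop$cov_effects) {
      x <- subject$covariates[[eff$name]]
      beta <- pop$betas[[paste0("beta_", eff$name)]]
      p$cl <- p$cl * if (eff$form == "power") (x / eff$ref)^beta
                     else 1 + beta * x
    }
  }
  p
}

#' @export
residuals.pkfit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  pr <- predict(object, type = "individual")
  r <- pr$dv - pr$pred
  if (type == "pearson") {
    s <- residual_sd(pr$pred, object$estimates$err_add,
                     object$estimates$err_prop)
    r <- r / s
  }
  r
}

#' Simulate new observations from a fitted model
#'
#' Draws fresh random effects and residual noise at the design points of
#' the (fitted or supplied) cohort. Concentrations are floored at zero.
#'
#' @param object A `pkfit`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed (required for reproducibility).
#' @param newdata Optional [pk_cohort].
#' @param ... Unused.
#' @return Data frame with `sim`, `id`, `time`, `dv`.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  cohort <- if (is.null(newdata)) object$cohort else newdata
  if (!is.null(seed)) set.seed(seed)
  flat <- .flatten_cohort(cohort)
  sims <- .sim_matrix(flat, object$estimates, nsim)
  data.frame(sim = rep(seq_len(nsim), each = length(flat$y)),
             id = rep(flat$ids[flat$obs_subj], nsim),
             time = rep(flat$obs_time, nsim),
             dv = as.vector(sims), stringsAsFactors = FALSE)
}

# Matrix of simulated DV (rows = observation records, cols = replicates)
# at the design points of a flattened cohort.
.sim_matrix <- function(flat, pop, n_sim) {
  cl_typ <- .typical_cl(flat, pop)
  out <- matrix(0, length(flat$y), n_sim)
  for (r in seq_len(n_sim)) {
    eta1 <- stats::rnorm(flat$n, 0, pop$omega_cl)
    eta2 <- stats::rnorm(flat$n, 0, pop$omega_v)
    f <- .conc_all(flat, cl_typ * exp(eta1), pop$v_pop * exp(eta2),
                   pop$ka_pop)
    dv <- f * (1 + pop$err_prop * stats::rnorm(length(f))) +
      pop$err_add * stats::rnorm(length(f))
    out[, r] <- pmax(dv, 0)
  }
  out
}

#' @export
plot.pkfit <- function(x, ...) {
  pr <- predict(x, type = "individual")
  pp <- predict(x, type = "population")
  oldpar <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  lim <- range(c(pr$dv, pr$pred, pp$pred), na.rm = TRUE)
  graphics::plot(pp$pred, pp$dv, xlim = lim, ylim = lim,
                 xlab = "Population prediction (mg/L)",
                 ylab = "Observed (mg/L)", main = "Population", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(pr$pred, pr$dv, xlim = lim, ylim = lim,
                 xlab = "Individual prediction (mg/L)",
                 ylab = "Observed (mg/L)", main = "Individual", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Likelihood-ratio test for one nested covariate effect
#'
#' Refits the model with one additional free parameter (a currently
#' fixed built-in parameter such as `cov_alb`, or a [pk_covariate()]
#' effect) and compares -2 log-likelihoods against a chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param cohort A [pk_cohort].
#' @param base_fit A `pkfit` for the base (smaller) model.
#' @param candidate Either a parameter name present in `base_fit$fixed`
#'   (it is freed) or a [pk_covariate()] (it is added).
#' @param alpha Significance threshold (default 0.01).
#' @param control Optional [pk_control()]; defaults to the base fit's.
#' @return List with `delta_ofv`, `p_value`, `accepted`, and the
#'   `extended` fit.
#' @export
covariate_lrt <- function(cohort, base_fit, candidate, alpha = 0.01,
                          control = NULL) {
  stopifnot(inherits(base_fit, "pkfit"))
  if (is.null(control)) control <- base_fit$control
  control$compute_rse <- FALSE
  start <- base_fit$estimates
  covs <- base_fit$estimates$cov_effects
  covs_arg <- if (is.null(covs)) list() else .effects_to_covariates(base_fit)
  if (inherits(candidate, "pk_covariate")) {
    covs_arg <- c(covs_arg, list(candidate))
    fixed <- base_fit$fixed
  } else if (is.character(candidate) && length(candidate) == 1L) {
    if (!candidate %in% base_fit$fixed) {
      stop("configuration error: candidate '", candidate,
           "' is not fixed in the base model (non-nested)", call. = FALSE)
    }
    fixed <- setdiff(base_fit$fixed, candidate)
  } else {
    stop("configuration error: candidate must be a parameter name or a ",
         "pk_covariate", call. = FALSE)
  }
  ext <- pkfit(cohort, start = .strip_effects(start), priors = base_fit$priors,
               fixed = fixed, covariates = covs_arg,
               use_held_out = base_fit$use_held_out, control = control)
  delta <- max(base_fit$ofv - ext$ofv, 0)
  p <- stats::pchisq(delta, df = 1, lower.tail = FALSE)
  list(delta_ofv = delta, p_value = p, accepted = p < alpha,
       extended = ext)
}

.effects_to_covariates <- function(fit) {
  pop <- fit$estimates
  lapply(pop$cov_effects, function(eff) {
    pk_covariate(eff$name, eff$form, ref = eff$ref,
                 start = pop$betas[[paste0("beta_", eff$name)]])
  })
}

.strip_effects <- function(pop) {
  pop$cov_effects <- NULL
  pop$betas <- NULL
  pop
}

#' Stepwise forward-addition / backward-elimination covariate search
#'
#' Forward step: among the remaining candidates, repeatedly add the one
#' with the smallest likelihood-ratio p-value below `alpha` (ties broken
#' by declaration order). Backward step: repeatedly remove the included
#' effect whose deletion gives the largest p-value above `alpha`.
#' Deterministic given the data.
#'
#' @param cohort A [pk_cohort].
#' @param base_fit A `pkfit` for the covariate-free model.
#' @param candidates Named list of candidates, each a fixed-parameter
#'   name or a [pk_covariate()].
#' @param alpha Threshold for both directions (default 0.01).
#' @param control Optional [pk_control()].
#' @return List with `fit` (selected model), `selected` (names) and
#'   `trace` (data frame of tested steps).
#' @export
stepwise_covariate_search <- function(cohort, base_fit, candidates,
                                      alpha = 0.01, control = NULL) {
  stopifnot(inherits(base_fit, "pkfit"))
  if (length(candidates) == 0L) {
    return(list(fit = base_fit, selected = character(0),
                trace = data.frame()))
  }
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- vapply(candidates, function(cd) {
      if (inherits(cd, "pk_covariate")) cd$name else cd
    }, character(1))
  }
  current <- base_fit
  remaining <- names(candidates)
  selected <- character(0)
  trace <- list()
  repeat {   # forward
    if (length(remaining) == 0L) break
    tests <- lapply(remaining, function(nm) {
      covariate_lrt(cohort, current, candidates[[nm]], alpha, control)
    })
    pvals <- vapply(tests, `[[`, numeric(1), "p_value")
    for (i in seq_along(remaining)) {
      trace[[length(trace) + 1L]] <- data.frame(
        phase = "forward", candidate = remaining[i],
        delta_ofv = tests[[i]]$delta_ofv, p_value = pvals[i])
    }
    best <- which.min(pvals)   # first index wins ties (declaration order)
    if (pvals[best] >= alpha) break
    current <- tests[[best]]$extended
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  repeat {   # backward
    if (length(selected) == 0L) break
    drops <- lapply(selected, function(nm) {
      .drop_effect(cohort, current, candidates[[nm]], control)
    })
    ## deleting an effect raises the OFV of the larger model by delta_ofv
    pvals <- stats::pchisq(pmax(vapply(drops, `[[`, numeric(1), "ofv") -
                                  current$ofv, 0),
                           df = 1, lower.tail = FALSE)
    for (i in seq_along(selected)) {
      trace[[length(trace) + 1L]] <- data.frame(
        phase = "backward", candidate = selected[i],
        delta_ofv = drops[[i]]$ofv - current$ofv, p_value = pvals[i])
    }
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    current <- drops[[worst]]
    selected <- selected[-worst]
  }
  list(fit = current, selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else data.frame())
}

.drop_effect <- function(cohort, fit, candidate, control = NULL) {
  if (is.null(control)) control <- fit$control
  control$compute_rse <- FALSE
  start <- fit$estimates
  if (inherits(candidate, "pk_covariate")) {
    keep <- vapply(start$cov_effects, function(e) e$name != candidate$name,
                   logical(1))
    covs <- .effects_to_covariates(fit)[keep]
    pkfit(cohort, start = .strip_effects(start), priors = fit$priors,
          fixed = fit$fixed, covariates = covs,
          use_held_out = fit$use_held_out, control = control)
  } else {
    start[[candidate]] <- 0
    covs <- if (is.null(start$cov_effects)) list()
            else .effects_to_covariates(fit)
    pkfit(cohort, start = .strip_effects(start), priors = fit$priors,
          fixed = c(fit$fixed, candidate), covariates = covs,
          use_held_out = fit$use_held_out, control = control)
  }
}

#' Case-resampling bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original cohort size,
#' refits the model on each replicate (initialised at the original
#' estimates; subject multiplicities enter the likelihood as weights),
#' and summarises each free parameter by mean, percent RSE and
#' percentile 95% interval. Non-converged replicates are excluded and
#' counted. Fully reproducible under a fixed seed.
#'
#' @param fit A `pkfit`.
#' @param n_reps Number of replicates (default 500).
#' @param seed Integer seed (mandatory).
#' @param control Optional [pk_control()]; standard errors are switched
#'   off for replicates regardless.
#' @return Object of class `pk_bootstrap`: `estimates` (replicates x
#'   parameters), `summary` data frame, `indices` (resampled subject
#'   indices), `n_excluded`, `seed`.
#' @export
bootstrap_fit <- function(fit, n_reps = 500L, seed, control = NULL) {
  stopifnot(inherits(fit, "pkfit"), n_reps >= 1L)
  if (missing(seed)) stop("seed is required for bootstrap_fit", call. = FALSE)
  if (is.null(control)) control <- fit$control
  control$compute_rse <- FALSE
  control$polish_maxit <- 0L
  ## replicates start at the original optimum; looser tolerances are
  ## ample against the bootstrap sampling spread
  control$outer_reltol <- max(control$outer_reltol, 1e-6)
  control$inner_tol <- max(control$inner_tol, 1e-6)
  control$inner_maxit <- min(control$inner_maxit, 50L)
  control$outer_maxit <- min(control$outer_maxit, 80L)
  set.seed(seed)
  flat <- .flatten_cohort(fit$cohort, use_held_out = fit$use_held_out)
  n <- flat$n
  idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), n, n_reps)
  covs <- if (is.null(fit$estimates$cov_effects)) list()
          else .effects_to_covariates(fit)
  start <- .strip_effects(fit$estimates)
  est <- matrix(NA_real_, n_reps, length(fit$free),
                dimnames = list(NULL, fit$free))
  conv <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    w <- tabulate(idx[, r], nbins = n)
    sub <- .subset_flat(flat, which(w > 0))
    repfit <- tryCatch(
      .fit_engine(sub$flat, start, fit$priors, fit$fixed, covs, control,
                  weights = w[sub$keep],
                  eta_init = fit$ebes[sub$keep, , drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(repfit)) {
      conv[r] <- repfit$converged
      est[r, ] <- vapply(fit$free, function(nm) {
        p <- repfit$estimates
        if (startsWith(nm, "beta_")) p$betas[[nm]] else p[[nm]]
      }, numeric(1))
    }
  }
  ok <- conv & stats::complete.cases(est)
  used <- est[ok, , drop = FALSE]
  summ <- data.frame(
    mean = colMeans(used),
    rse_pct = 100 * apply(used, 2, stats::sd) / abs(colMeans(used)),
    lo95 = apply(used, 2, stats::quantile, 0.025),
    hi95 = apply(used, 2, stats::quantile, 0.975),
    row.names = colnames(used))
  structure(list(estimates = est, converged = conv, summary = summ,
                 indices = idx, n_reps = n_reps,
                 n_excluded = sum(!ok), seed = seed,
                 point = vapply(fit$free, function(nm) {
                   p <- fit$estimates
                   if (startsWith(nm, "beta_")) p$betas[[nm]] else p[[nm]]
                 }, numeric(1))),
            class = "pk_bootstrap")
}

.subset_flat <- function(flat, keep) {
  map <- integer(flat$n); map[keep] <- seq_along(keep)
  obs_keep <- flat$obs_subj %in% keep
  pair_keep <- flat$pair_subj %in% keep
  old_obs_idx <- which(obs_keep)
  obs_map <- integer(length(flat$y)); obs_map[old_obs_idx] <- seq_along(old_obs_idx)
  list(flat = .index_flat(list(
    n = length(keep), ids = flat$ids[keep],
    y = flat$y[obs_keep], obs_subj = map[flat$obs_subj[obs_keep]],
    obs_time = flat$obs_time[obs_keep], held = flat$held[obs_keep],
    pair_obs = obs_map[flat$pair_obs[pair_keep]],
    pair_subj = map[flat$pair_subj[pair_keep]],
    pair_amt = flat$pair_amt[pair_keep],
    pair_tau = flat$pair_tau[pair_keep],
    alb = flat$alb[keep], aaa = flat$aaa[keep],
    extras = flat$extras[keep, , drop = FALSE])),
    keep = keep)
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d excluded as non-converged), seed %d\n",
              x$n_reps, x$n_excluded, x$seed))
  print(x$summary, digits = 4)
  invisible(x)
}
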