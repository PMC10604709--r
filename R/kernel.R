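# Internal fitting kernel.
#
# The population objective requires, at every trial value of the fixed
# effects, the posterior mode of the two random effects of every subject
# plus the log-determinant of the curvature there (Laplace
# approximation). To keep this affordable in pure R the kernel is
# batched: all subjects' random effects are updated simultaneously with
# vectorised evaluations of the likelihood and its analytic derivatives,
# and the curvature from the final Newton iteration feeds the Laplace
# determinant.

# Flatten a cohort into the vectors the batched likelihood needs.
# Pairs are (observation, earlier dose) combinations; superposition sums
# pair contributions per observation.
.flatten_cohort <- function(cohort, use_held_out = TRUE) {
  .flatten_from_subjects(cohort_subjects(cohort), use_held_out)
}

.flatten_from_subjects <- function(subjects, use_held_out = TRUE) {
  n <- length(subjects)
  y <- numeric(0); obs_subj <- integer(0); obs_time <- numeric(0)
  held <- logical(0)
  pair_obs <- integer(0); pair_subj <- integer(0)
  pair_amt <- numeric(0); pair_tau <- numeric(0)
  alb <- numeric(n); aaa <- numeric(n)
  extra_names <- names(subjects[[1]]$covariates)
  extras <- matrix(NA_real_, n, length(extra_names),
                   dimnames = list(NULL, extra_names))
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    obs <- s$obs
    if (!use_held_out) obs <- obs[!obs$held_out, , drop = FALSE]
    m <- nrow(obs)
    alb[i] <- s$alb; aaa[i] <- s$aaa
    if (length(extra_names)) extras[i, ] <- unlist(s$covariates)
    if (m == 0L) next
    o0 <- length(y)
    y <- c(y, obs$dv); obs_subj <- c(obs_subj, rep.int(i, m))
    obs_time <- c(obs_time, obs$time); held <- c(held, obs$held_out)
    if (nrow(s$doses) > 0L) {
      tau <- outer(obs$time, s$doses$time, "-")
      sel <- which(tau > 0)
      if (length(sel)) {
        oi <- ((sel - 1L) %% m) + 1L
        di <- ((sel - 1L) %/% m) + 1L
        pair_obs <- c(pair_obs, o0 + oi)
        pair_subj <- c(pair_subj, rep.int(i, length(sel)))
        pair_amt <- c(pair_amt, s$doses$amt[di])
        pair_tau <- c(pair_tau, tau[sel])
      }
    }
  }
  .index_flat(list(n = n, ids = names(subjects), y = y,
                   obs_subj = obs_subj, obs_time = obs_time, held = held,
                   pair_obs = pair_obs, pair_subj = pair_subj,
                   pair_amt = pair_amt, pair_tau = pair_tau,
                   alb = alb, aaa = aaa, extras = extras))
}

# Precompute contiguous-run indices so group sums reduce to cumsum
# differences (pairs are sorted by observation; observations arrive
# grouped by subject).
.index_flat <- function(flat) {
  ord <- order(flat$pair_obs)
  flat$pair_obs <- flat$pair_obs[ord]
  flat$pair_subj <- flat$pair_subj[ord]
  flat$pair_amt <- flat$pair_amt[ord]
  flat$pair_tau <- flat$pair_tau[ord]
  p <- flat$pair_obs
  if (length(p)) {
    ends <- c(which(p[-1] != p[-length(p)]), length(p))
    flat$pair_run_ends <- ends
    flat$pair_run_obs <- p[ends]
  } else {
    flat$pair_run_ends <- integer(0)
    flat$pair_run_obs <- integer(0)
  }
  s <- flat$obs_subj
  if (length(s)) {
    ends <- c(which(s[-1] != s[-length(s)]), length(s))
    flat$obs_run_ends <- ends
    flat$obs_run_subj <- s[ends]
  } else {
    flat$obs_run_ends <- integer(0)
    flat$obs_run_subj <- integer(0)
  }
  ## observations no dose can reach (structurally zero prediction)
  flat$obs_no_dose <- setdiff(seq_along(flat$y), flat$pair_run_obs)
  flat$cache <- new.env(parent = emptyenv())
  flat
}

# An observation before any dose has prediction 0 for every parameter
# value: under a proportional-only error model its likelihood is
# degenerate, which is a data/configuration problem, not a numerical
# one.
.check_structural_zero <- function(flat, pop) {
  if (pop$err_add == 0 && length(flat$obs_no_dose) > 0L) {
    stop("zero residual SD: ", length(flat$obs_no_dose),
         " observation(s) precede any dose, so their prediction is 0 ",
         "under a proportional-only error model", call. = FALSE)
  }
  invisible(TRUE)
}

# Typical clearance per subject, including optional extra covariate
# effects (used by the stepwise covariate search).
.typical_cl <- function(flat, pop) {
  cl <- covariate_clearance(pop$cl_pop, flat$aaa, pop$cov_aaa, flat$alb,
                            pop$m_alb, pop$cov_alb)
  if (!is.null(pop$cov_effects) && length(pop$cov_effects)) {
    for (eff in pop$cov_effects) {
      x <- flat$extras[, eff$name]
      beta <- pop$betas[[paste0("beta_", eff$name)]]
      cl <- cl * if (eff$form == "power") (x / eff$ref)^beta else 1 + beta * x
    }
  }
  cl
}

# Concentrations at all observation rows, given per-subject cl and v.
.conc_all <- function(flat, cl, v, ka) {
  f <- numeric(length(flat$y))
  if (length(flat$pair_obs) == 0L) return(f)
  ke <- cl / v
  ke_p <- ke[flat$pair_subj]
  v_p <- v[flat$pair_subj]
  cache <- flat$cache
  if (is.null(cache$ka) || cache$ka != ka) {
    cache$ka <- ka
    cache$eka <- exp(-ka * flat$pair_tau)
  }
  d <- ka - ke_p
  small <- abs(d) < 1e-8 * ka
  contrib <- flat$pair_amt * ka / (v_p * d) *
    (exp(-ke_p * flat$pair_tau) - cache$eka)
  if (any(small)) {
    ## series expansion around ka = ke, first order in (ka - ke) tau
    contrib[small] <- (flat$pair_amt * ka * flat$pair_tau * cache$eka *
                         (1 + d * flat$pair_tau / 2) / v_p)[small]
  }
  block <- diff(c(0, cumsum(contrib)[flat$pair_run_ends]))
  f[flat$pair_run_obs] <- block
  f
}

# Per-subject joint log-likelihood of data and random effects, batched
# over subjects. Returns a length-n vector.
.ll_all <- function(flat, pop, cl_typ, eta1, eta2) {
  cl <- cl_typ * exp(eta1)
  v <- pop$v_pop * exp(eta2)
  f <- .conc_all(flat, cl, v, pop$ka_pop)
  ## floored to guard exp() underflow at extreme random effects;
  ## structurally zero predictions are rejected at solver entry
  s <- pmax(pop$err_add + pop$err_prop * f, 1e-10)
  r <- (flat$y - f) / s
  ll_obs <- -0.918938533204672742 - log(s) - 0.5 * r * r  # log dnorm
  ll <- numeric(flat$n)
  if (length(ll_obs)) {
    ll[flat$obs_run_subj] <- diff(c(0, cumsum(ll_obs)[flat$obs_run_ends]))
  }
  ll - 0.5 * (eta1^2 / pop$omega_cl^2 + eta2^2 / pop$omega_v^2) -
    1.83787706640934548 - log(pop$omega_cl) - log(pop$omega_v)
}

# Joint log-likelihood with exact analytic gradient and Hessian in
# (eta_cl, eta_v), batched over subjects.
#
# For one dose-observation pair, writing K = D ka / V, delta = ka - ke,
# q(ke) = (e^{-ke tau} - e^{-ka tau}) / delta, the pair concentration is
# A = K q, and because ke scales with exp(eta_cl - eta_v) and V with
# exp(eta_v), the eta-derivatives collapse to combinations of q, q' and
# q'': A1 = K q' ke, A2 = -A - A1, A11 = K(q'' ke^2 + q' ke),
# A12 = -A11 - A1, A22 = A + A11 + 2 A1 (subscript 1 = d/d eta_cl,
# 2 = d/d eta_v). Near ke = ka the limits q = tau e^{-ka tau},
# q' = -tau^2 e^{-ka tau} / 2, q'' = tau^3 e^{-ka tau} / 3 are used.
# Gaussian observation terms with SD s = a + b f then contribute
# dl/df = (r + b(r^2 - 1))/s and
# d2l/df2 = -[(1 + b r)(1 + 2 b r) + b(r + b(r^2 - 1))]/s^2,
# r = (y - f)/s, chained through f's eta-derivatives.
.ll_grad_hess <- function(flat, pop, cl_typ, eta1, eta2) {
  n <- flat$n
  cl <- cl_typ * exp(eta1)
  v <- pop$v_pop * exp(eta2)
  ka <- pop$ka_pop
  N <- length(flat$y)
  f <- f1 <- f11 <- numeric(N)
  if (length(flat$pair_obs)) {
    ke <- cl / v
    ke_p <- ke[flat$pair_subj]
    v_p <- v[flat$pair_subj]
    tau <- flat$pair_tau
    cache <- flat$cache
    if (is.null(cache$ka) || cache$ka != ka) {
      cache$ka <- ka
      cache$eka <- exp(-ka * tau)
    }
    bx <- cache$eka
    ax <- exp(-ke_p * tau)
    dlt0 <- ka - ke_p
    dlt <- dlt0
    small <- abs(dlt) < 1e-8 * ka
    if (any(small)) dlt[small] <- 1   # placeholder, overwritten below
    q0 <- (ax - bx) / dlt
    q1 <- (q0 - tau * ax) / dlt
    q2 <- (tau^2 * ax + 2 * (q0 - tau * ax) / dlt) / dlt
    if (any(small)) {
      q0[small] <- (tau * bx * (1 + dlt0 * tau / 2))[small]
      q1[small] <- (-tau^2 * bx / 2)[small]
      q2[small] <- (tau^3 * bx / 3)[small]
    }
    K <- flat$pair_amt * ka / v_p
    A <- K * q0
    A1 <- K * q1 * ke_p
    A11 <- K * (q2 * ke_p^2 + q1 * ke_p)
    ends <- flat$pair_run_ends; oi <- flat$pair_run_obs
    f[oi] <- diff(c(0, cumsum(A)[ends]))
    f1[oi] <- diff(c(0, cumsum(A1)[ends]))
    f11[oi] <- diff(c(0, cumsum(A11)[ends]))
  }
  f2 <- -f - f1
  f12 <- -f11 - f1
  f22 <- f + f11 + 2 * f1
  s <- pmax(pop$err_add + pop$err_prop * f, 1e-10)
  b <- pop$err_prop
  r <- (flat$y - f) / s
  lf <- (r + b * (r^2 - 1)) / s
  lff <- -((1 + b * r) * (1 + 2 * b * r) + b * (r + b * (r^2 - 1))) / s^2
  ll_o <- -0.918938533204672742 - log(s) - 0.5 * r * r
  ## expected information per observation: E[-d2l/df2] = (1 + 2 b^2)/s^2
  fisher <- (1 + 2 * b * b) / (s * s)
  bs_ <- function(x) {
    out <- numeric(n)
    if (length(x)) {
      out[flat$obs_run_subj] <- diff(c(0, cumsum(x)[flat$obs_run_ends]))
    }
    out
  }
  ll <- bs_(ll_o) -
    0.5 * (eta1^2 / pop$omega_cl^2 + eta2^2 / pop$omega_v^2) -
    1.83787706640934548 - log(pop$omega_cl) - log(pop$omega_v)
  g1 <- bs_(lf * f1) - eta1 / pop$omega_cl^2
  g2 <- bs_(lf * f2) - eta2 / pop$omega_v^2
  list(ll = ll, g1 = g1, g2 = g2,
       ## observed negative Hessian (fast Newton steps near the mode)
       a11 = 1 / pop$omega_cl^2 - bs_(lff * f1 * f1 + lf * f11),
       a12 = -bs_(lff * f1 * f2 + lf * f12),
       a22 = 1 / pop$omega_v^2 - bs_(lff * f2 * f2 + lf * f22),
       ## expected (Fisher) curvature: positive definite by construction
       e11 = 1 / pop$omega_cl^2 + bs_(fisher * f1 * f1),
       e12 = bs_(fisher * f1 * f2),
       e22 = 1 / pop$omega_v^2 + bs_(fisher * f2 * f2))
}

# Batched Newton maximisation of the per-subject joint log-likelihood
# over (eta_cl, eta_v), using the exact gradient and Hessian. Steps in
# the quadratic regime are taken unconditionally; larger steps are
# safeguarded by backtracking on the exact log-likelihood. The returned
# curvature is the exact negative Hessian at the solution, reused for
# the Laplace determinant.
.ebe_solve <- function(flat, pop, cl_typ, eta_init = NULL,
                       tol = 1e-8, maxit = 100L) {
  .check_structural_zero(flat, pop)
  n <- flat$n
  e1 <- if (is.null(eta_init)) numeric(n) else eta_init[, 1]
  e2 <- if (is.null(eta_init)) numeric(n) else eta_init[, 2]
  L <- function(a, b) .ll_all(flat, pop, cl_typ, a, b)
  gh <- .ll_grad_hess(flat, pop, cl_typ, e1, e2)
  frozen <- rep(FALSE, n)
  conv <- rep(FALSE, n)
  for (iter in seq_len(maxit)) {
    det <- gh$a11 * gh$a22 - gh$a12^2
    pd <- gh$a11 > 0 & det > 0
    ## observed-Hessian Newton step where positive definite, scoring
    ## step (Fisher curvature, always PD) elsewhere
    edet <- gh$e11 * gh$e22 - gh$e12^2
    d1 <- ifelse(pd, (gh$a22 * gh$g1 - gh$a12 * gh$g2) / det,
                 (gh$e22 * gh$g1 - gh$e12 * gh$g2) / edet)
    d2 <- ifelse(pd, (gh$a11 * gh$g2 - gh$a12 * gh$g1) / det,
                 (gh$e11 * gh$g2 - gh$e12 * gh$g1) / edet)
    conv <- pmax(abs(gh$g1), abs(gh$g2)) <= tol
    ## a vanishing Newton step cannot move the objective further even
    ## when the gradient scale is still large (razor-thin likelihoods):
    ## such subjects stop iterating but stay flagged non-converged
    need <- !frozen & !conv & pmax(abs(d1), abs(d2)) > 1e-12
    if (!any(need)) break
    ## cap the step to keep exp() in range for pathological starts
    sc <- pmax(1, pmax(abs(d1), abs(d2)) / 2)
    d1 <- d1 / sc; d2 <- d2 / sc
    d1[!need] <- 0; d2[!need] <- 0
    ## tiny steps are taken unconditionally (objective comparisons
    ## there sit at rounding level and must not veto the step)
    small_step <- pmax(abs(d1), abs(d2)) <= 1e-4
    f0 <- gh$ll
    step <- rep(1, n)
    fnew <- f0
    ## deep backtracking: razor-thin likelihoods (near-zero residual
    ## error) may need microscopic steps before the ascent direction
    ## pays off
    for (h in 1:30) {
      fnew <- L(e1 + step * d1, e2 + step * d2)
      worse <- need & !small_step &
        (fnew < f0 - 1e-12 | !is.finite(fnew))
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    ## subjects the backtracking cannot improve even at the minimal
    ## step are frozen where they stand (numerical optimum)
    stuck <- need & !small_step & (fnew < f0 - 1e-12 | !is.finite(fnew))
    frozen <- frozen | stuck
    take <- need & !stuck
    if (!any(take)) break
    e1[take] <- e1[take] + (step * d1)[take]
    e2[take] <- e2[take] + (step * d2)[take]
    gh <- .ll_grad_hess(flat, pop, cl_typ, e1, e2)
  }
  list(eta = cbind(eta_cl = e1, eta_v = e2),
       grad = cbind(gh$g1, gh$g2),
       hess = .blend_curvature(gh),
       obs_hess = cbind(a11 = gh$a11, a22 = gh$a22, a12 = gh$a12),
       ll = gh$ll,
       converged = conv)
}

# Curvature used for the Laplace determinant. The observed negative
# Hessian is the accurate (unbiased) choice, but for sparse subjects it
# can approach singularity at the mode, where its log-determinant
# diverges and would carve an artificial well into the marginal
# likelihood for the outer optimizer to mine. Its eigenvalues are
# therefore passed through a C1 floor scaled by the expected (Fisher)
# information's smallest eigenvalue lF (positive by construction):
# exact above 0.1 lF, saturating smoothly at 0.05 lF below. Subjects
# with a healthy observed Hessian - the overwhelming majority - are
# untouched, so no bias is introduced.
.blend_curvature <- function(gh, delta = 0.05) {
  lmin2 <- function(a, d, b) {
    tr <- a + d
    tr / 2 - sqrt(pmax(tr^2 / 4 - (a * d - b^2), 0))
  }
  eps <- delta * lmin2(gh$e11, gh$e22, gh$e12)
  tr <- gh$a11 + gh$a22
  disc <- sqrt(pmax(tr^2 / 4 - (gh$a11 * gh$a22 - gh$a12^2), 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  phi <- function(l) ifelse(l >= 2 * eps, l,
                            eps + eps * exp(pmin((l - 2 * eps) / eps, 0)))
  p1 <- phi(l1); p2 <- phi(l2)
  s <- (p1 + p2) / 2
  m <- ifelse(disc > 1e-12, (p1 - p2) / (2 * disc), 0)
  cbind(a11 = s + m * (gh$a11 - tr / 2),
        a22 = s + m * (gh$a22 - tr / 2),
        a12 = m * gh$a12)
}

# Per-subject -2 log marginal likelihood contributions by Laplace
# approximation: -2 ll(eta_hat) + log det(A) - d log(2 pi), with A the
# expected-information curvature at the mode (positive definite by
# construction; the eigenvalue floor is a belt-and-braces guard).
.laplace_terms <- function(sol) {
  a11 <- sol$hess[, "a11"]; a22 <- sol$hess[, "a22"]; a12 <- sol$hess[, "a12"]
  tr <- a11 + a22
  det <- a11 * a22 - a12^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  lmin <- tr / 2 - disc
  floor_ <- 1e-8
  bad <- lmin < floor_
  if (any(bad)) {
    warning(sum(bad), " subject(s) with non-positive-definite curvature; ",
            "eigenvalue floor applied", call. = FALSE)
    shift <- (floor_ - lmin[bad])
    a11[bad] <- a11[bad] + shift
    a22[bad] <- a22[bad] + shift
    det <- a11 * a22 - a12^2
  }
  -2 * sol$ll + log(det) - 2 * 1.83787706640934548
}

# Warm-startable Laplace -2LL over a flattened cohort; `weights` are
# subject multiplicities (bootstrap resampling).
.laplace_ofv_flat <- function(flat, pop, eta_init = NULL, weights = NULL,
                              tol = 1e-8, maxit = 100L) {
  cl_typ <- .typical_cl(flat, pop)
  sol <- .ebe_solve(flat, pop, cl_typ, eta_init, tol = tol, maxit = maxit)
  terms <- .laplace_terms(sol)
  ofv <- if (is.null(weights)) sum(terms) else sum(weights * terms)
  list(ofv = ofv, sol = sol)
}
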