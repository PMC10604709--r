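test_that("empirical Bayes estimates shrink to the population without data", {
  pop <- final_params()
  s <- cohort_subjects(toy_cohort())$A
  s$obs <- s$obs[0, ]
  ebe <- estimate_ebe(s, pop)
  expect_equal(unname(ebe$eta), c(0, 0))
  expect_true(ebe$converged)
})

test_that("empirical Bayes estimates recover simulated random effects", {
  ## rich design, near-noiseless data: the posterior mode pins the truth
  pop <- pk_pop_params(cl_pop = 0.0312, v_pop = 7.76, cov_alb = -2.33,
                       omega_cl = 0.667, omega_v = 0.477,
                       err_prop = 0.01)
  doses <- data.frame(time = c(0, 336, 672, 1008, 1344),
                      amt = c(160, 80, 40, 40, 40))
  times <- seq(48, 1650, length.out = 20)
  set.seed(31)
  for (k in 1:5) {
    eta <- c(stats::rnorm(1, 0, 0.5), stats::rnorm(1, 0, 0.4))
    p <- individual_params(pop, eta, 3.5, 0)
    f <- conc_profile(times, doses, p$cl, p$v, p$ka)
    dv <- f * (1 + pop$err_prop * stats::rnorm(length(f)))
    s <- structure(list(id = "X", doses = doses,
                        obs = data.frame(time = times, dv = dv,
                                         held_out = FALSE),
                        alb = 3.5, aaa = 0, covariates = list()),
                   class = "pk_subject")
    ebe <- estimate_ebe(s, pop)
    expect_true(ebe$converged)
    expect_lt(max(abs(ebe$eta - eta)), 0.02)
    expect_lt(ebe$grad_norm, 1e-8)
  }
})

test_that("a low trough inflates the individual clearance estimate", {
  pop <- final_params()
  s <- cohort_subjects(toy_cohort())$A
  p <- individual_params(pop, c(0, 0), s$alb, s$aaa)
  f <- conc_profile(s$obs$time, s$doses, p$cl, p$v, p$ka)
  s$obs$dv <- f / 5    # far below the typical prediction
  ebe <- estimate_ebe(s, pop)
  expect_gt(ebe$eta["eta_cl"], 0)
})

test_that("Laplace marginal matches 2-d quadrature on a single subject", {
  ## additive-error subject with one observation; at small omega the
  ## model is near-linear in eta and the Laplace approximation is exact
  ## to high order
  mk_pop <- function(om) {
    pk_pop_params(cl_pop = 0.0312, v_pop = 7.76, omega_cl = om,
                  omega_v = om, err_add = 1.2, err_prop = 0)
  }
  d <- data.frame(ID = "A", TIME = c(0, 336), AMT = c(160, NA),
                  DV = c(NA, 9.1), EVID = c(1, 0), ALB = 3.77, AAA = 0)
  co <- pk_cohort(d)
  s <- cohort_subjects(co)$A
  near_linear <- mk_pop(5e-4)
  expect_lt(abs(laplace_ofv(co, near_linear) /
                  quadrature_ofv(s, near_linear) - 1), 1e-6)
  ## at a realistic omega the approximation stays within a few percent
  ## (expected-information curvature; see the methods vignette)
  realistic <- mk_pop(0.5)
  expect_lt(abs(laplace_ofv(co, realistic) /
                  quadrature_ofv(s, realistic) - 1), 0.06)
})

test_that("the marginal -2LL is additive over subjects", {
  pop <- final_params()
  sim <- sim_sparse(n = 8, seed = 9)
  co <- sim$cohort
  total <- laplace_ofv(co, pop)
  parts <- vapply(unique(co$data$ID), function(id) {
    laplace_ofv(pk_cohort(co$data[co$data$ID == id, ], validate = FALSE),
                pop)
  }, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-10)
  ## duplicating every subject doubles the OFV
  d2 <- co$data
  d2$ID <- paste0(d2$ID, "_copy")
  both <- pk_cohort(rbind(co$data, d2), validate = FALSE)
  expect_equal(laplace_ofv(both, pop), 2 * total, tolerance = 1e-10)
})

test_that("the OFV has a local minimum at the generating parameters", {
  pop <- final_params()
  sim <- simulate_cohort(cohort_design(n_subjects = 150,
                                       rich_design = TRUE, seed = 77), pop)
  f0 <- laplace_ofv(sim$cohort, pop)
  for (fac in c(0.7, 1.4)) {
    up <- pop; up$cl_pop <- pop$cl_pop * fac
    expect_gt(laplace_ofv(sim$cohort, up), f0)
  }
})

test_that("MAP degenerates correctly at the prior extremes", {
  sim <- sim_sparse(n = 40, seed = 12)
  ctrl <- pk_control(compute_rse = FALSE)
  plain <- pkfit(sim$cohort, control = ctrl)
  ## near-zero prior uncertainty pins the parameter at the prior mean
  tight <- pkfit(sim$cohort,
                 priors = pk_priors("omega_cl", 0.65, 1e-6),
                 control = ctrl)
  expect_lt(abs(tight$estimates$omega_cl / 0.65 - 1), 1e-3)
  ## a vague prior changes nothing
  vague <- pkfit(sim$cohort,
                 priors = pk_priors("omega_cl", 0.65, 1e6),
                 control = ctrl)
  expect_lt(abs(vague$ofv - plain$ofv), 1e-6)
})

test_that("refitting from a fit's own optimum leaves the OFV unchanged", {
  sim <- sim_sparse(n = 30, seed = 13)
  ctrl <- pk_control(compute_rse = FALSE)
  fit1 <- pkfit(sim$cohort, control = ctrl)
  fit2 <- pkfit(sim$cohort, start = fit1$estimates, control = ctrl)
  expect_lt(abs(fit2$ofv - fit1$ofv), 1e-4)
})

test_that("fixing every parameter makes the fit a pure evaluation", {
  sim <- sim_sparse(n = 10, seed = 14)
  allp <- c("cl_pop", "v_pop", "ka_pop", "cov_aaa", "cov_alb",
            "omega_cl", "omega_v", "err_add", "err_prop")
  fit <- pkfit(sim$cohort, fixed = allp)
  expect_equal(fit$ofv, laplace_ofv(sim$cohort, final_params()))
  expect_true(all(is.na(fit$rse)) && length(fit$rse) == 0)
  expect_true(fit$converged)
})

test_that("likelihood-ratio test is calibrated and guards nesting", {
  ## no albumin variation: freeing the albumin exponent cannot help
  d <- cohort_design(n_subjects = 25, seed = 21)
  sim <- simulate_cohort(d, final_params())
  dat <- sim$cohort$data
  dat$ALB <- 3.77
  co <- pk_cohort(dat, validate = FALSE)
  ctrl <- pk_control(compute_rse = FALSE)
  base <- pkfit(co, start = pk_pop_params(cl_pop = 0.03, v_pop = 7.8,
                                          omega_cl = 0.65, omega_v = 0.48,
                                          err_prop = 0.55),
                fixed = c("ka_pop", "cov_aaa", "cov_alb"), control = ctrl)
  lrt <- covariate_lrt(co, base, "cov_alb", control = ctrl)
  expect_lt(lrt$delta_ofv, 0.5)
  expect_gt(lrt$p_value, 0.4)
  expect_false(lrt$accepted)
  ## a candidate that is already free is non-nested
  expect_error(covariate_lrt(co, lrt$extended, "cov_alb"), "non-nested")
})

test_that("stepwise search selects the real covariate and not a decoy", {
  d <- cohort_design(n_subjects = 80, rich_design = TRUE, seed = 5)
  sim <- simulate_cohort(d, final_params())
  dat <- sim$cohort$data
  set.seed(99)
  wt <- stats::setNames(stats::rnorm(length(unique(dat$ID)), 70, 12),
                        unique(dat$ID))
  dat$WT <- wt[dat$ID]
  co <- pk_cohort(dat, validate = FALSE)
  ctrl <- pk_control(compute_rse = FALSE)
  base <- pkfit(co, start = pk_pop_params(cl_pop = 0.03, v_pop = 7.8,
                                          omega_cl = 0.65, omega_v = 0.48,
                                          err_prop = 0.55),
                fixed = c("ka_pop", "cov_aaa", "cov_alb"), control = ctrl)
  sw <- stepwise_covariate_search(
    co, base, list(alb = "cov_alb", wt = pk_covariate("WT", "power")),
    control = ctrl)
  expect_equal(sw$selected, "alb")
  expect_true(all(c("forward", "backward") %in% sw$trace$phase))
  ## empty candidate set returns the base model untouched
  sw0 <- stepwise_covariate_search(co, base, list())
  expect_identical(sw0$fit, base)
})

test_that("bootstrap replicates preserve size and are seed-reproducible", {
  sim <- sim_sparse(n = 20, seed = 17)
  fit <- pkfit(sim$cohort, control = pk_control(compute_rse = FALSE))
  b1 <- bootstrap_fit(fit, n_reps = 3, seed = 5)
  expect_equal(dim(b1$indices), c(20, 3))
  expect_true(all(b1$indices >= 1 & b1$indices <= 20))
  b2 <- bootstrap_fit(fit, n_reps = 3, seed = 5)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$estimates, b2$estimates)
  b3 <- bootstrap_fit(fit, n_reps = 3, seed = 6)
  expect_false(identical(b1$estimates, b3$estimates))
})
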