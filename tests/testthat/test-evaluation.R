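test_that("bias and imprecision match hand arithmetic", {
  pairs <- data.frame(y_obs = c(4, 6, 10), y_pred = c(5, 5, 9))
  expect_equal(mpe(pairs), -1 / 3)
  expect_equal(rmspe(pairs), 1)
  one <- data.frame(y_obs = 8, y_pred = 10)
  expect_equal(mpe(one), 2)
  perfect <- data.frame(y_obs = 1:5, y_pred = 1:5)
  expect_equal(mpe(perfect), 0)
  expect_equal(rmspe(perfect), 0)
  ## constant error: imprecision equals absolute bias
  const <- data.frame(y_obs = 1:5, y_pred = 1:5 + 2)
  expect_equal(rmspe(const), 2)
  expect_equal(rmspe(const), abs(mpe(const)))
  expect_error(mpe(perfect[0, ]), "no prediction pairs")
  expect_error(rmspe(perfect[0, ]), "no prediction pairs")
})

test_that("imprecision dominates bias on random prediction pairs", {
  set.seed(4)
  for (k in 1:20) {
    pairs <- data.frame(y_obs = stats::runif(10, 0, 20),
                        y_pred = stats::runif(10, 0, 20))
    expect_gte(rmspe(pairs) + 1e-12, abs(mpe(pairs)))
  }
})

test_that("a held-out trough regenerated from its own EBEs is predicted
          exactly", {
  ## self-consistency: replace each held-out value by the noiseless
  ## prediction from the leave-last-out EBEs; re-running the procedure
  ## must reproduce those values (the held-out point never feeds the
  ## EBEs, so they are unchanged)
  pop <- final_params()
  sim <- simulate_cohort(cohort_design(n_subjects = 12, n_troughs = 4,
                                       seed = 55), pop)
  co <- hold_out_last(sim$cohort)
  pairs <- leave_last_out(co, pop)
  expect_equal(nrow(pairs), 12)
  held_rows <- which(co$data$HELD)
  co$data$DV[held_rows] <-
    pairs$y_pred[match(co$data$ID[held_rows], pairs$id)]
  pairs2 <- leave_last_out(co, pop)
  expect_lt(max(abs(pairs2$y_pred - pairs2$y_obs)), 1e-6)
})

test_that("leave-last-out yields one pair per subject at the study design", {
  sim <- sim_sparse(n = 54, seed = 42)
  co <- hold_out_last(sim$cohort)
  pairs <- leave_last_out(co, final_params())
  expect_equal(nrow(pairs), 54)
  expect_setequal(pairs$id, unique(co$data$ID))
  ## pairs carry the held-out observation values
  held <- co$data[co$data$HELD, ]
  expect_equal(pairs$y_obs[match(held$ID, pairs$id)], held$DV)
  expect_error(leave_last_out(sim$cohort, final_params()), "hold_out_last")
})

test_that("seeing the held-out point can only improve its prediction", {
  pop <- final_params()
  sim <- sim_sparse(n = 54, seed = 46)
  co <- hold_out_last(sim$cohort)
  pairs <- leave_last_out(co, pop)
  subjects <- cohort_subjects(co)
  with_all <- vapply(pairs$id, function(id) {
    s <- subjects[[id]]
    ebe <- estimate_ebe(s, pop, use_held_out = TRUE)
    p <- individual_params(pop, ebe$eta, s$alb, s$aaa)
    held <- s$obs[s$obs$held_out, ]
    abs(conc_profile(held$time, s$doses, p$cl, p$v, p$ka) - held$dv)
  }, numeric(1))
  expect_lte(stats::median(with_all),
             stats::median(abs(pairs$y_pred - pairs$y_obs)))
})

test_that("bootstrap performance comparison flags a constructed bias gap", {
  set.seed(8)
  truth <- stats::runif(54, 1, 15)
  good <- data.frame(y_obs = truth,
                     y_pred = truth + stats::rnorm(54, 0, 0.1))
  biased <- data.frame(y_obs = truth,
                       y_pred = truth + 3 + stats::rnorm(54, 0, 0.1))
  bp <- bootstrap_performance(list(good = good, biased = biased),
                              n_reps = 300, seed = 11)
  d <- bp$differences
  expect_true(d$mpe_significant)
  expect_lt(d$mpe_hi, 0)          # good minus biased is clearly negative
  ## identical models: the difference interval straddles zero
  same <- bootstrap_performance(list(a = good, b = good),
                                n_reps = 200, seed = 12)
  expect_equal(same$differences$mpe_diff, 0)
  expect_false(same$differences$mpe_significant)
  ## determinism under the seed
  bp2 <- bootstrap_performance(list(good = good, biased = biased),
                               n_reps = 300, seed = 11)
  expect_identical(bp$models, bp2$models)
  expect_error(bootstrap_performance(good[1, , drop = FALSE],
                                     n_reps = 10, seed = 1),
               "at least 2")
})

test_that("prediction correction is the identity on a homogeneous design", {
  ## identical covariates and doses: every observation shares the same
  ## population prediction, so the correction factor is 1
  pop <- final_params()
  d <- cohort_design(n_subjects = 20, n_troughs = 3, trough_jitter = 1e-9,
                     aaa_prevalence = 0, alb_sd = 1e-9, variant_frac = 0,
                     seed = 61)
  sim <- simulate_cohort(d, pop)
  ## force one shared trough grid deep into steady state, where the
  ## population prediction is the same at every sampled trough
  dat <- sim$cohort$data
  obs <- dat$EVID == 0
  dat$TIME[obs] <- rep(c(4031, 4367, 4703), times = 20)
  co <- pk_cohort(dat, validate = FALSE)
  v <- pcvpc(co, pop, n_sim = 50, bins = 3, seed = 62)
  pts <- attr(v, "points")
  flat_dv <- co$data$DV[co$data$EVID == 0]
  expect_equal(sort(pts$pcy), sort(flat_dv), tolerance = 1e-5)
})

test_that("prediction-corrected observations are invariant to a uniform
          rescaling of the population prediction", {
  pop <- final_params()
  sim <- sim_sparse(n = 40, seed = 63)
  v1 <- pcvpc(sim$cohort, pop, n_sim = 100, seed = 64)
  ## scaling CL/F and V/F together halves every population prediction
  ## (ke is unchanged) and must leave the corrected observations intact
  pop2 <- pop; pop2$cl_pop <- pop$cl_pop * 2; pop2$v_pop <- pop$v_pop * 2
  v2 <- pcvpc(sim$cohort, pop2, n_sim = 100, seed = 64)
  p1 <- attr(v1, "points"); p2 <- attr(v2, "points")
  expect_equal(p1$pcy, p2$pcy, tolerance = 1e-8)
})

test_that("numerical predictive check is calibrated on model-generated data", {
  pop <- final_params()
  sim <- sim_sparse(n = 54, seed = 65)
  tab <- npc(sim$cohort, pop, n_sim = 400, seed = 66)
  expect_equal(tab$interval, c(0.5, 0.8, 0.9, 0.95))
  expect_true(all(abs(tab$observed - tab$expected) <
                    1.96 * sqrt(tab$expected * (1 - tab$expected) /
                                  tab$n) + 0.05))
  ## a model with doubled residual noise is conservative: too many
  ## observations inside its 50% interval
  wide <- pop; wide$err_prop <- pop$err_prop * 2
  tab2 <- npc(sim$cohort, wide, n_sim = 400, seed = 66)
  expect_gt(tab2$observed[tab2$interval == 0.5], 0.5)
  ## no observations: empty table, not an error
  empty <- sim$cohort
  empty$data <- empty$data[empty$data$EVID == 1, ]
  expect_equal(nrow(npc(empty, pop, n_sim = 120, seed = 1)), 0)
  expect_warning(npc(sim$cohort, pop, n_sim = 50, seed = 1), "unstable")
})

test_that("npde applies the midrank convention to tied simulations", {
  ## an observation reported as exactly 0 ties with the simulated mass
  ## that the proportional-error model floors at 0 (about 3% of draws):
  ## the midrank convention places it at half that mass instead of at
  ## the extreme-rank cap
  pop <- final_params()
  d <- data.frame(ID = "A", TIME = c(0, 336, 671), AMT = c(160, 80, NA),
                  DV = c(NA, NA, 0), EVID = c(1, 1, 0), ALB = 3.0, AAA = 0)
  co <- pk_cohort(d)
  nd <- npde(co, pop, n_sim = 500, seed = 72)
  expect_lt(nd$values$npde, -1.6)              # deep in the left tail
  expect_gt(nd$values$npde, stats::qnorm(2 / 500))  # but above the cap
})

test_that("evaluation outputs are invariant to subject ordering", {
  pop <- final_params()
  sim <- sim_sparse(n = 20, seed = 73)
  co <- hold_out_last(sim$cohort)
  pairs <- leave_last_out(co, pop)
  ids <- unique(co$data$ID)
  shuffled <- pk_cohort(co$data[order(match(co$data$ID, rev(ids))), ],
                        validate = FALSE)
  pairs2 <- leave_last_out(shuffled, pop)
  expect_equal(mpe(pairs), mpe(pairs2))
  expect_equal(rmspe(pairs), rmspe(pairs2))
})
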