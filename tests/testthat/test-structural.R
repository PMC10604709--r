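final_doses <- function() {
  data.frame(time = c(0, 336, 672 + 336 * (0:9)),
             amt = c(160, 80, rep(40, 10)))
}

test_that("no drug on board before the first dose", {
  expect_equal(conc_profile(0, final_doses(), 0.03, 8, 0.006), 0)
  expect_equal(conc_profile(5, data.frame(time = 10, amt = 40),
                            0.03, 8, 0.006), 0)
})

test_that("closed form matches adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  ## the published single-dose worked case
  d1 <- data.frame(time = 0, amt = 40)
  a <- conc_profile(336, d1, 0.0312, 7.76, 0.00625)
  b <- ode_conc(336, d1, 0.0312, 7.76, 0.00625)
  expect_lt(abs(a - b) / b, 1e-6)
  ## the flip-flop limit branch, ka set exactly to ke
  ke <- 0.00625
  a <- conc_profile(336, d1, ke * 7.76, 7.76, ke)
  b <- ode_conc(336, d1, ke * 7.76, 7.76, ke)
  expect_lt(abs(a - b) / b, 1e-6)
  expect_true(is.finite(a))
})

test_that("profile is the superposition of single-dose profiles", {
  d <- final_doses()
  t <- c(100, 400, 700, 1500, 3000)
  total <- conc_profile(t, d, 0.0312, 7.76, 0.00625)
  bydose <- Reduce(`+`, lapply(seq_len(nrow(d)), function(i) {
    conc_profile(t, d[i, ], 0.0312, 7.76, 0.00625)
  }))
  expect_equal(total, bydose)
  ## linear in each dose amount
  d2 <- d; d2$amt <- 2 * d$amt
  expect_equal(conc_profile(t, d2, 0.0312, 7.76, 0.00625), 2 * total)
})

test_that("profile is continuous through the ka -> ke switch", {
  ka <- 0.00625; v <- 7.76
  t <- c(100, 336, 1000)
  d1 <- data.frame(time = 0, amt = 40)
  ## just inside the threshold: the switch takes the series branch.
  ## Oracle: the exact two-exponential formula evaluated without
  ## catastrophic cancellation via expm1
  ke <- ka * (1 - 0.99e-8)
  got <- conc_profile(t, d1, ke * v, v, ka)
  exact <- 40 * ka / (v * (ka - ke)) * exp(-ka * t) * expm1((ka - ke) * t)
  expect_lt(max(abs(got - exact) / exact), 1e-9)
})

test_that("maintenance troughs accumulate towards steady state", {
  d <- data.frame(time = 336 * (0:19), amt = 40)
  troughs <- conc_profile(336 * (1:20) - 1e-6, d, 0.0312, 7.76, 0.00625)
  expect_true(all(diff(troughs) > -1e-12))
})

test_that("clearance covariate model reproduces the published values", {
  ## at the centering albumin the clearance is the population value
  expect_equal(covariate_clearance(0.0312, 0, 4.5, 3.77, 3.77, -2.33),
               0.0312)
  ## antibody positivity multiplies clearance by 1 + 4.5
  expect_equal(covariate_clearance(0.0312, 1, 4.5, 3.77, 3.77, -2.33),
               0.0312 * 5.5)
  ## low albumin: independent arithmetic of the power term
  expect_equal(covariate_clearance(0.0312, 0, 4.5, 1.97, 3.77, -2.33),
               0.0312 * (1.97 / 3.77)^-2.33)
  expect_equal(round(covariate_clearance(0.0312, 0, 4.5, 1.97, 3.77,
                                         -2.33), 3), 0.142)
})

test_that("clearance is monotone decreasing in albumin for a negative exponent", {
  alb <- seq(1.97, 4.96, length.out = 50)
  cl <- covariate_clearance(0.0312, 0, 4.5, alb, 3.77, -2.33)
  expect_true(all(diff(cl) < 0))
  expect_error(covariate_clearance(0.0312, 0, 4.5, -1, 3.77, -2.33),
               "alb")
})

test_that("individual parameters follow the lognormal convention", {
  pop <- final_params()
  p0 <- individual_params(pop, c(0, 0), 3.77, 0)
  expect_equal(p0$cl, pop$cl_pop)
  expect_equal(p0$v, pop$v_pop)
  expect_equal(p0$ka, pop$ka_pop)
  p2 <- individual_params(pop, c(log(2), 0), 3.77, 0)
  expect_equal(p2$cl, 2 * p0$cl)
  ## lognormal median property: median over eta draws = typical value
  set.seed(1)
  cls <- pop$cl_pop * exp(stats::rnorm(1e5, 0, pop$omega_cl))
  expect_lt(abs(stats::median(cls) / pop$cl_pop - 1), 0.02)
})

test_that("nonpositive structural parameters are rejected", {
  d <- data.frame(time = 0, amt = 40)
  expect_error(conc_profile(1, d, -0.03, 8, 0.006), "cl")
  expect_error(conc_profile(1, d, 0.03, 0, 0.006), "v")
  expect_error(conc_profile(1, data.frame(time = 0, amt = -40),
                            0.03, 8, 0.006), "amt")
})
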