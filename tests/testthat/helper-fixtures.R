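# Shared fixture builders. Everything is generated in code; no data
# files ship with the tests.

# Minimal two-subject dataset: 160/80 induction + one maintenance dose,
# two troughs each.
toy_data <- function() {
  data.frame(
    ID = rep(c("A", "B"), each = 5),
    TIME = rep(c(0, 336, 672, 335, 671), 2),
    AMT = rep(c(160, 80, 40, NA, NA), 2),
    DV = rep(c(NA, NA, NA, 6.2, 4.8), 2) + rep(c(0, 1), each = 5),
    EVID = rep(c(1, 1, 1, 0, 0), 2),
    ALB = rep(c(3.5, 4.1), each = 5),
    AAA = rep(c(0, 1), each = 5),
    stringsAsFactors = FALSE)
}

toy_cohort <- function() pk_cohort(toy_data())

# Write a cohort's data frame to a temp CSV and return the path.
toy_csv <- function(data = toy_data()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Small simulated sparse cohort at the study design.
sim_sparse <- function(n = 54, seed = 42, pop = final_params()) {
  simulate_cohort(cohort_design(n_subjects = n, seed = seed), pop)
}

# Numerical 2-d marginalisation of one subject's likelihood over the
# random effects (independent oracle for the Laplace approximation).
quadrature_ofv <- function(subject, pop, half_width = 8, n_grid = 201) {
  z <- seq(-half_width, half_width, length.out = n_grid)
  h1 <- z * pop$omega_cl
  h2 <- z * pop$omega_v
  ll <- outer(seq_along(h1), seq_along(h2), Vectorize(function(i, j) {
    individual_loglik(subject, pop, c(h1[i], h2[j]))
  }))
  m <- max(ll)
  integ <- sum(exp(ll - m)) * diff(h1)[1] * diff(h2)[1]
  -2 * (m + log(integ))
}

# Adaptive ODE solution of the depot/central system (independent oracle
# for the closed-form concentration profile).
ode_conc <- function(t_eval, doses, cl, v, ka) {
  ke <- cl / v
  rhs <- function(t, y, p) list(c(-ka * y[1], ka * y[1] - ke * y[2]))
  times <- sort(unique(c(0, doses$time, t_eval)))
  ev <- data.frame(var = 1, time = doses$time, value = doses$amt,
                   method = "add")
  out <- deSolve::ode(c(A = 0, C = 0), times, rhs, NULL,
                      events = list(data = ev),
                      rtol = 1e-12, atol = 1e-12)
  out[match(t_eval, out[, "time"]), "C"] / v
}
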