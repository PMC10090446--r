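# Independent numerical oracles and small fixture builders used across the
# suite.  The ODE oracle deliberately goes through a generic adaptive
# stiff solver (deSolve::lsoda) so it shares nothing with the closed-form
# propagation it checks.

# high-accuracy ODE solution of the 1-/2-compartment infusion system
ode_oracle <- function(params, doses, times, n_compartments = 2) {
  p <- unclass(params)
  rate_at <- function(t) {
    on <- doses$time <= t & t < doses$time + doses$duration
    sum(doses$rate[on])
  }
  deriv <- if (n_compartments == 2) {
    function(t, y, parms) {
      R <- rate_at(t)
      list(c(R - (p["CL"] / p["Vc"] + p["Q"] / p["Vc"]) * y[1] +
               (p["Q"] / p["Vp"]) * y[2],
             (p["Q"] / p["Vc"]) * y[1] - (p["Q"] / p["Vp"]) * y[2]))
    }
  } else {
    function(t, y, parms) {
      list(R = rate_at(t) - (p["CL"] / p["Vc"]) * y[1])
    }
  }
  # force solver steps at every infusion boundary
  breaks <- sort(unique(c(0, doses$time, doses$time + doses$duration, times)))
  grid <- sort(unique(c(breaks, seq(0, max(times), length.out = 200))))
  y0 <- if (n_compartments == 2) c(0, 0) else 0
  sol <- deSolve::lsoda(y0, grid, deriv, NULL, rtol = 1e-11, atol = 1e-11,
                        hmax = min(diff(breaks)[diff(breaks) > 0]))
  sol[match(times, sol[, 1]), 2] / p["Vc"]
}

# direct per-pair likelihood evaluation (no scaling, no caching)
naive_likelihood <- function(cohort, points, model) {
  sapply(seq_len(nrow(points)), function(j) {
    th <- do.call(pk_parameters, as.list(points[j, ]))
    vapply(cohort$subjects, function(s) {
      th_i <- apply_covariates(th, s$covariates, model$covariates)
      exp(log_likelihood_subject(th_i, s, model$error,
                                 model$n_compartments))
    }, numeric(1))
  })
}

# brute-force maximiser of sum_i log(P w) over the 2-point simplex
brute_force_weights2 <- function(P, grid = seq(0, 1, by = 1e-4)) {
  obj <- vapply(grid, function(a) sum(log(P %*% c(a, 1 - a))), numeric(1))
  a <- grid[which.max(obj)]
  c(a, 1 - a)
}

# a tiny deterministic two-subject cohort for likelihood tests
tiny_cohort <- function(noise_seed = 1, covariates = FALSE) {
  set.seed(noise_seed)
  doses <- dose_events(c(0, 12), c(100, 50), c(1, 1))
  mk <- function(id, theta, covs) {
    times <- c(1, 6, 11.5, 13.5)
    conc <- predict_concentrations(theta, doses, times) *
      exp(rnorm(length(times), 0, 0.05))
    pk_subject(id, doses,
               data.frame(time = times, conc = conc, blq = FALSE), covs)
  }
  c1 <- list(age = 68, wt = 60, sex = "male", scr = 75, alb = 31.45,
             apache2 = 21)
  c2 <- list(age = 45, wt = 70, sex = "female", scr = 60, alb = 25,
             apache2 = 30)
  pk_cohort(list(
    mk("A", pk_parameters(1.2, 15, 3, 60), c1),
    mk("B", pk_parameters(1.6, 20, 2.5, 70), c2)))
}

table3_truth <- function(cv = c(CL = 30.48, Vc = 76.55, Q = 74.78,
                                Vp = 54.76),
                         covariates = covariate_model(),
                         gamma = 0.72) {
  list(mean = c(CL = 1.24, Vc = 16.64, Q = 3.04, Vp = 66.2),
       cv_pct = cv, covariates = covariates,
       error = error_spec(gamma = gamma))
}

# reduced-budget NPAG control for simulation studies in the tests
fast_control <- function(seed = 1L, ...)
  npag_control(n_init = 300, max_cycles = 25, tol = 0.02, delta_min = 5e-3,
               em_max_iter = 1500, seed = seed, ...)

# stable digest of a cohort via its serialized event records
write_read_hash <- function(cohort) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(cohort, path)
  unname(tools::md5sum(path))
}
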