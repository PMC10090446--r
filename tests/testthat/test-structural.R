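test_that("no doses gives zero concentration everywhere", {
  p <- pk_parameters(1.24, 16.64, 3.04, 66.2)
  d <- dose_events(numeric(0), numeric(0), numeric(0))
  expect_identical(predict_concentrations(p, d, c(0, 1, 5)), rep(0, 3))
  expect_identical(predict_one_compartment(pk_parameters(2, 20), d, 1), 0)
})

test_that("closed form matches the adaptive ODE oracle on the reference profile", {
  p <- pk_parameters(1.24, 16.64, 3.04, 66.2)
  d <- dose_events(0, 75, 1)
  times <- c(0.25, 0.5, 1, 1.5, 3, 6, 12, 24)
  mine <- predict_concentrations(p, d, times)
  orac <- ode_oracle(p, d, times)
  expect_lt(max(abs(mine - orac) / orac), 1e-6)
})

test_that("superposition: two doses equal the sum of shifted single doses", {
  set.seed(42)
  for (r in 1:5) {
    p <- pk_parameters(runif(1, 0.5, 4), runif(1, 5, 60),
                       runif(1, 0.5, 10), runif(1, 10, 150))
    t2 <- runif(1, 3, 20)
    dur <- runif(2, 0.5, 2)
    amt <- runif(2, 40, 150)
    times <- sort(c(runif(6, 0, 40), t2 + dur[2]))
    both <- predict_concentrations(p, dose_events(c(0, t2), amt, dur), times)
    d1 <- predict_concentrations(p, dose_events(0, amt[1], dur[1]), times)
    d2 <- predict_concentrations(p, dose_events(t2, amt[2], dur[2]), times)
    expect_equal(both, d1 + d2, tolerance = 1e-10)
  }
})

test_that("mass balance holds along the profile", {
  # X1 + X2 + CL * integral(C) must equal the administered amount
  p <- pk_parameters(1.24, 16.64, 3.04, 66.2)
  doses <- dose_events(c(0, 12, 24), c(100, 75, 75), c(1, 2, 1))
  t_end <- 36
  grid <- seq(0, t_end, length.out = 40001)
  conc <- predict_concentrations(p, doses, grid)
  eliminated <- p["CL"] * sum((conc[-1] + conc[-length(conc)]) / 2) *
    (grid[2] - grid[1])
  # recover amounts from a fine ODE solve for X1, X2 at t_end
  given <- sum(doses$amount)
  # X1 at t_end from the model itself; X2 via the oracle state
  oc <- ode_oracle(p, doses, t_end)
  x1 <- conc[length(conc)] * p["Vc"]
  # X2 from mass balance of the oracle is what we are testing, so derive it
  # independently: integrate dX2/dt with the trapezoid on the closed form
  x2_grid <- cumsum(c(0, diff(grid) * (
    (p["Q"] / 1) * (conc[-1] + conc[-length(conc)]) / 2)))
  # dX2/dt = (Q/Vc) X1 - (Q/Vp) X2; solve discretely
  x2 <- 0
  dt <- grid[2] - grid[1]
  k21 <- unname(p["Q"] / p["Vp"])
  inflow <- unname(p["Q"]) * conc  # (Q/Vc) X1 = Q * C
  for (i in seq_len(length(grid) - 1)) {
    x2 <- (x2 + dt / 2 * (inflow[i] + inflow[i + 1] - k21 * x2)) /
      (1 + dt / 2 * k21)
  }
  expect_lt(abs(unname(x1 + x2 + eliminated) - given) / given, 1e-6)
})

test_that("closed form matches the ODE oracle on random draws", {
  set.seed(7)
  for (r in 1:30) {
    p <- pk_parameters(runif(1, 0.3, 5), runif(1, 4, 80),
                       runif(1, 0.3, 15), runif(1, 5, 200))
    reg <- regimen(runif(1, 40, 100), loading_dose = runif(1, 100, 150),
                   interval = 12, infusion_duration = runif(1, 0.5, 2))
    doses <- regimen_doses(reg, 3)
    times <- sort(runif(6, 0.1, 48))
    mine <- predict_concentrations(p, doses, times)
    orac <- ode_oracle(p, doses, times)
    expect_lt(max(abs(mine - orac) / pmax(orac, 1e-12)), 1e-6)
  }
})

test_that("steady-state AUC24 follows the dose/CL identity", {
  expect_equal(steady_state_auc24(pk_parameters(2, 20, 1, 50), regimen(100)),
               100)
  expect_equal(steady_state_auc24(pk_parameters(1.24, 16.64, 3.04, 66.2),
                                  regimen(0)), 0)
  expect_equal(steady_state_auc24(pk_parameters(1.24, 16.64, 3.04, 66.2),
                                  regimen(75)), 120.9677, tolerance = 1e-6)
})

test_that("closed-form AUC24 agrees with trapezoidal integration at steady state", {
  p <- pk_parameters(1.24, 16.64, 3.04, 66.2)
  reg <- regimen(75, interval = 12, infusion_duration = 1)
  # terminal half-life here is ~59 h, so run in for ~10 half-lives
  doses <- regimen_doses(reg, 55)
  t0 <- 600
  grid <- seq(t0, t0 + 24, length.out = 4001)
  conc <- predict_concentrations(p, doses, grid)
  auc_num <- sum((conc[-1] + conc[-length(conc)]) / 2) * (grid[2] - grid[1])
  expect_lt(abs(auc_num - steady_state_auc24(p, reg)) /
              steady_state_auc24(p, reg), 0.005)
})

test_that("one-compartment model reaches the rate/CL plateau", {
  p <- pk_parameters(2, 20)
  d <- dose_events(0, 2000, 1000)  # 2 mg/h constant infusion
  plateau <- predict_one_compartment(p, d, c(900, 990))
  expect_equal(plateau, rep(2 / 2, 2), tolerance = 1e-6)
})

test_that("two-compartment model degenerates to one compartment as Q -> 0", {
  doses <- dose_events(c(0, 12), c(100, 50), c(1, 1))
  times <- c(0.5, 2, 8, 13, 20)
  c1 <- predict_one_compartment(pk_parameters(1.5, 25), doses, times)
  c2 <- predict_concentrations(pk_parameters(1.5, 25, 1e-9, 50), doses, times)
  expect_equal(c2, c1, tolerance = 1e-6)
})

test_that("short infusion decays log-linearly with slope -CL/V", {
  p <- pk_parameters(1.5, 25)
  d <- dose_events(0, 100, 0.05)
  times <- seq(1, 20, by = 0.5)
  lc <- log(predict_one_compartment(p, d, times))
  slope <- stats::coef(stats::lm(lc ~ times))[2]
  expect_equal(unname(slope), -1.5 / 25, tolerance = 1e-9)
})

test_that("concentrations are continuous across infusion boundaries", {
  p <- pk_parameters(1.24, 16.64, 3.04, 66.2)
  d <- dose_events(c(0, 12), c(100, 75), c(1, 1.5))
  eps <- 1e-7
  for (tb in c(1, 12, 13.5)) {
    c_lo <- predict_concentrations(p, d, tb - eps)
    c_hi <- predict_concentrations(p, d, tb + eps)
    expect_lt(abs(c_hi - c_lo), 1e-4)
  }
  expect_true(all(predict_concentrations(p, d, seq(0, 36, 0.25)) >= 0))
})

test_that("parameter validation rejects non-positive values", {
  expect_error(pk_parameters(-1, 10, 1, 10), "positive")
  expect_error(pk_parameters(1, 10, Q = 2), "together")
  expect_error(regimen(50, infusion_duration = 13), "interval")
})
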