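# one modest fitted cohort shared across the diagnostics tests
local_fit <- local({
  des <- cohort_design(n_subjects = 8, sampling = "rich",
                       samples_per_subject = 6, n_intervals = 5,
                       truth = table3_truth())
  gen <- generate_cohort(des, seed = 6)
  fit <- run_npag(gen$cohort, model_spec(2), control = fast_control(seed = 2))
  list(gen = gen, fit = fit)
})

test_that("gof table matches fit metrics and residual definitions", {
  gen <- local_fit$gen; fit <- local_fit$fit
  gof <- gof_table(fit, gen$cohort)
  met <- fit_metrics(fit, gen$cohort)
  expect_equal(gof$r2_pop, met$r2_pop, tolerance = 1e-12)
  expect_equal(gof$r2_post, met$r2_post, tolerance = 1e-12)
  expect_equal(nrow(gof$records), n_obs(gen$cohort, blq = FALSE))
  # residual definition: (obs - pred) / (gamma * sd(obs))
  r <- gof$records
  sd_obs <- fit$gamma * sd_of_observation(r$observed, fit$model$error)
  expect_equal(r$wres_pop, (r$observed - r$pop_pred) / sd_obs,
               tolerance = 1e-12)
  expect_true(all(is.finite(r$wres_pop)))
  # a well-specified fit keeps most weighted residuals inside +/-2
  expect_gte(mean(abs(r$wres_post) <= 2), 0.9)
})

test_that("weighted residuals reduce to raw residuals when gamma*SD = 1", {
  gen <- local_fit$gen
  fit <- local_fit$fit
  fit$gamma <- 1
  fit$model$error <- error_spec(c0 = 1, c1 = 0, gamma = 1)
  gof <- gof_table(fit, gen$cohort)
  expect_equal(gof$records$wres_pop,
               gof$records$observed - gof$records$pop_pred, tolerance = 1e-12)
})

test_that("bootstrap on cloned subjects gives a degenerate interval", {
  # identical subjects: every resample is the same cohort
  s <- local_fit$gen$cohort$subjects[[1]]
  clones <- lapply(1:5, function(i) { s2 <- s; s2$id <- paste0("c", i); s2 })
  boot <- pk_bootstrap(pk_cohort(clones), model_spec(2), parameter_space(),
                       B = 3, control = fast_control(seed = 1), seed = 2)
  width <- boot$summary$ci_high - boot$summary$ci_low
  expect_true(all(width / boot$summary$median < 1e-9))
  expect_true(all(boot$summary$ci_low <= boot$summary$median &
                    boot$summary$median <= boot$summary$ci_high))
  expect_error(pk_bootstrap(pk_cohort(clones), model_spec(2),
                            parameter_space(), B = 1), "B >= 2")
})

test_that("data splitting is seed-stable and handles the boundary fraction", {
  gen <- local_fit$gen
  ctl <- fast_control(seed = 1)
  # the 25% split holds only two subjects, which is flagged
  expect_warning(
    sp <- split_validate(gen$cohort, model_spec(2), parameter_space(),
                         fraction = 0.75, control = ctl, seed = 9),
    "only 2 subjects")
  sp2 <- suppressWarnings(
    split_validate(gen$cohort, model_spec(2), parameter_space(),
                   fraction = 0.75, control = ctl, seed = 9))
  expect_identical(sp, sp2)
  expect_setequal(unique(sp$cohort), c("full", "75%", "25%"))
  # fraction 1: only the full fit, and it must equal a direct run
  expect_warning(sp1 <- split_validate(
    pk_cohort(gen$cohort$subjects[1:4]), model_spec(2), parameter_space(),
    fraction = 1, control = ctl, seed = 9), NA)
  expect_identical(unique(sp1$cohort), "full")
  expect_error(split_validate(gen$cohort, model_spec(2), parameter_space(),
                              fraction = 0), "fraction")
})

test_that("vpc bands behave in the degenerate limits", {
  gen <- local_fit$gen; fit <- local_fit$fit
  # n_sim = 1: all three band percentiles coincide with that simulation
  v1 <- vpc(fit, gen$cohort, n_sim = 1, bins = 3, seed = 4)
  expect_equal(v1$table$sim_lo, v1$table$sim_hi)
  # single-point support and vanishing error: simulations are deterministic
  fit0 <- fit
  top <- which.max(fit$support$weights)
  fit0$support <- support_set(fit$support$points[top, , drop = FALSE], 1)
  fit0$gamma <- 1e-12
  v0 <- vpc(fit0, gen$cohort, n_sim = 20, bins = 3, seed = 4)
  expect_equal(v0$table$sim_lo, v0$table$sim_hi, tolerance = 1e-6)
  # reproducibility
  va <- vpc(fit, gen$cohort, n_sim = 50, bins = 4, seed = 8)
  vb <- vpc(fit, gen$cohort, n_sim = 50, bins = 4, seed = 8)
  expect_identical(va, vb)
  # percentiles ordered within every bin
  tab <- va$table
  for (b in unique(tab$bin)) {
    o <- tab$observed[tab$bin == b]
    expect_true(all(diff(o) >= 0))
  }
})

test_that("vpc median band covers the observed median in most bins", {
  gen <- local_fit$gen; fit <- local_fit$fit
  v <- vpc(fit, gen$cohort, n_sim = 200, bins = 4, seed = 3)
  med <- v$table[v$table$pct == 50, ]
  covered <- mean(med$observed >= med$sim_lo & med$observed <= med$sim_hi)
  expect_gte(covered, 0.75)
})
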