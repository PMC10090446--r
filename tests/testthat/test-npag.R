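test_that("likelihood matrix matches naive per-pair evaluation", {
  ch <- tiny_cohort()
  pts <- rbind(c(1.2, 15, 3, 60), c(1.6, 20, 2.5, 70), c(2.5, 40, 5, 100))
  colnames(pts) <- c("CL", "Vc", "Q", "Vp")
  m <- model_spec(2, error = error_spec(gamma = 0.5))
  P <- likelihood_matrix(ch, support_set(pts, rep(1 / 3, 3)), m)
  raw <- P * exp(attr(P, "log_scale"))
  attributes(raw) <- list(dim = dim(raw))
  expect_equal(raw, unname(naive_likelihood(ch, pts, m)), tolerance = 1e-9)
  # duplicated support point gives identical columns
  pts2 <- pts[c(1, 1, 2), ]
  P2 <- likelihood_matrix(ch, support_set(pts2, rep(1 / 3, 3)), m)
  expect_identical(P2[, 1], P2[, 2])
  # K = 1 gives the per-subject likelihood column
  P1 <- likelihood_matrix(ch, support_set(pts[1, , drop = FALSE], 1), m)
  expect_equal(dim(P1), c(2L, 1L))
})

test_that("EM weights solve trivial and symmetric problems", {
  expect_equal(as.numeric(optimize_weights(matrix(c(0.3, 0.7), 2, 1))), 1)
  # symmetric 2x2: equal weights
  w <- optimize_weights(matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2))
  expect_equal(as.numeric(w), c(0.5, 0.5), tolerance = 1e-6)
  # N=1: all mass on the better point
  w1 <- optimize_weights(matrix(c(0.2, 0.8), 1, 2), max_iter = 100000)
  expect_equal(as.numeric(w1), c(0, 1), tolerance = 1e-3)
  expect_error(optimize_weights(matrix(c(1, 0, 0, 0), 2, 2)),
               "zero likelihood")
})

test_that("EM matches brute-force simplex maximisation and is monotone", {
  set.seed(21)
  for (r in 1:5) {
    P <- matrix(rexp(8), 4, 2)
    w_em <- optimize_weights(P, trace = TRUE, max_iter = 50000)
    w_bf <- brute_force_weights2(P)
    expect_lt(max(abs(as.numeric(w_em) - w_bf)), 2e-4)
    expect_true(all(diff(attr(w_em, "trace")) >= -1e-12))
  }
})

test_that("degenerate single-truth cohort collapses onto the truth", {
  truth <- c(CL = 1.24, Vc = 16.64, Q = 3.04, Vp = 66.2)
  des <- cohort_design(n_subjects = 8, sampling = "rich",
                       samples_per_subject = 12,
                       truth = list(mean = truth,
                                    cv_pct = c(CL = 1e-6, Vc = 1e-6,
                                               Q = 1e-6, Vp = 1e-6),
                                    covariates = covariate_model(),
                                    error = error_spec(gamma = 0.02)))
  gen <- generate_cohort(des, seed = 3)
  fit <- run_npag(gen$cohort, model_spec(2, error = error_spec(gamma = 1)),
                  control = npag_control(max_cycles = 300, seed = 1))
  w <- fit$support$weights
  top <- order(-w)[1:2]
  expect_gte(sum(w[top]), 0.99)
  for (j in top[w[top] > 0.01]) {
    expect_lt(max(abs(fit$support$points[j, ] - truth) / truth), 0.05)
  }
  expect_true(all(diff(fit$cycle_log$neg2ll) <= 1e-5))
})

test_that("NPAG improves on the initial grid and is reproducible", {
  des <- cohort_design(n_subjects = 5, sampling = "rich",
                       samples_per_subject = 6,
                       truth = table3_truth())
  gen <- generate_cohort(des, seed = 8)
  ctl <- fast_control(seed = 4)
  fit1 <- run_npag(gen$cohort, model_spec(2), control = ctl)
  fit2 <- run_npag(gen$cohort, model_spec(2), control = ctl)
  expect_equal(fit1$neg2ll, fit2$neg2ll, tolerance = 1e-9)
  expect_identical(fit1$support$points, fit2$support$points)
  # final -2LL beats the initial-grid solution and decreases cyclewise
  expect_lt(fit1$neg2ll, fit1$cycle_log$neg2ll[1])
  expect_true(all(diff(fit1$cycle_log$neg2ll) <= 1e-5))
  # weights stay on the simplex
  expect_equal(sum(fit1$support$weights), 1, tolerance = 1e-10)
  expect_true(all(fit1$support$weights >= 0))
  # support respects the box
  sp <- fit1$space
  expect_true(all(sweep(fit1$support$points, 2, sp$lower, ">=")))
  expect_true(all(sweep(fit1$support$points, 2, sp$upper, "<=")))
})

test_that("posterior follows Bayes' rule and degenerates correctly", {
  ch <- tiny_cohort()
  pts <- rbind(c(1.2, 15, 3, 60), c(1.6, 20, 2.5, 70))
  colnames(pts) <- c("CL", "Vc", "Q", "Vp")
  m <- model_spec(2, error = error_spec(gamma = 0.5))
  fake_fit <- structure(list(support = support_set(pts, c(0.3, 0.7)),
                             gamma = 0.5, model = m,
                             space = parameter_space()),
                        class = "npag_fit")
  s <- ch$subjects[[1]]
  post <- posterior_subject(fake_fit, s)
  # hand Bayes: prior x likelihood, renormalised
  lik <- naive_likelihood(pk_cohort(list(s)), pts, m)
  hand <- c(0.3, 0.7) * lik / sum(c(0.3, 0.7) * lik)
  expect_equal(as.numeric(post$weights), as.numeric(hand), tolerance = 1e-9)
  expect_equal(unname(unclass(post$mean)[c("CL", "Vc", "Q", "Vp")]),
               unname(drop(hand %*% pts)), tolerance = 1e-9)
  # no observations: posterior equals the prior
  s0 <- pk_subject("empty", s$doses, NULL, s$covariates)
  post0 <- posterior_subject(fake_fit, s0)
  expect_equal(as.numeric(post0$weights), c(0.3, 0.7))
  # single support point: posterior is that point
  fit1 <- structure(list(support = support_set(pts[1, , drop = FALSE], 1),
                         gamma = 0.5, model = m, space = parameter_space()),
                    class = "npag_fit")
  expect_equal(unname(unclass(posterior_subject(fit1, s)$mean)[1:4]),
               unname(pts[1, ]))
})

test_that("information criteria reproduce the printed model-comparison table", {
  # one-compartment base: k = 3; two-compartment rows: k = 5; n = 64
  printed <- rbind(
    c(neg2ll = 188.6, k = 3, aic = 195.0, bic = 201.0),
    c(145.6, 5, 156.6, 166.4),
    c(145.3, 5, 156.3, 166.1),
    c(139.9, 5, 151.0, 160.7),
    c(143.7, 5, 154.7, 164.5),
    c(138.9, 5, 150.0, 159.7))
  for (i in seq_len(nrow(printed))) {
    ic <- information_criteria(unname(printed[i, "neg2ll"]),
                               unname(printed[i, "k"]), 64)
    expect_lt(abs(ic["aicc"] - printed[i, "aic"]), 0.1)
    expect_lt(abs(ic["bic"] - printed[i, "bic"]), 0.1)
  }
  expect_error(information_criteria(100, 5, 6), "exceed")
})

test_that("fit metrics are coherent on a fitted cohort", {
  des <- cohort_design(n_subjects = 6, sampling = "rich",
                       samples_per_subject = 6, truth = table3_truth())
  gen <- generate_cohort(des, seed = 12)
  fit <- run_npag(gen$cohort, model_spec(2), control = fast_control(seed = 2))
  met <- fit_metrics(fit, gen$cohort)
  expect_equal(unname(met$aicc),
               unname(information_criteria(fit$neg2ll, 5, met$n_obs)["aicc"]))
  expect_gt(met$aicc, met$neg2ll)
  expect_true(met$r2_pop >= 0 && met$r2_pop <= 1)
  expect_true(met$r2_post >= 0 && met$r2_post <= 1)
  expect_gte(met$r2_post, met$r2_pop - 0.05)
  expect_equal(met$parameters$cv_pct,
               100 * met$parameters$sd / met$parameters$mean)
})
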