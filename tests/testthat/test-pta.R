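test_that("PD target conversion derives the total-drug threshold", {
  t <- pd_targets()
  expect_equal(t$auc_mic_threshold, 50)
  expect_equal(10 * ceiling(20 / 0.42 / 10), 50)
  expect_equal(pd_targets(fauc_mic_target = 30)$auc_mic_threshold, 80)
})

test_that("efficacy and toxicity PTA match closed-form cases", {
  # clearance fixed at the population mean for every subject
  pop <- data.frame(CL = rep(1.24, 200), Vc = 16.64, Q = 3.04, Vp = 66.2,
                    alb = 38, age = 68)
  expect_equal(unname(pta_efficacy(pop, regimen(75), mic_grid = 2)), 1)
  expect_equal(unname(pta_efficacy(pop, regimen(75), mic_grid = 4)), 0)
  expect_equal(pta_toxicity(pop, regimen(40)), 0)   # AUC 64.5
  expect_equal(pta_toxicity(pop, regimen(100)), 1)  # AUC 161.3
  expect_equal(pta_toxicity(pop, regimen(0)), 0)
  expect_error(pta_efficacy(pop, regimen(75), mic_grid = -1), "positive")
})

test_that("lognormal published-table sampling preserves the published means", {
  sc <- pta_scenario(c(35, 41.5), 68)
  pop <- sample_virtual_population(published_model(covariate_model()),
                                   sc, n = 1e5, seed = 1)
  # base CL untouched by the empty covariate model
  se <- 1.24 * 0.3048 / sqrt(1e5)
  expect_lt(abs(mean(pop$CL) - 1.24), 3 * se)
  expect_lt(abs(mean(pop$Vc) - 16.64) / 16.64, 0.02)
  expect_lt(abs(sd(pop$CL) / mean(pop$CL) - 0.3048), 0.01)
  expect_true(all(pop$alb >= 35 & pop$alb <= 41.5))
})

test_that("virtual sampling is reproducible and honours the covariate model", {
  sc <- pta_scenario(c(25, 34.9), 93)
  a <- sample_virtual_population(published_model(), sc, n = 50, seed = 9)
  b <- sample_virtual_population(published_model(), sc, n = 50, seed = 9)
  expect_identical(a, b)
  # fitted-mode with a single support point: that point plus covariates
  pts <- matrix(c(1.24, 16.64, 3.04, 66.2), 1,
                dimnames = list(NULL, c("CL", "Vc", "Q", "Vp")))
  fit1 <- structure(list(support = support_set(pts, 1),
                         model = model_spec(2, final_covariate_model())),
                    class = "npag_fit")
  p1 <- sample_virtual_population(fit1, sc, n = 5, seed = 1)
  expect_equal(p1$CL, 1.24 * (p1$alb / 31.45)^(-0.95), tolerance = 1e-12)
  expect_equal(p1$Vc, rep(16.64 * (93 / 68)^0.95, 5), tolerance = 1e-12)
})

test_that("PTA is monotone in MIC and dose, and age-invariant for efficacy", {
  sc <- pta_scenario(c(35, 41.5), 68)
  pop <- sample_virtual_population(published_model(), sc, n = 2000, seed = 3)
  regs <- default_regimens()
  eff <- sapply(regs, pta_efficacy, pop = pop)
  # non-increasing in MIC (rows) for every regimen
  expect_true(all(apply(eff, 2, function(x) all(diff(x) <= 0))))
  # non-decreasing in maintenance dose at every MIC (V..I is increasing dose)
  expect_true(all(apply(eff[, rev(seq_along(regs))], 1,
                        function(x) all(diff(x) >= 0))))
  tox <- vapply(regs, pta_toxicity, pop = pop, numeric(1))
  expect_true(all(diff(rev(tox)) >= 0))
  # efficacy depends on CL only, and age enters the final model through Vc
  sc_old <- pta_scenario(c(35, 41.5), 93)
  pop_old <- sample_virtual_population(published_model(), sc_old, n = 2000,
                                       seed = 3)
  expect_equal(pta_efficacy(pop_old, regs$III), pta_efficacy(pop, regs$III))
})

test_that("dosing report covers the factorial design and flags MIC 4", {
  rep <- dosing_report(published_model(), n = 400, seed = 5)
  expect_equal(nrow(rep$table), 9 * 5 * 5)
  expect_true(all(rep$table$pta_efficacy >= 0 & rep$table$pta_efficacy <= 1))
  # at MIC 0.25 every regimen attains efficacy in every scenario
  sub <- rep$table[rep$table$mic == 0.25, ]
  expect_true(all(sub$pta_efficacy >= 0.9))
  # recommendations: none attainable at the resistance breakpoint
  rec4 <- rep$recommendations[rep$recommendations$mic == 4, ]
  expect_true(all(rec4$recommended == "none attainable"))
  # at MIC 0.25 the recommendation is the smallest qualifying dose
  rec025 <- rep$recommendations[rep$recommendations$mic == 0.25, ]
  expect_true(all(rec025$recommended %in% c("IV", "V")))
  # determinism
  rep2 <- dosing_report(published_model(), n = 400, seed = 5)
  expect_identical(rep$table, rep2$table)
})

test_that("replicate PTA estimates vary within the binomial bound", {
  sc <- pta_scenario(c(25, 34.9), 68)
  vals <- vapply(1:5, function(s) {
    pop <- sample_virtual_population(published_model(), sc, n = 1000,
                                     seed = s)
    unname(pta_efficacy(pop, regimen(50), mic_grid = 1))
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 2 * 3 * sqrt(0.25 / 1000))
})
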