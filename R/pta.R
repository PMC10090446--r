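#' Pharmacodynamic targets for polymyxin B
#'
#' The efficacy driver is the free-drug AUC/MIC ratio.  With a target
#' fAUC/MIC of about 20 and an unbound fraction of 0.42, the equivalent
#' total-drug threshold is `20 / 0.42 = 47.6`, rounded **up to the nearest
#' ten** to AUC/MIC >= 50.  Toxicity (nephrotoxicity risk) is flagged when
#' the steady-state 24-h AUC exceeds 100 mg·h/L.
#'
#' @param fauc_mic_target free-drug AUC/MIC target
#' @param unbound_fraction plasma unbound fraction of polymyxin B
#' @param auc_mic_threshold total-drug AUC/MIC threshold; by default derived
#'   from the two values above by the round-up-to-ten rule
#' @param toxicity_auc AUC_ss,24h upper limit, mg·h/L
#' @param attainment_threshold PTA level regarded as adequate
#' @return list of class `pd_targets`
#' @export
pd_targets <- function(fauc_mic_target = 20, unbound_fraction = 0.42,
                       auc_mic_threshold = NULL, toxicity_auc = 100,
                       attainment_threshold = 0.9) {
  derived <- 10 * ceiling(fauc_mic_target / unbound_fraction / 10)
  if (is.null(auc_mic_threshold)) auc_mic_threshold <- derived
  if (auc_mic_threshold < fauc_mic_target / unbound_fraction - 10)
    stop("pd_targets: total-drug threshold inconsistent with fAUC/MIC target")
  structure(list(fauc_mic_target = fauc_mic_target,
                 unbound_fraction = unbound_fraction,
                 auc_mic_threshold = auc_mic_threshold,
                 toxicity_auc = toxicity_auc,
                 attainment_threshold = attainment_threshold),
            class = "pd_targets")
}

#' Simulation scenario: albumin stratum x age
#'
#' @param alb_range albumin interval, g/L (lower < upper); albumin is drawn
#'   uniformly within it
#' @param age fixed age, years
#' @param label optional scenario label
#' @return list of class `pta_scenario`
#' @export
pta_scenario <- function(alb_range, age, label = NULL) {
  if (alb_range[1] >= alb_range[2]) stop("pta_scenario: need lower < upper albumin")
  if (age <= 0) stop("pta_scenario: age must be positive")
  structure(list(alb_range = alb_range, age = age,
                 label = if (is.null(label))
                   sprintf("alb%.1f-%.1f/age%d", alb_range[1], alb_range[2], age)
                 else label),
            class = "pta_scenario")
}

#' The nine albumin x age scenarios of the dosing analysis
#'
#' Albumin strata: ultra-low 21.3-24.9, low 25-34.9, normal 35-41.5 g/L;
#' ages: 34 (5th percentile), 68 (median), 93 (95th percentile) years.
#'
#' @return named list of [pta_scenario()] objects
#' @export
default_scenarios <- function() {
  strata <- list(ultra_low = c(21.3, 24.9), low = c(25, 34.9),
                 normal = c(35, 41.5))
  ages <- c(34, 68, 93)
  out <- list()
  for (nm in names(strata)) for (a in ages) {
    lab <- sprintf("%s/age%d", nm, a)
    out[[lab]] <- pta_scenario(strata[[nm]], a, label = lab)
  }
  out
}

#' The five maintenance regimens of the dosing analysis
#'
#' I: 100, II: 75, III: 60, IV: 50, V: 40 mg q12h (1-h infusions).
#'
#' @return named list of [regimen()] objects
#' @export
default_regimens <- function() {
  doses <- c(I = 100, II = 75, III = 60, IV = 50, V = 40)
  stats::setNames(lapply(names(doses), function(nm)
    regimen(doses[[nm]], interval = 12, infusion_duration = 1, label = nm)),
    names(doses))
}

#' Published population model for simulation
#'
#' Parameter means and between-subject CV% of the final two-compartment
#' covariate model, for use in "published-table" Monte Carlo mode when no
#' fitted support is at hand: CL0 1.24 L/h (30.48% CV), Vc0 16.64 L
#' (76.55%), Q 3.04 L/h (74.78%), Vp 66.2 L (54.76%), with the
#' age-on-volume / albumin-on-clearance covariate model.
#'
#' @param covariates a [covariate_model()]
#' @return list of class `published_model`
#' @export
published_model <- function(covariates = final_covariate_model()) {
  structure(list(mean = c(CL = 1.24, Vc = 16.64, Q = 3.04, Vp = 66.2),
                 cv_pct = c(CL = 30.48, Vc = 76.55, Q = 74.78, Vp = 54.76),
                 covariates = covariates),
            class = "published_model")
}

#' Sample a virtual patient population
#'
#' Draws `n` individual parameter sets for one scenario.  With a fitted
#' [run_npag()] result the base parameters are resampled from the support
#' points by weight; with a [published_model()] they are drawn independently
#' lognormal, matching the published mean and CV% of each parameter.
#' Albumin is drawn uniformly over the scenario stratum, age is fixed, and
#' the covariate model is applied.
#'
#' @param model an `npag_fit` or a [published_model()]
#' @param scenario a [pta_scenario()]
#' @param n population size
#' @param seed RNG seed
#' @return data.frame: one row per individual, columns `CL`, `Vc`, `Q`,
#'   `Vp` (individual values), `alb`, `age`
#' @export
sample_virtual_population <- function(model, scenario, n = 1000, seed = 1L) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  if (inherits(model, "npag_fit")) {
    pts <- model$support$points
    idx <- sample.int(nrow(pts), n, replace = TRUE,
                      prob = model$support$weights)
    theta <- pts[idx, , drop = FALSE]
    covmod <- model$model$covariates
  } else if (inherits(model, "published_model")) {
    if (any(model$cv_pct <= 0)) stop("sample_virtual_population: CV% must be positive")
    theta <- sapply(names(model$mean), function(p) {
      cv <- model$cv_pct[[p]] / 100
      sigma <- sqrt(log(1 + cv^2))
      # meanlog chosen so the arithmetic mean equals the published mean
      stats::rlnorm(n, meanlog = log(model$mean[[p]]) - sigma^2 / 2,
                    sdlog = sigma)
    })
    covmod <- model$covariates
  } else stop("sample_virtual_population: model must be an npag_fit or published_model")
  if (ncol(theta) == 2) theta <- cbind(theta, Q = NA_real_, Vp = NA_real_)
  colnames(theta) <- c("CL", "Vc", "Q", "Vp")
  alb <- stats::runif(n, scenario$alb_range[1], scenario$alb_range[2])
  out <- as.data.frame(theta)
  for (e in covmod$effects) {
    v <- switch(e$covariate, alb = alb, age = rep(scenario$age, n),
                stop("sample_virtual_population: covariate '", e$covariate,
                     "' is not defined by a scenario"))
    out[[e$target]] <- out[[e$target]] * (v / e$reference)^e$exponent
  }
  out$alb <- alb
  out$age <- scenario$age
  out
}

#' Probability of attaining the efficacy target
#'
#' Per MIC, the fraction of the virtual population whose steady-state 24-h
#' AUC divided by the MIC meets the total-drug threshold (AUC/MIC >= 50 by
#' default).
#'
#' @param pop population from [sample_virtual_population()]
#' @param reg a [regimen()]
#' @param targets a [pd_targets()]
#' @param mic_grid MICs, mg/L
#' @return named numeric vector of PTA per MIC
#' @export
pta_efficacy <- function(pop, reg, targets = pd_targets(),
                         mic_grid = c(0.25, 0.5, 1, 2, 4)) {
  if (nrow(pop) == 0) stop("pta_efficacy: empty population")
  if (any(mic_grid <= 0)) stop("pta_efficacy: MIC must be positive")
  auc <- (24 / reg$interval) * reg$maintenance_dose / pop$CL
  vapply(stats::setNames(mic_grid, mic_grid), function(mic)
    mean(auc / mic >= targets$auc_mic_threshold), numeric(1))
}

#' Probability of exceeding the toxicity exposure limit
#'
#' Fraction of the virtual population with steady-state 24-h AUC strictly
#' above the nephrotoxicity limit (100 mg·h/L by default).
#'
#' @inheritParams pta_efficacy
#' @return scalar fraction
#' @export
pta_toxicity <- function(pop, reg, targets = pd_targets()) {
  if (nrow(pop) == 0) stop("pta_toxicity: empty population")
  auc <- (24 / reg$interval) * reg$maintenance_dose / pop$CL
  mean(auc > targets$toxicity_auc)
}

#' Full factorial dosing report
#'
#' Runs the Monte Carlo PTA analysis over every scenario x regimen x MIC
#' cell and recommends, per scenario and MIC, the smallest maintenance dose
#' whose efficacy PTA reaches the attainment threshold while the toxicity
#' PTA stays below it; cells where no regimen qualifies are flagged
#' `"none attainable"` (expected at the resistance breakpoint MIC of
#' 4 mg/L).
#'
#' @param model an `npag_fit` or [published_model()]
#' @param scenarios list of [pta_scenario()] (default [default_scenarios()])
#' @param regimens list of [regimen()] (default [default_regimens()])
#' @param targets a [pd_targets()]
#' @param mic_grid MICs, mg/L
#' @param n virtual subjects per scenario
#' @param seed RNG seed
#' @return list of class `pta_report`: `table` (long data.frame: scenario,
#'   regimen, maintenance_dose, mic, pta_efficacy, pta_toxicity) and
#'   `recommendations` (scenario, mic, recommended regimen or
#'   "none attainable")
#' @export
dosing_report <- function(model, scenarios = default_scenarios(),
                          regimens = default_regimens(),
                          targets = pd_targets(),
                          mic_grid = c(0.25, 0.5, 1, 2, 4),
                          n = 1000, seed = 1L) {
  rows <- list(); recs <- list()
  thr <- targets$attainment_threshold
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    pop <- sample_virtual_population(model, sc, n = n, seed = seed + si)
    eff <- lapply(regimens, pta_efficacy, pop = pop, targets = targets,
                  mic_grid = mic_grid)
    tox <- vapply(regimens, pta_toxicity, pop = pop, targets = targets,
                  numeric(1))
    for (ri in seq_along(regimens)) {
      reg <- regimens[[ri]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$label, regimen = reg$label,
        maintenance_dose = reg$maintenance_dose, mic = mic_grid,
        pta_efficacy = unname(eff[[ri]]), pta_toxicity = tox[ri],
        row.names = NULL)
    }
    doses <- vapply(regimens, function(r) r$maintenance_dose, numeric(1))
    for (mi in seq_along(mic_grid)) {
      ok <- vapply(seq_along(regimens), function(ri)
        eff[[ri]][mi] >= thr && tox[ri] < thr, logical(1))
      rec <- if (any(ok)) {
        names(regimens)[ok][which.min(doses[ok])]
      } else "none attainable"
      recs[[length(recs) + 1L]] <- data.frame(
        scenario = sc$label, mic = mic_grid[mi], recommended = rec,
        row.names = NULL)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 recommendations = do.call(rbind, recs),
                 targets = targets, n = n, seed = seed),
            class = "pta_report")
}
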