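#' Synthetic cohort design
#'
#' Statistical design of a simulated critical-care cohort, defaulting to
#' the observed study structure: 22 subjects contributing 64 total
#' concentrations, demographics matched to the cohort's min/median/max
#' (age 31-94 median 68 y; weight 50-80 median 60 kg; albumin 23.1-41.5
#' median 31.45 g/L; serum creatinine 33-125 median 75 umol/L; APACHE-II
#' 15-46 median 21.5; 77.3% male), loading doses of 100-150 mg followed by
#' 50-75 mg q12h over 1-2 h infusions, and a sparse sampling mix of 37.5%
#' troughs, 35.9% peaks and 26.6% mid-interval (6-8 h post-infusion)
#' samples, all drawn at or after 48 h of treatment.
#'
#' Skewed demographics are drawn from Beta distributions rescaled to each
#' (min, max) range with the shape chosen so the distribution median equals
#' the design median.
#'
#' @param n_subjects cohort size
#' @param n_obs_total total concentration samples across the cohort
#'   (ignored when `sampling = "rich"`)
#' @param sampling `"sparse"` (trough/peak/mid mix) or `"rich"`
#'   (`samples_per_subject` samples spread over one late dosing interval)
#' @param samples_per_subject per-subject samples in rich mode
#' @param demographics list of `c(min, median, max)` per covariate
#' @param male_fraction probability of male sex
#' @param loading_doses,maintenance_doses candidate doses, mg (sampled per
#'   subject)
#' @param infusion_range infusion duration range, h
#' @param interval dosing interval, h
#' @param n_intervals maintenance doses simulated per subject
#' @param sampling_mix trough/peak/mid probabilities (must sum to 1)
#' @param truth list with `mean` and `cv_pct` per base parameter (defaults:
#'   the published final-model values), `covariates`
#'   (a [covariate_model()]) and `error` (an [error_spec()] whose gamma is
#'   the true process-noise scale)
#' @param lloq below-quantification limit applied to generated
#'   observations, mg/L
#' @return list of class `cohort_design`
#' @export
cohort_design <- function(n_subjects = 22,
                          n_obs_total = 64,
                          sampling = c("sparse", "rich"),
                          samples_per_subject = 12,
                          demographics = list(
                            age = c(31, 68, 94),
                            wt = c(50, 60, 80),
                            alb = c(23.1, 31.45, 41.5),
                            scr = c(33, 75, 125),
                            apache2 = c(15, 21.5, 46)),
                          male_fraction = 0.773,
                          loading_doses = c(100, 125, 150),
                          maintenance_doses = c(50, 60, 75),
                          infusion_range = c(1, 2),
                          interval = 12,
                          n_intervals = 11,
                          sampling_mix = c(trough = 0.375, peak = 0.359,
                                           mid = 0.266),
                          truth = list(
                            mean = c(CL = 1.24, Vc = 16.64, Q = 3.04,
                                     Vp = 66.2),
                            cv_pct = c(CL = 30.48, Vc = 76.55, Q = 74.78,
                                       Vp = 54.76),
                            covariates = final_covariate_model(),
                            error = error_spec(gamma = 0.72)),
                          lloq = 0.19) {
  sampling <- match.arg(sampling)
  if (abs(sum(sampling_mix) - 1) > 1e-9)
    stop("cohort_design: sampling_mix must sum to 1")
  if (max(infusion_range) >= interval)
    stop("cohort_design: infusion duration must be shorter than the interval")
  for (nm in names(demographics)) {
    d <- demographics[[nm]]
    if (!(d[1] < d[2] && d[2] < d[3]))
      stop("cohort_design: demographic range must contain its median (", nm, ")")
  }
  structure(as.list(environment()), class = "cohort_design")
}

# Beta(s*m, s*(1-m)) rescaled to [min, max], with the mixing proportion m
# solved so the distribution median hits the design median; concentration
# s = 4 keeps realistic spread over the range.
.rbeta_med <- function(n, lo, med, hi, s = 4) {
  target <- (med - lo) / (hi - lo)
  f <- function(m) suppressWarnings(stats::qbeta(0.5, s * m, s * (1 - m))) - target
  m <- stats::uniroot(f, c(1e-6, 1 - 1e-6))$root
  lo + (hi - lo) * stats::rbeta(n, s * m, s * (1 - m))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates from the design's demographic distributions, per-subject
#' base parameters lognormally around the truth means with the truth CV%,
#' applies the truth covariate model, builds the dosing history (loading
#' dose then q12h maintenance), draws sampling times per the design mix
#' (troughs within 1 h before a dose, peaks within 1 h after an infusion
#' end, mid samples 6-8 h after an infusion end, all at >= 48 h), and
#' generates observations as model predictions plus Gaussian noise with SD
#' `gamma * sd_of_observation(prediction)` (the polynomial evaluated at the
#' noiseless prediction, which removes the observed-side circularity during
#' generation).  Values below the LLOQ are flagged BLQ.
#'
#' @param design a [cohort_design()]
#' @param seed RNG seed
#' @return list with `cohort` (a [pk_cohort()]) and `truth` (data.frame of
#'   per-subject base and individual parameters)
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1L) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  N <- design$n_subjects
  dm <- design$demographics
  covs <- data.frame(
    age = .rbeta_med(N, dm$age[1], dm$age[2], dm$age[3]),
    wt = .rbeta_med(N, dm$wt[1], dm$wt[2], dm$wt[3]),
    alb = .rbeta_med(N, dm$alb[1], dm$alb[2], dm$alb[3]),
    scr = .rbeta_med(N, dm$scr[1], dm$scr[2], dm$scr[3]),
    apache2 = .rbeta_med(N, dm$apache2[1], dm$apache2[2], dm$apache2[3]),
    sex = ifelse(stats::runif(N) < design$male_fraction, "male", "female"))
  # per-subject base parameters: lognormal, arithmetic mean preserved
  tr <- design$truth
  base <- sapply(names(tr$mean), function(p) {
    cv <- tr$cv_pct[[p]] / 100
    sig <- sqrt(log(1 + cv^2))
    stats::rlnorm(N, log(tr$mean[[p]]) - sig^2 / 2, sig)
  })
  colnames(base) <- names(tr$mean)
  # per-subject sample counts
  n_per <- if (design$sampling == "rich") {
    rep(design$samples_per_subject, N)
  } else {
    base_n <- design$n_obs_total %/% N
    extra <- design$n_obs_total %% N
    cnt <- rep(base_n, N)
    if (extra > 0) cnt[sample.int(N, extra)] <- base_n + 1L
    cnt
  }
  subjects <- vector("list", N)
  truth_rows <- vector("list", N)
  two <- "Q" %in% colnames(base)
  for (i in seq_len(N)) {
    cv_i <- as.list(covs[i, ])
    load <- sample(design$loading_doses, 1)
    maint <- sample(design$maintenance_doses, 1)
    dur <- round(stats::runif(1, design$infusion_range[1],
                              design$infusion_range[2]) * 2) / 2
    reg <- regimen(maint, loading_dose = load, interval = design$interval,
                   infusion_duration = dur)
    doses <- regimen_doses(reg, design$n_intervals)
    # eligible maintenance doses starting at >= 48 h (troughs precede the
    # next dose, so anchor doses one interval later for troughs)
    anchors <- doses$time[doses$time >= 48 &
                            doses$time + 8 + dur <= max(doses$time) + design$interval]
    times <- numeric(0); kind <- character(0)
    if (design$sampling == "rich") {
      # profile both the first dose (distribution phase, pre-accumulation)
      # and one late occasion (steady state): together they identify Vc/Q/Vp
      # from the early shape and CL from the accumulation level
      occ <- c(dur + 0.1, dur + 0.75, 2.5, 4, 6.5, 9, 11.8)
      pool <- sort(c(occ, anchors[1] + occ))
      idx <- unique(round(seq(1, length(pool), length.out = min(n_per[i],
                                                                length(pool)))))
      times <- pool[idx]
      kind <- rep("rich", length(times))
      n_per[i] <- length(times)
    } else {
      for (k in seq_len(n_per[i])) {
        cat_k <- sample(names(design$sampling_mix), 1,
                        prob = design$sampling_mix)
        # troughs must precede an actual later dose
        pool <- if (cat_k == "trough")
          anchors[anchors + design$interval <= max(doses$time)]
        else anchors
        a <- if (length(pool) > 1) sample(pool, 1) else pool
        t_k <- switch(cat_k,
                      trough = a + design$interval - stats::runif(1, 0, 1),
                      peak = a + dur + stats::runif(1, 0, 1),
                      mid = a + dur + stats::runif(1, 6, 8))
        times <- c(times, t_k); kind <- c(kind, cat_k)
      }
      o <- order(times); times <- times[o]; kind <- kind[o]
    }
    theta_base <- do.call(pk_parameters, as.list(base[i, ]))
    theta_i <- apply_covariates(theta_base, cv_i, tr$covariates)
    pred <- if (two) predict_concentrations(theta_i, doses, times)
            else predict_one_compartment(theta_i, doses, times)
    sdv <- tr$error$gamma * sd_of_observation(pred, tr$error)
    conc <- pmax(pred + stats::rnorm(length(pred)) * sdv, 0)
    obs <- data.frame(time = times, conc = conc, blq = conc < design$lloq)
    attr(obs, "kind") <- kind
    id <- sprintf("S%02d", i)
    subjects[[i]] <- pk_subject(id, doses, obs, cv_i)
    attr(subjects[[i]]$observations, "kind") <- kind
    truth_rows[[i]] <- cbind(data.frame(id = id),
                             as.data.frame(t(base[i, ]))[paste0(colnames(base))],
                             data.frame(CL_i = unname(theta_i["CL"]),
                                        Vc_i = unname(theta_i["Vc"])))
  }
  truth <- do.call(rbind, truth_rows)
  names(truth)[2:(1 + ncol(base))] <- paste0(colnames(base), "0")
  list(cohort = pk_cohort(subjects), truth = truth)
}

#' End-to-end recovery harness
#'
#' Generates a cohort from known truth, fits it with [run_npag()], runs
#' [stepwise_select()] over the candidate covariate effects, and reports
#' truth-versus-estimate deltas for the population means plus which
#' covariate effects were accepted.
#'
#' @param design a [cohort_design()]
#' @param seed RNG seed for the generation
#' @param control [npag_control()] for the fits
#' @param candidates candidate [covariate_effect()]s for selection; `NULL`
#'   skips the selection stage
#' @param space [parameter_space()] for the fit
#' @return list: `truth_mean` (expected individual-parameter means),
#'   `fitted_mean`, `rel_error`, `selection` (from [stepwise_select()], or
#'   NULL), `fit`, `cohort`
#' @export
recovery_harness <- function(design = cohort_design(sampling = "rich",
                                                    n_subjects = 50),
                             seed = 1L,
                             control = npag_control(),
                             candidates = NULL,
                             space = parameter_space()) {
  gen <- generate_cohort(design, seed = seed)
  base_model <- model_spec(
    n_compartments = if ("Q" %in% names(design$truth$mean)) 2 else 1,
    error = error_spec(gamma = 5))
  fit <- run_npag(gen$cohort, base_model, space, control)
  fitted_mean <- .pop_means(fit)
  # expected mean of the individual parameters under the truth model
  truth_mean <- c(CL = mean(gen$truth$CL_i), Vc = mean(gen$truth$Vc_i),
                  Q = if ("Q0" %in% names(gen$truth)) mean(gen$truth$Q0) else NA,
                  Vp = if ("Vp0" %in% names(gen$truth)) mean(gen$truth$Vp0) else NA)
  truth_mean <- truth_mean[names(fitted_mean)]
  sel <- if (!is.null(candidates))
    stepwise_select(gen$cohort, fit, candidates, control = control)
  else NULL
  list(truth_mean = truth_mean, fitted_mean = fitted_mean,
       rel_error = (fitted_mean - truth_mean) / truth_mean,
       selection = sel, fit = fit, cohort = gen$cohort, truth = gen$truth)
}
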