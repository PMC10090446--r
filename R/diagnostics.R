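#' Goodness-of-fit table
#'
#' One record per quantifiable observation: observed value, population
#' prediction (weight-averaged over the fitted support), individual
#' posterior prediction, and weighted residuals
#' `(observed - prediction) / (gamma * SD(observed))` under both
#' conventions.  In a well-specified fit the weighted residuals lie mostly
#' within ±2.
#'
#' @param result an [run_npag()] fit
#' @param cohort the fitted cohort
#' @return list with `records` (data.frame: id, time, observed, pop_pred,
#'   post_pred, wres_pop, wres_post), `r2_pop`, `r2_post`
#' @export
gof_table <- function(result, cohort) {
  model <- result$model
  model$error$gamma <- result$gamma
  w <- result$support$weights
  cache <- .obs_cache(cohort, result$support$points, model)
  sw <- .ssw_from_cache(cache)
  ll <- .loglik_from_ssw(sw, result$gamma)
  m <- apply(ll, 1, max)
  P <- exp(ll - m)
  recs <- list()
  for (i in seq_along(cache)) {
    cc <- cache[[i]]
    if (cc$n == 0) next
    s <- cohort$subjects[[i]]
    obs <- s$observations[!s$observations$blq, , drop = FALSE]
    wpost <- w * P[i, ]; wpost <- wpost / sum(wpost)
    pop <- drop(cc$pred %*% w)
    post <- drop(cc$pred %*% wpost)
    denom <- result$gamma * cc$sd
    recs[[length(recs) + 1L]] <- data.frame(
      id = s$id, time = obs$time, observed = cc$y,
      pop_pred = pop, post_pred = post,
      wres_pop = (cc$y - pop) / denom,
      wres_post = (cc$y - post) / denom)
  }
  records <- do.call(rbind, recs)
  list(records = records,
       r2_pop = stats::cor(records$observed, records$pop_pred)^2,
       r2_post = stats::cor(records$observed, records$post_pred)^2)
}

# weighted population mean parameters of a fit
.pop_means <- function(fit) drop(fit$support$weights %*% fit$support$points)

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original cohort size, refits
#' each replicate with [run_npag()], and summarises the weighted population
#' mean of every parameter by its median and 2.5/97.5 percentiles.
#'
#' @param cohort a [pk_cohort()]
#' @param model a [model_spec()]
#' @param space a [parameter_space()]
#' @param B number of bootstrap replicates
#' @param control [npag_control()] for the replicate fits (typically a
#'   reduced budget)
#' @param seed RNG seed for the resampling
#' @return list of class `bootstrap_summary`: `summary` (data.frame of
#'   parameter, median, ci_low, ci_high), `B`, `replicates` (B x d matrix),
#'   `n_nonconverged`
#' @export
pk_bootstrap <- function(cohort, model, space, B = 200,
                         control = npag_control(), seed = 1L) {
  if (B < 2) stop("pk_bootstrap: need B >= 2")
  N <- length(cohort$subjects)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  draws <- matrix(sample.int(N, N * B, replace = TRUE), nrow = B)
  reps <- matrix(NA_real_, B, length(space$names),
                 dimnames = list(NULL, space$names))
  nonconv <- 0L
  for (b in seq_len(B)) {
    subs <- cohort$subjects[draws[b, ]]
    for (i in seq_along(subs)) subs[[i]]$id <- sprintf("%s.%d", subs[[i]]$id, i)
    fit <- run_npag(pk_cohort(subs), model, space, control)
    if (!fit$converged) nonconv <- nonconv + 1L
    reps[b, ] <- .pop_means(fit)
  }
  if (nonconv > 0.2 * B)
    stop(sprintf("pk_bootstrap: %d/%d replicates did not converge", nonconv, B))
  qs <- apply(reps, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  structure(list(summary = data.frame(parameter = space$names,
                                      median = qs[1, ], ci_low = qs[2, ],
                                      ci_high = qs[3, ], row.names = NULL),
                 B = B, replicates = reps, n_nonconverged = nonconv),
            class = "bootstrap_summary")
}

#' Data-splitting stability check
#'
#' Randomly partitions the subjects into an `fraction` / `1 - fraction`
#' split, fits the full cohort and both subsets independently, and tabulates
#' the weighted population mean and SD of every parameter for each fit —
#' stable estimates should agree across the three cohorts.
#'
#' @param cohort a [pk_cohort()]
#' @param model a [model_spec()]
#' @param space a [parameter_space()]
#' @param fraction size of the larger split, in (0, 1]; 1 skips the second
#'   split
#' @param control [npag_control()]
#' @param seed RNG seed for the partition
#' @return data.frame: parameter, cohort ("full"/"80%"/"20%"), mean, sd
#' @export
split_validate <- function(cohort, model, space, fraction = 0.8,
                           control = npag_control(), seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop("split_validate: fraction must be in (0, 1]")
  N <- length(cohort$subjects)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  n_big <- round(fraction * N)
  idx <- sample.int(N, n_big)
  pieces <- list(full = seq_len(N))
  if (fraction < 1) {
    pieces[[sprintf("%d%%", round(100 * fraction))]] <- idx
    pieces[[sprintf("%d%%", round(100 * (1 - fraction)))]] <- setdiff(seq_len(N), idx)
  }
  rows <- lapply(names(pieces), function(nm) {
    sel <- pieces[[nm]]
    if (length(sel) < 3)
      warning(sprintf("split_validate: %s split has only %d subjects", nm,
                      length(sel)))
    fit <- run_npag(pk_cohort(cohort$subjects[sel]), model, space, control)
    data.frame(parameter = space$names, cohort = nm,
               mean = .pop_means(fit),
               sd = apply(fit$support$points, 2, .weighted_sd,
                          w = fit$support$weights),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Visual-predictive-check table
#'
#' Simulates `n_sim` replicates of the cohort at its observed design (same
#' doses, sampling times and covariates), drawing each subject's parameters
#' from the fitted support (by weight) and residual noise from the error
#' model, then compares observed concentration percentiles with the
#' simulated percentile bands within time-after-last-dose bins.
#'
#' @param result an [run_npag()] fit
#' @param cohort the fitted cohort
#' @param n_sim number of simulated cohort replicates
#' @param bins number of quantile bins on time after last dose
#' @param seed RNG seed
#' @param probs percentiles summarised per bin
#' @return list of class `vpc_table`: `table` (bin, time range, n, observed
#'   and simulated percentiles with simulation CIs), `n_sim`
#' @export
vpc <- function(result, cohort, n_sim = 1000, bins = 6, seed = 1L,
                probs = c(0.05, 0.5, 0.95)) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  model <- result$model
  model$error$gamma <- result$gamma
  pts <- result$support$points
  w <- result$support$weights
  obs_all <- tad_all <- numeric(0)
  sims <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    obs <- s$observations[!s$observations$blq, , drop = FALSE]
    if (nrow(obs) == 0) next
    tad <- vapply(obs$time, function(t) {
      prior <- s$doses$time[s$doses$time <= t]
      if (length(prior)) t - max(prior) else t
    }, 0)
    obs_all <- c(obs_all, obs$conc)
    tad_all <- c(tad_all, tad)
    draw <- sample.int(nrow(pts), n_sim, replace = TRUE, prob = w)
    pred <- .predict_subject_matrix(s, pts[draw, , drop = FALSE], model,
                                    obs$time)
    noise <- matrix(stats::rnorm(length(pred)), nrow(pred))
    sdm <- result$gamma * sd_of_observation(pmax(pred, 0), model$error)
    sims[[i]] <- pmax(pred + noise * sdm, 0)   # n_obs x n_sim
  }
  simmat <- do.call(rbind, sims)
  # quantile bins on time after dose; merge any empty bin with its neighbor
  brk <- unique(stats::quantile(tad_all, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(tad_all, brk, include.lowest = TRUE)
  tab <- lapply(levels(bin), function(bl) {
    sel <- bin == bl
    if (!any(sel)) return(NULL)
    oq <- stats::quantile(obs_all[sel], probs)
    # per-replicate percentiles, then their median and 95% CI
    sq <- apply(simmat[sel, , drop = FALSE], 2, stats::quantile, probs = probs)
    sq <- if (is.null(dim(sq))) matrix(sq, nrow = length(probs)) else sq
    band <- apply(sq, 1, stats::quantile, probs = c(0.025, 0.5, 0.975))
    data.frame(bin = bl, n = sum(sel),
               tad_mid = stats::median(tad_all[sel]),
               pct = 100 * probs, observed = unname(oq),
               sim_lo = band[1, ], sim_med = band[2, ], sim_hi = band[3, ],
               row.names = NULL)
  })
  structure(list(table = do.call(rbind, tab), n_sim = n_sim),
            class = "vpc_table")
}
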