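#' Structural + covariate + error model specification
#'
#' Bundles the pieces that define the observation model: compartment count,
#' covariate model (mapping base parameters CL0/V0 to individual CL/Vc) and
#' residual-error specification.
#'
#' @param n_compartments 1 or 2
#' @param covariates a [covariate_model()]
#' @param error an [error_spec()]
#' @return object of class `model_spec`
#' @export
model_spec <- function(n_compartments = 2, covariates = covariate_model(),
                       error = error_spec()) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% c(1L, 2L)) stop("model_spec: 1 or 2 compartments")
  structure(list(n_compartments = n_compartments, covariates = covariates,
                 error = error), class = "model_spec")
}

#' Parameter-space box for the nonparametric estimator
#'
#' The support of the population distribution is searched inside this box.
#' Defaults cover the plausible critical-care range for polymyxin B
#' (literature means plus several between-subject SDs): CL 0.05-8 L/h,
#' Vc 1-120 L, Q 0.05-30 L/h, Vp 1-300 L.
#'
#' @param names parameter labels, in the column order used throughout
#' @param lower,upper bounds, elementwise `lower < upper`
#' @param n_compartments convenience: 1 drops Q and Vp from the defaults
#' @return object of class `parameter_space`
#' @export
parameter_space <- function(names = NULL, lower = NULL, upper = NULL,
                            n_compartments = 2) {
  if (is.null(names)) {
    names <- if (n_compartments == 2) c("CL", "Vc", "Q", "Vp") else c("CL", "Vc")
    lower <- c(CL = 0.05, Vc = 1, Q = 0.05, Vp = 1)[names]
    upper <- c(CL = 8, Vc = 120, Q = 30, Vp = 300)[names]
  }
  if (length(lower) != length(names) || length(upper) != length(names))
    stop("parameter_space: bounds must match names")
  if (any(lower >= upper)) stop("parameter_space: need lower < upper")
  structure(list(names = names, lower = stats::setNames(as.numeric(lower), names),
                 upper = stats::setNames(as.numeric(upper), names)),
            class = "parameter_space")
}

#' Discrete support of the population distribution
#'
#' @param points K x d matrix of parameter vectors (columns named)
#' @param weights K probabilities summing to 1
#' @return object of class `support_set`
#' @export
support_set <- function(points, weights) {
  points <- as.matrix(points)
  if (nrow(points) != length(weights))
    stop("support_set: points/weights mismatch")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-10)
    stop("support_set: weights must be a probability vector")
  structure(list(points = points, weights = pmax(weights, 0) / sum(pmax(weights, 0))),
            class = "support_set")
}

#' NPAG tuning parameters
#'
#' @param n_init initial grid size; default `512 * d` quasi-random points
#' @param max_cycles adaptive-grid cycle budget
#' @param tol convergence tolerance on -2LL between cycles
#' @param delta_init initial perturbation, as a fraction of each parameter
#'   range
#' @param delta_min smallest perturbation fraction before stopping
#' @param eps_w support points with weight below `eps_w * max(weight)` are
#'   dropped
#' @param eps_d points closer than `eps_d` (relative to each range) are
#'   merged
#' @param k_max support-size cap after condensation (top points by weight;
#'   `NULL` for `max(50, 5 * n_subjects)`).  Late in a run many perturbed
#'   points become likelihood-equivalent and EM spreads weight across them;
#'   capping prunes these near-duplicates without likelihood loss
#' @param gamma_range search interval for the residual-error scale
#' @param optimize_gamma re-optimise gamma each cycle (golden-section)
#' @param em_tol,em_max_iter weight-EM stopping rule
#' @param seed RNG seed for the quasi-random initial grid
#' @return list of class `npag_control`
#' @export
npag_control <- function(n_init = NULL, max_cycles = 50, tol = 0.01,
                         delta_init = 0.2, delta_min = 1e-4,
                         eps_w = 1e-8, eps_d = 1e-4, k_max = NULL,
                         gamma_range = c(0.01, 50), optimize_gamma = TRUE,
                         em_tol = 1e-10, em_max_iter = 5000, seed = 1L) {
  structure(as.list(environment()), class = "npag_control")
}

# ---------------------------------------------------------------------------
# Internal caches.  Predictions do not depend on gamma, so per (subject,
# support point) we cache n_obs predictions once and reduce them to
#   SSW[i, j] = sum_obs (y - pred)^2 / sd_assay(y)^2
# after which the log-likelihood at any gamma is
#   LL[i, j] = const_i - n_i log(gamma) - SSW[i, j] / (2 gamma^2),
# making the per-cycle 1-D gamma search essentially free.
# ---------------------------------------------------------------------------

# predictions for one subject at all rows of the base-parameter matrix
.predict_subject_matrix <- function(subject, theta, model, times) {
  th <- .apply_covariates_matrix(theta, subject$covariates, model$covariates)
  t(.conc_matrix(th, subject$doses, times, model$n_compartments))
}

# per-subject list: y, sd, n, pred (n x K)
.obs_cache <- function(cohort, theta, model) {
  lapply(cohort$subjects, function(s) {
    obs <- s$observations[!s$observations$blq, , drop = FALSE]
    if (nrow(obs) == 0)
      return(list(y = numeric(0), sd = numeric(0), n = 0L,
                  pred = matrix(0, 0, nrow(theta))))
    list(y = obs$conc, sd = sd_of_observation(obs$conc, model$error),
         n = nrow(obs),
         pred = .predict_subject_matrix(s, theta, model, obs$time))
  })
}

.ssw_from_cache <- function(cache) {
  K <- ncol(cache[[1]]$pred)
  ssw <- t(vapply(cache, function(cc) {
    if (cc$n == 0) return(numeric(K))
    colSums((cc$y - cc$pred)^2 / cc$sd^2)
  }, numeric(K)))
  const <- vapply(cache, function(cc)
    -sum(log(cc$sd)) - cc$n / 2 * log(2 * pi), numeric(1))
  nobs <- vapply(cache, function(cc) cc$n, integer(1))
  list(ssw = matrix(ssw, nrow = length(cache)), const = const, n = nobs)
}

.loglik_from_ssw <- function(sw, gamma) {
  sw$const - sw$n * log(gamma) - sw$ssw / (2 * gamma^2)
}

#' Likelihood matrix over a support set
#'
#' Returns the N x K matrix of subject likelihoods `p(subject_i | point_j)`
#' (each entry `exp` of [log_likelihood_subject()]), computed in log space
#' and rescaled by each row's maximum to avoid underflow.  The row scaling
#' is recorded in the `"log_scale"` attribute, so that the exact
#' log-likelihood of a weight vector `w` is
#' `sum(log(P %*% w) + attr(P, "log_scale"))`.
#'
#' @param cohort a [pk_cohort()]
#' @param support a [support_set()] (weights unused here)
#' @param model a [model_spec()]
#' @return scaled likelihood matrix with attribute `log_scale`
#' @export
likelihood_matrix <- function(cohort, support, model) {
  cache <- .obs_cache(cohort, support$points, model)
  sw <- .ssw_from_cache(cache)
  ll <- .loglik_from_ssw(sw, model$error$gamma)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll), arr.ind = TRUE)[1, ]
    stop(sprintf("likelihood_matrix: non-finite likelihood for subject %s at support point %d",
                 cohort$subjects[[bad[1]]]$id, bad[2]))
  }
  m <- apply(ll, 1, max)
  P <- exp(ll - m)
  attr(P, "log_scale") <- m
  P
}

#' Optimal mixing weights for a fixed support (EM)
#'
#' Maximises the nonparametric mixture log-likelihood
#' `sum_i log(sum_j P[i,j] w[j])` over the probability simplex with the
#' classical multiplicative (EM) update
#' `w_j <- (w_j / N) * sum_i P[i,j] / (P w)_i`, which increases the
#' objective at every step.
#'
#' @param P N x K non-negative likelihood matrix (each row must have a
#'   positive entry)
#' @param tol stop when the objective improves by less than this
#' @param max_iter iteration cap
#' @param w_init optional starting weights
#' @param trace record the objective path in attribute `"trace"`
#' @return weight vector with attributes `objective` (final log-likelihood,
#'   up to any row scaling of `P`) and `iterations`
#' @export
optimize_weights <- function(P, tol = 1e-10, max_iter = 10000, w_init = NULL,
                             trace = FALSE) {
  P <- as.matrix(P)
  N <- nrow(P); K <- ncol(P)
  if (any(P < 0)) stop("optimize_weights: negative likelihoods")
  dead <- which(rowSums(P) == 0)
  if (length(dead))
    stop("optimize_weights: subject(s) ", paste(dead, collapse = ", "),
         " have zero likelihood at every support point")
  w <- if (is.null(w_init)) rep(1 / K, K) else w_init / sum(w_init)
  # active-set bookkeeping: dominated columns shrink monotonically under the
  # multiplicative update, so once negligible they are dropped from the
  # O(N K) inner products
  active <- seq_len(K)
  Pa <- P
  mix <- drop(Pa %*% w)
  obj <- sum(log(mix))
  path <- if (trace) obj else NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- w * drop(crossprod(Pa, 1 / mix)) / N
    w <- w / sum(w)
    if (iter %% 25L == 0L && length(w) > N) {
      keep <- w > 1e-13 * max(w)
      if (!all(keep)) {
        Pa <- Pa[, keep, drop = FALSE]
        w <- w[keep] / sum(w[keep])
        active <- active[keep]
      }
    }
    mix <- drop(Pa %*% w)
    obj_new <- sum(log(mix))
    if (trace) path <- c(path, obj_new)
    if (obj_new - obj < tol) { obj <- obj_new; break }
    obj <- obj_new
  }
  w_full <- numeric(K)
  w_full[active] <- w
  w <- w_full
  attr(w, "objective") <- obj
  attr(w, "iterations") <- iter
  if (trace) attr(w, "trace") <- path
  w
}

# drop negligible-weight points, merge near-coincident ones, cap the
# support size; returns indices into the original columns plus merged
# weights
.condense <- function(points, w, space, eps_w, eps_d, k_max = Inf) {
  keep <- which(w > eps_w * max(w))
  pts <- points[keep, , drop = FALSE]
  wk <- w[keep]
  rng <- space$upper - space$lower
  rel <- sweep(pts, 2, rng, "/")
  o <- order(-wk)
  sel <- integer(0)
  for (i in o) {
    merged <- FALSE
    if (length(sel)) {
      d <- abs(rel[sel, , drop = FALSE] - matrix(rel[i, ], length(sel),
                                                 ncol(rel), byrow = TRUE))
      hit <- which(apply(d, 1, max) < eps_d)
      if (length(hit)) {
        wk[sel[hit[1]]] <- wk[sel[hit[1]]] + wk[i]
        merged <- TRUE
      }
    }
    if (!merged) sel <- c(sel, i)
  }
  if (length(sel) > k_max)
    sel <- sel[order(-wk[sel])][seq_len(k_max)]
  sel <- sort(sel)
  list(idx = keep[sel], weights = wk[sel] / sum(wk[sel]))
}

# columns (support candidates) whose best relative log-likelihood across
# subjects is below -drop nats can never attract EM weight; prune them
# before the (quadratic-cost) weight optimisation.  Protected columns are
# kept regardless.
.viable_columns <- function(sw, gamma, protect = integer(0), drop = 40) {
  ll <- .loglik_from_ssw(sw, gamma)
  m <- apply(ll, 1, max)
  best <- apply(sweep(ll, 1, m), 2, max)
  sort(unique(c(protect, which(best > -drop))))
}

# EM at a given gamma from cached sufficient statistics
.fit_weights_at_gamma <- function(sw, gamma, control, w_init = NULL,
                                  tol = NULL, max_iter = NULL) {
  ll <- .loglik_from_ssw(sw, gamma)
  m <- apply(ll, 1, max)
  P <- exp(ll - m)
  w <- optimize_weights(P, tol = if (is.null(tol)) control$em_tol else tol,
                        max_iter = if (is.null(max_iter)) control$em_max_iter
                                   else max_iter,
                        w_init = w_init)
  list(w = w, loglik = attr(w, "objective") + sum(m))
}

#' Nonparametric adaptive-grid population fit
#'
#' Estimates the population distribution of the structural parameters as a
#' discrete distribution (support points + weights) by maximum likelihood:
#'
#' 1. seed a quasi-random (Latin-hypercube) grid of `n_init` points in the
#'    parameter box;
#' 2. optimise the mixing weights by EM ([optimize_weights()]);
#' 3. condense: drop points with negligible weight, merge near-coincident
#'    points;
#' 4. re-optimise the residual-error scale `gamma` by a 1-D golden-section
#'    search (each cycle);
#' 5. expand: perturb each surviving point by ±delta of each parameter
#'    range (out-of-box proposals rejected), re-optimise weights;
#' 6. halve delta whenever a cycle improves -2LL by less than `tol`; stop
#'    when delta < `delta_min` and the improvement is below `tol`.
#'
#' @param cohort a [pk_cohort()]
#' @param model a [model_spec()]
#' @param space a [parameter_space()]
#' @param control an [npag_control()]
#' @param init_points optional matrix of additional starting support points
#'   (e.g. the support of a previously fitted reference model, as in
#'   sequential covariate-model building); appended to the quasi-random
#'   initial grid
#' @return object of class `npag_fit`: `support` ([support_set()]), `gamma`,
#'   `neg2ll`, `cycle_log`, `converged`, plus the model/space/control used
#' @export
run_npag <- function(cohort, model = model_spec(),
                     space = parameter_space(n_compartments = model$n_compartments),
                     control = npag_control(), init_points = NULL) {
  if (length(cohort$subjects) == 0) stop("run_npag: empty cohort")
  if (n_obs(cohort, blq = FALSE) == 0) stop("run_npag: no quantifiable observations")
  d <- length(space$names)
  n_init <- if (is.null(control$n_init)) 512L * d else control$n_init
  k_max <- if (is.null(control$k_max)) max(50L, 5L * length(cohort$subjects))
           else control$k_max
  if (!is.null(control$seed)) {
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(control$seed)
  }
  u <- lhs::randomLHS(n_init, d)
  points <- sweep(sweep(u, 2, space$upper - space$lower, "*"), 2,
                  space$lower, "+")
  colnames(points) <- space$names
  if (!is.null(init_points)) {
    init_points <- as.matrix(init_points)
    if (ncol(init_points) != d)
      stop("run_npag: init_points dimension does not match the parameter space")
    inbox <- apply(sweep(init_points, 2, space$lower, ">=") &
                     sweep(init_points, 2, space$upper, "<="), 1, all)
    points <- rbind(init_points[inbox, , drop = FALSE], points)
    colnames(points) <- space$names
  }
  gamma <- model$error$gamma
  sw <- .ssw_from_cache(.obs_cache(cohort, points, model))

  gamma_step <- function(sw, gamma, w) {
    if (!control$optimize_gamma) {
      ft <- .fit_weights_at_gamma(sw, gamma, control, w_init = w)
      return(list(gamma = gamma, w = ft$w, loglik = ft$loglik))
    }
    f <- function(g) .fit_weights_at_gamma(sw, g, control, w_init = w,
                                           tol = 1e-5, max_iter = 500)$loglik
    opt <- stats::optimize(f, interval = control$gamma_range,
                           maximum = TRUE, tol = 0.005)
    g <- if (opt$objective > f(gamma)) opt$maximum else gamma
    ft <- .fit_weights_at_gamma(sw, g, control, w_init = w)
    list(gamma = g, w = ft$w, loglik = ft$loglik)
  }

  # cycle 0: initial grid (dominated grid points pruned before the EM)
  keep0 <- .viable_columns(sw, gamma)
  points <- points[keep0, , drop = FALSE]
  sw$ssw <- sw$ssw[, keep0, drop = FALSE]
  st <- gamma_step(sw, gamma, NULL)
  gamma <- st$gamma
  cond <- .condense(points, st$w, space, control$eps_w, control$eps_d, k_max)
  points <- points[cond$idx, , drop = FALSE]
  sw$ssw <- sw$ssw[, cond$idx, drop = FALSE]
  w <- cond$weights
  neg2ll <- -2 * st$loglik
  log_rows <- list(data.frame(cycle = 0L, neg2ll = neg2ll,
                              K = nrow(points), delta = NA_real_))
  delta <- control$delta_init
  rng <- space$upper - space$lower
  converged <- FALSE

  for (cycle in seq_len(control$max_cycles)) {
    # expand around every surviving point
    K0 <- nrow(points)
    cand <- vector("list", 2L * d)
    for (j in seq_len(d)) {
      up <- points; up[, j] <- up[, j] + delta * rng[j]
      dn <- points; dn[, j] <- dn[, j] - delta * rng[j]
      cand[[2L * j - 1L]] <- up
      cand[[2L * j]] <- dn
    }
    cand <- do.call(rbind, cand)
    inbox <- apply(sweep(cand, 2, space$lower, ">=") &
                     sweep(cand, 2, space$upper, "<="), 1, all)
    cand <- cand[inbox, , drop = FALSE]
    all_pts <- rbind(points, cand)
    dup <- duplicated(all_pts)
    all_pts <- all_pts[!dup, , drop = FALSE]
    new_pts <- all_pts[-seq_len(K0), , drop = FALSE]
    sw_new <- .ssw_from_cache(.obs_cache(cohort, new_pts, model))
    sw$ssw <- cbind(sw$ssw, sw_new$ssw)
    points <- all_pts
    keepc <- .viable_columns(sw, gamma, protect = seq_len(K0))
    points <- points[keepc, , drop = FALSE]
    sw$ssw <- sw$ssw[, keepc, drop = FALSE]
    n_new <- nrow(points) - K0
    w0 <- c(0.9 * w, rep(0.1 / max(n_new, 1), n_new))
    st <- gamma_step(sw, gamma, w0)
    gamma <- st$gamma
    cond <- .condense(points, st$w, space, control$eps_w, control$eps_d, k_max)
    points <- points[cond$idx, , drop = FALSE]
    sw$ssw <- sw$ssw[, cond$idx, drop = FALSE]
    w <- cond$weights
    new_neg2ll <- -2 * st$loglik
    improvement <- neg2ll - new_neg2ll
    neg2ll <- min(neg2ll, new_neg2ll)
    log_rows[[cycle + 1L]] <- data.frame(cycle = cycle, neg2ll = new_neg2ll,
                                         K = nrow(points), delta = delta)
    if (improvement < control$tol) {
      if (delta <= control$delta_min) { converged <- TRUE; break }
      delta <- delta / 2
    }
  }

  model$error$gamma <- gamma
  structure(list(support = support_set(points, w),
                 gamma = gamma,
                 neg2ll = neg2ll,
                 cycle_log = do.call(rbind, log_rows),
                 converged = converged,
                 model = model, space = space, control = control,
                 seed = control$seed),
            class = "npag_fit")
}

#' @export
print.npag_fit <- function(x, ...) {
  cat(sprintf("NPAG fit: %d support points, gamma = %.3f, -2LL = %.2f (%s)\n",
              nrow(x$support$points), x$gamma, x$neg2ll,
              if (x$converged) "converged" else "cycle budget reached"))
  invisible(x)
}

#' Posterior distribution for one subject
#'
#' Bayes' rule on the fitted discrete population distribution:
#' `w_post_j = w_j p(subject | theta_j) / sum_l w_l p(subject | theta_l)`.
#' A subject with no quantifiable observations recovers the population
#' weights.
#'
#' @param result an [run_npag()] fit
#' @param subject a [pk_subject()]
#' @return list with `weights` (posterior over support points) and `mean`
#'   (posterior-mean [pk_parameters()])
#' @export
posterior_subject <- function(result, subject) {
  cache <- .obs_cache(pk_cohort(list(subject)), result$support$points,
                      result$model)
  sw <- .ssw_from_cache(cache)
  ll <- drop(.loglik_from_ssw(sw, result$gamma))
  lw <- log(result$support$weights) + ll
  wpost <- exp(lw - max(lw))
  wpost <- wpost / sum(wpost)
  mean_par <- drop(wpost %*% result$support$points)
  list(weights = wpost,
       mean = do.call(pk_parameters, as.list(mean_par)[c("CL", "Vc",
         if ("Q" %in% names(mean_par)) c("Q", "Vp"))]))
}

#' Posterior-mean parameter table for a cohort
#'
#' @param result an [run_npag()] fit
#' @param cohort the fitted cohort
#' @return data.frame: `id` plus one column per structural parameter
#' @export
posterior_table <- function(result, cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    pm <- posterior_subject(result, s)$mean
    cbind(data.frame(id = s$id), as.data.frame(t(unclass(pm)[result$space$names])))
  })
  do.call(rbind, rows)
}

.weighted_sd <- function(x, w) sqrt(sum(w * (x - sum(w * x))^2))
.weighted_median <- function(x, w) {
  o <- order(x)
  x[o][which(cumsum(w[o]) >= 0.5)[1]]
}

#' Fit indices and parameter summaries
#'
#' Model-comparison indices and per-parameter summaries of the fitted
#' population distribution.  With `k` = number of structural dimensions + 1
#' (for gamma) and `n` = quantifiable observations:
#' `AICc = -2LL + 2k + 2k(k+1)/(n-k-1)` and `BIC = -2LL + k log(n)`.
#' `r2_pop` is the squared Pearson correlation of observations with the
#' weight-averaged population prediction, `r2_post` with the
#' individual-posterior prediction.  Shrinkage per parameter is
#' `100 (1 - SD(posterior means) / population SD)`.
#'
#' @param result an [run_npag()] fit
#' @param cohort the fitted cohort
#' @return list of class `fit_metrics`: `neg2ll`, `aicc`, `bic`, `r2_pop`,
#'   `r2_post`, `n_obs`, `k`, and `parameters` (data.frame of mean, median,
#'   SD, CV%, shrinkage%)
#' @export
fit_metrics <- function(result, cohort) {
  pts <- result$support$points
  w <- result$support$weights
  k <- ncol(pts) + 1L
  model <- result$model
  model$error$gamma <- result$gamma
  cache <- .obs_cache(cohort, pts, model)
  sw <- .ssw_from_cache(cache)
  n <- sum(sw$n)
  if (n <= k + 1)
    stop("fit_metrics: AICc undefined with n_obs <= k + 1")
  ll <- .loglik_from_ssw(sw, result$gamma)
  m <- apply(ll, 1, max)
  P <- exp(ll - m)
  obs <- pop <- post <- numeric(0)
  for (i in seq_along(cache)) {
    cc <- cache[[i]]
    if (cc$n == 0) next
    wpost <- w * P[i, ]
    wpost <- wpost / sum(wpost)
    obs <- c(obs, cc$y)
    pop <- c(pop, drop(cc$pred %*% w))
    post <- c(post, drop(cc$pred %*% wpost))
  }
  pm <- posterior_table(result, cohort)
  mu <- drop(w %*% pts)
  sdv <- apply(pts, 2, .weighted_sd, w = w)
  shr <- 100 * (1 - apply(pm[, -1, drop = FALSE], 2, stats::sd) / sdv)
  pars <- data.frame(parameter = colnames(pts), mean = mu,
                     median = apply(pts, 2, .weighted_median, w = w),
                     sd = sdv, cv_pct = 100 * sdv / mu,
                     shrinkage_pct = as.numeric(shr), row.names = NULL)
  structure(list(neg2ll = result$neg2ll,
                 aicc = information_criteria(result$neg2ll, k, n)["aicc"],
                 bic = information_criteria(result$neg2ll, k, n)["bic"],
                 r2_pop = stats::cor(obs, pop)^2,
                 r2_post = stats::cor(obs, post)^2,
                 n_obs = n, k = k, parameters = pars),
            class = "fit_metrics")
}

#' Small-sample information criteria
#'
#' @param neg2ll -2 log-likelihood
#' @param k number of effective parameters (structural dimensions + 1 for
#'   gamma)
#' @param n number of observations
#' @return named vector `c(aicc = , bic = )`
#' @examples
#' information_criteria(145.6, 5, 64)  # AICc 156.6, BIC 166.4
#' @export
information_criteria <- function(neg2ll, k, n) {
  if (n <= k + 1) stop("information_criteria: n must exceed k + 1")
  c(aicc = neg2ll + 2 * k + 2 * k * (k + 1) / (n - k - 1),
    bic = neg2ll + k * log(n))
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("-2LL %.2f  AICc %.2f  BIC %.2f  R2(pop) %.3f  R2(post) %.3f  [n=%d, k=%d]\n",
              x$neg2ll, x$aicc, x$bic, x$r2_pop, x$r2_post, x$n_obs, x$k))
  print(x$parameters, digits = 4)
  invisible(x)
}
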