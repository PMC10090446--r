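#' Pharmacokinetic parameter set
#'
#' Constructs and validates a parameter vector for the structural model.
#' `CL` is central clearance (L/h), `Vc` the central volume of
#' distribution (L); for the two-compartment model `Q` (inter-compartmental
#' clearance, L/h) and `Vp` (peripheral volume, L) are also required.
#'
#' @param CL central clearance, L/h
#' @param Vc central volume, L
#' @param Q inter-compartmental clearance, L/h (`NA` for one compartment)
#' @param Vp peripheral volume, L (`NA` for one compartment)
#' @return named numeric vector of class `pk_parameters`
#' @examples
#' pk_parameters(CL = 1.24, Vc = 16.64, Q = 3.04, Vp = 66.2)
#' @export
pk_parameters <- function(CL, Vc, Q = NA_real_, Vp = NA_real_) {
  p <- c(CL = as.numeric(CL), Vc = as.numeric(Vc),
         Q = as.numeric(Q), Vp = as.numeric(Vp))
  present <- !is.na(p)
  if (any(p[present] <= 0) || !all(is.finite(p[present])))
    stop("pk_parameters: all supplied parameters must be strictly positive and finite")
  if (is.na(p["Q"]) != is.na(p["Vp"]))
    stop("pk_parameters: Q and Vp must be supplied together or both omitted")
  class(p) <- "pk_parameters"
  p
}

#' Dosing events
#'
#' Builds the dosing-history table used by the prediction functions: one row
#' per intravenous infusion, on a time axis of hours since the first dose.
#'
#' @param time start of each infusion, h (>= 0)
#' @param amount dose, mg (>= 0)
#' @param duration infusion length, h (> 0)
#' @return data.frame with columns `time`, `amount`, `duration` and derived
#'   `rate` (mg/h), sorted by `time`
#' @export
dose_events <- function(time, amount, duration) {
  n <- length(time)
  if (length(amount) != n || length(duration) != n)
    stop("dose_events: time, amount and duration must have equal length")
  if (n == 0)
    return(data.frame(time = numeric(0), amount = numeric(0),
                      duration = numeric(0), rate = numeric(0)))
  if (any(time < 0)) stop("dose_events: negative dose time")
  if (any(amount < 0)) stop("dose_events: negative dose amount")
  if (any(duration <= 0)) stop("dose_events: infusion duration must be > 0")
  d <- data.frame(time = time, amount = amount, duration = duration,
                  rate = amount / duration)
  if (any(!is.finite(d$rate))) stop("dose_events: non-finite infusion rate")
  d[order(d$time), , drop = FALSE]
}

#' Maintenance dosing regimen
#'
#' @param loading_dose loading dose, mg (given at time 0)
#' @param maintenance_dose maintenance dose, mg
#' @param interval dosing interval, h
#' @param infusion_duration infusion length, h
#' @param label optional regimen label (e.g. "I" for 100 mg q12h)
#' @return object of class `pk_regimen`
#' @export
regimen <- function(maintenance_dose, loading_dose = 0, interval = 12,
                    infusion_duration = 1, label = NULL) {
  if (interval <= infusion_duration || infusion_duration <= 0)
    stop("regimen: require interval > infusion_duration > 0")
  if (maintenance_dose < 0 || loading_dose < 0)
    stop("regimen: doses must be non-negative")
  structure(list(loading_dose = loading_dose,
                 maintenance_dose = maintenance_dose,
                 interval = interval,
                 infusion_duration = infusion_duration,
                 label = label),
            class = "pk_regimen")
}

#' Expand a regimen into explicit dosing events
#'
#' @param reg a [regimen()]
#' @param n_doses number of maintenance doses following the loading dose
#' @return data.frame as returned by [dose_events()]
#' @export
regimen_doses <- function(reg, n_doses) {
  stopifnot(inherits(reg, "pk_regimen"), n_doses >= 0)
  if (reg$loading_dose > 0) {
    times <- c(0, seq_len(n_doses) * reg$interval)
    amts <- c(reg$loading_dose, rep(reg$maintenance_dose, n_doses))
  } else {
    times <- (seq_len(n_doses) - 1) * reg$interval
    amts <- rep(reg$maintenance_dose, n_doses)
  }
  if (length(times) == 0) return(dose_events(numeric(0), numeric(0), numeric(0)))
  dose_events(times, amts, rep(reg$infusion_duration, length(times)))
}

# ---------------------------------------------------------------------------
# Closed-form propagation.
#
# Two-compartment rate constants: k10 = CL/Vc (elimination), k12 = Q/Vc,
# k21 = Q/Vp.  The system matrix A = [[-(k10+k12), k21], [k12, -k21]] has
# discriminant (k10-k21)^2 + k12^2 + 2*k12*(k10+k21) > 0 whenever Q > 0,
# so eigenvalues are real, negative and distinct and exp(A h) is evaluated
# spectrally with no degenerate branch.  During a constant-rate infusion R
# the stationary point is (R*Vc/CL, R*Vp/CL) and
# x(t) = x_ss + exp(A t) (x0 - x_ss).
# ---------------------------------------------------------------------------

# one propagation step for all K parameter rows at once
.step2 <- function(X1, X2, h, R, k10, k12, k21) {
  X1s <- R / k10
  X2s <- X1s * k12 / k21
  s <- k10 + k12 + k21
  disc <- sqrt(s * s - 4 * k10 * k21)
  l1 <- (-s + disc) / 2
  l2 <- (-s - disc) / 2
  a11 <- -(k10 + k12)
  E1 <- exp(l1 * h)
  E2 <- exp(l2 * h)
  dn <- l1 - l2
  co <- (E1 - E2) / dn
  M11 <- ((a11 - l2) * E1 - (a11 - l1) * E2) / dn
  M22 <- ((-k21 - l2) * E1 - (-k21 - l1) * E2) / dn
  Y1 <- X1 - X1s
  Y2 <- X2 - X2s
  list(X1 = X1s + M11 * Y1 + k21 * co * Y2,
       X2 = X2s + k12 * co * Y1 + M22 * Y2)
}

# piecewise-constant infusion rate: breakpoints + rate on each interval
.rate_schedule <- function(doses, extra_times) {
  ev_t <- c(doses$time, doses$time + doses$duration)
  ev_dr <- c(doses$rate, -doses$rate)
  knots <- sort(unique(c(0, ev_t, extra_times)))
  # rate on [knots[i], knots[i+1]) = sum of onsets minus offsets at t <= knots[i]
  o <- order(ev_t)
  ev_t <- ev_t[o]; ev_dr <- ev_dr[o]
  csum <- cumsum(ev_dr)
  idx <- findInterval(knots, ev_t)
  rate <- ifelse(idx == 0, 0, csum[pmax(idx, 1)])
  # clip tiny negative accumulation noise
  rate[abs(rate) < 1e-12] <- 0
  list(knots = knots, rate = rate)
}

# core: concentrations for K parameter vectors (rows of theta) at `times`
# theta columns: CL, Vc, Q, Vp (Q, Vp ignored when n_compartments == 1)
.conc_matrix <- function(theta, doses, times, n_compartments = 2) {
  K <- nrow(theta)
  nt <- length(times)
  if (nt == 0) return(matrix(0, K, 0))
  if (any(times < 0)) stop("prediction times must be non-negative")
  if (is.unsorted(times)) stop("prediction times must be sorted")
  if (nrow(doses) == 0 || all(doses$amount == 0))
    return(matrix(0, K, nt))
  CL <- theta[, 1]; Vc <- theta[, 2]
  if (any(CL <= 0) || any(Vc <= 0))
    stop("non-positive PK parameter")
  k10 <- CL / Vc
  two <- n_compartments == 2
  if (two) {
    Q <- theta[, 3]; Vp <- theta[, 4]
    if (any(Q <= 0) || any(Vp <= 0)) stop("non-positive PK parameter")
    k12 <- Q / Vc; k21 <- Q / Vp
  }
  sched <- .rate_schedule(doses, times)
  knots <- sched$knots; rate <- sched$rate
  X1 <- numeric(K); X2 <- numeric(K)
  out <- matrix(NA_real_, K, nt)
  for (i in seq_along(knots)) {
    hit <- which(times == knots[i])
    if (length(hit)) out[, hit] <- X1 / Vc
    if (i < length(knots)) {
      h <- knots[i + 1] - knots[i]
      R <- rate[i]
      if (two) {
        st <- .step2(X1, X2, h, R, k10, k12, k21)
        X1 <- st$X1; X2 <- st$X2
      } else {
        X1s <- R / k10
        X1 <- X1s + (X1 - X1s) * exp(-k10 * h)
      }
    }
  }
  out
}

#' Predict concentrations under the two-compartment infusion model
#'
#' Solves, in closed form, the linear two-compartment disposition system
#' \deqn{dX_1/dt = R(t) - (CL/V_c + Q/V_c) X_1 + (Q/V_p) X_2}
#' \deqn{dX_2/dt = (Q/V_c) X_1 - (Q/V_p) X_2}
#' with piecewise-constant infusion rate \eqn{R(t)}, and returns the central
#' concentration \eqn{X_1(t)/V_c} at the requested times.  The state is
#' propagated analytically across every infusion start/stop boundary
#' (spectral matrix exponential per segment), so accuracy does not depend on
#' any solver tolerance.
#'
#' @param params a [pk_parameters()] with `CL`, `Vc`, `Q`, `Vp`
#' @param doses dosing history from [dose_events()] or [regimen_doses()]
#' @param times sorted, non-negative observation times, h
#' @return numeric vector of concentrations, mg/L
#' @examples
#' p <- pk_parameters(CL = 1.24, Vc = 16.64, Q = 3.04, Vp = 66.2)
#' d <- dose_events(0, 75, 1)
#' predict_concentrations(p, d, c(0.5, 1, 2, 8))
#' @export
predict_concentrations <- function(params, doses, times) {
  p <- if (inherits(params, "pk_parameters")) params else do.call(pk_parameters, as.list(params))
  if (is.na(p["Q"]))
    stop("predict_concentrations: two-compartment model requires Q and Vp; see predict_one_compartment")
  drop(.conc_matrix(matrix(p[c("CL", "Vc", "Q", "Vp")], 1), doses, times, 2L))
}

#' Predict concentrations under the one-compartment infusion model
#'
#' As [predict_concentrations()] but with a single disposition compartment:
#' \eqn{dX/dt = R(t) - (CL/V_c) X}.
#'
#' @inheritParams predict_concentrations
#' @return numeric vector of concentrations, mg/L
#' @export
predict_one_compartment <- function(params, doses, times) {
  p <- if (inherits(params, "pk_parameters")) params else do.call(pk_parameters, as.list(params))
  drop(.conc_matrix(matrix(p[c("CL", "Vc")], 1), doses, times, 1L))
}

#' Steady-state 24-hour area under the curve
#'
#' For linear pharmacokinetics the steady-state AUC over 24 h depends only on
#' the daily maintenance dose and clearance:
#' \deqn{AUC_{ss,24h} = (24/\tau) \cdot D_{maint} / CL}
#' independent of the compartmental structure or infusion duration.  The
#' loading dose does not contribute at steady state.
#'
#' @param params [pk_parameters()] (only `CL` is used)
#' @param reg a [regimen()]
#' @return AUC, mg·h/L
#' @examples
#' steady_state_auc24(pk_parameters(CL = 1.24, Vc = 16.64, Q = 3.04, Vp = 66.2),
#'                    regimen(75))
#' @export
steady_state_auc24 <- function(params, reg) {
  p <- if (inherits(params, "pk_parameters")) params else do.call(pk_parameters, as.list(params))
  stopifnot(inherits(reg, "pk_regimen"))
  (24 / reg$interval) * reg$maintenance_dose / unname(p["CL"])
}
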