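#' Multiplicative polynomial residual-error model
#'
#' The assay error is a cubic polynomial in the observed concentration,
#' \deqn{SD(C_{obs}) = C_0 + C_1 C_{obs} + C_2 C_{obs}^2 + C_3 C_{obs}^3,}
#' and the total residual standard deviation is `gamma * SD` where `gamma`
#' is a dimensionless process-noise multiplier (mis-recorded sampling times,
#' dosing imprecision, model misspecification).  Observations are weighted
#' by `1 / (gamma * SD)^2` in the likelihood.
#'
#' Defaults: `c0 = 0.1` mg/L, `c1 = 0.15`, `c2 = c3 = 0`, starting
#' `gamma = 5` (re-optimised during fitting; a well-behaved fit typically
#' ends below 1).
#'
#' @param c0,c1,c2,c3 polynomial coefficients (mg/L, unitless, (mg/L)^-1,
#'   (mg/L)^-2)
#' @param gamma multiplicative scale, > 0
#' @return object of class `error_spec`
#' @export
error_spec <- function(c0 = 0.1, c1 = 0.15, c2 = 0, c3 = 0, gamma = 5) {
  if (gamma <= 0) stop("error_spec: gamma must be > 0")
  structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3, gamma = gamma),
            class = "error_spec")
}

#' Assay standard deviation at an observed concentration
#'
#' @param c_obs observed concentration(s), mg/L, >= 0
#' @param spec an [error_spec()]
#' @return SD in mg/L (before gamma scaling)
#' @examples
#' sd_of_observation(1.0, error_spec())  # 0.25
#' @export
sd_of_observation <- function(c_obs, spec = error_spec()) {
  if (any(c_obs < 0)) stop("sd_of_observation: negative concentration")
  s <- spec$c0 + spec$c1 * c_obs + spec$c2 * c_obs^2 + spec$c3 * c_obs^3
  if (any(s <= 0))
    stop("sd_of_observation: error polynomial non-positive at an observed concentration")
  s
}

#' Observation log-likelihood for one subject
#'
#' Gaussian log-density of the subject's non-BLQ observations around the
#' structural-model predictions, with standard deviation
#' `gamma * sd_of_observation(c_obs)` (the polynomial is evaluated at the
#' observed, not predicted, concentration).  BLQ observations are excluded.
#'
#' @param params [pk_parameters()] for this subject
#' @param subject a [pk_subject()]
#' @param spec an [error_spec()]
#' @param n_compartments 1 or 2
#' @return scalar log-likelihood; 0 (with a warning) if the subject has no
#'   quantifiable observations
#' @export
log_likelihood_subject <- function(params, subject, spec = error_spec(),
                                   n_compartments = 2) {
  obs <- subject$observations
  obs <- obs[!obs$blq, , drop = FALSE]
  if (nrow(obs) == 0) {
    warning("log_likelihood_subject: subject ", subject$id,
            " has no quantifiable observations; returning 0")
    return(0)
  }
  pred <- if (n_compartments == 2)
    predict_concentrations(params, subject$doses, obs$time)
  else predict_one_compartment(params, subject$doses, obs$time)
  sds <- spec$gamma * sd_of_observation(obs$conc, spec)
  sum(stats::dnorm(obs$conc, mean = pred, sd = sds, log = TRUE))
}
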