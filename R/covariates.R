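#' Cockcroft-Gault creatinine clearance
#'
#' \deqn{CCR = (140 - age) \cdot WT / (72 \cdot Scr/88.4)} in mL/min, with
#' serum creatinine in umol/L (the division by 88.4 converts to mg/dL), and
#' a factor 0.85 for female patients.
#'
#' @param age years (< 140)
#' @param wt weight, kg
#' @param scr serum creatinine, umol/L
#' @param sex "male" or "female"
#' @return creatinine clearance, mL/min
#' @examples
#' cockcroft_gault(40, 72, 88.4, "male")  # 100
#' @export
cockcroft_gault <- function(age, wt, scr, sex) {
  if (any(age >= 140)) stop("cockcroft_gault: age must be < 140")
  if (any(c(age, wt, scr) <= 0)) stop("cockcroft_gault: inputs must be positive")
  sex <- match.arg(tolower(sex), c("male", "female"), several.ok = TRUE)
  ccr <- (140 - age) * wt / (72 * scr / 88.4)
  ccr * ifelse(sex == "female", 0.85, 1)
}

#' A single power-law covariate effect
#'
#' Multiplies a base structural parameter by `(covariate / reference) ^
#' exponent`, e.g. `CL = CL0 * (ALB/31.45)^(-0.95)`.
#'
#' @param target "CL" or "Vc"
#' @param covariate one of "alb", "age", "apache2", "wt", "ccr"
#' @param reference centering value (cohort median), same units as the
#'   covariate
#' @param exponent power
#' @return object of class `covariate_effect`
#' @export
covariate_effect <- function(target, covariate, reference, exponent) {
  target <- match.arg(target, c("CL", "Vc"))
  covariate <- match.arg(covariate, c("alb", "age", "apache2", "wt", "ccr"))
  if (reference <= 0) stop("covariate_effect: reference must be positive")
  if (!is.finite(exponent)) stop("covariate_effect: exponent must be finite")
  structure(list(target = target, covariate = covariate,
                 reference = reference, exponent = exponent),
            class = "covariate_effect")
}

#' Set of covariate effects
#'
#' At most one effect per (target parameter, covariate) pair.  The empty
#' model (no effects) is the base structural model.
#'
#' @param ... [covariate_effect()] objects
#' @return object of class `covariate_model`
#' @export
covariate_model <- function(...) {
  effects <- list(...)
  if (length(effects) == 1 && is.list(effects[[1]]) &&
      !inherits(effects[[1]], "covariate_effect"))
    effects <- effects[[1]]
  keys <- vapply(effects, function(e) paste(e$target, e$covariate), character(1))
  if (anyDuplicated(keys))
    stop("covariate_model: duplicate effect for ", keys[duplicated(keys)][1])
  structure(list(effects = effects), class = "covariate_model")
}

#' The published final covariate model
#'
#' Age on central volume and albumin on clearance, both with exponent
#' magnitude 0.95 and cohort-median centering (age 68 y, ALB 31.45 g/L):
#' `Vc = V0 * (age/68)^0.95`, `CL = CL0 * (ALB/31.45)^(-0.95)`.
#'
#' @return a [covariate_model()]
#' @export
final_covariate_model <- function() {
  covariate_model(
    covariate_effect("Vc", "age", 68, 0.95),
    covariate_effect("CL", "alb", 31.45, -0.95))
}

# value of a named covariate for a covariate list, deriving ccr on demand
.cov_value <- function(covariates, name) {
  if (name == "ccr") {
    v <- cockcroft_gault(covariates$age, covariates$wt, covariates$scr,
                         covariates$sex)
  } else v <- covariates[[name]]
  if (is.null(v) || is.na(v))
    stop("apply_covariates: missing covariate '", name, "'")
  v
}

#' Apply a covariate model to base parameters
#'
#' Each effect multiplies its target parameter by
#' `(covariate/reference)^exponent`; `Q` and `Vp` pass through unchanged.
#' With every covariate at its reference value this is the identity.
#'
#' @param base [pk_parameters()] holding the base (CL0, V0) values
#' @param covariates named list as in [pk_subject()]
#' @param model a [covariate_model()]
#' @return [pk_parameters()] for the individual
#' @export
apply_covariates <- function(base, covariates, model) {
  p <- unclass(base)
  for (e in model$effects) {
    v <- .cov_value(covariates, e$covariate)
    p[e$target] <- p[e$target] * (v / e$reference)^e$exponent
  }
  class(p) <- "pk_parameters"
  p
}

# vectorised over a K x 4 theta matrix (columns CL, Vc, Q, Vp)
.apply_covariates_matrix <- function(theta, covariates, model) {
  if (length(model$effects) == 0) return(theta)
  col <- c(CL = 1L, Vc = 2L)
  for (e in model$effects) {
    v <- .cov_value(covariates, e$covariate)
    j <- col[[e$target]]
    theta[, j] <- theta[, j] * (v / e$reference)^e$exponent
  }
  theta
}

#' Screen covariates by linear regression on posterior estimates
#'
#' Ordinary least squares of each subject-level posterior-mean parameter
#' against each covariate; reports the slope and R^2 (squared Pearson
#' correlation).  A zero-variance covariate gets R^2 = 0 and a flag.
#'
#' @param posteriors data.frame with column `id` plus one column per
#'   structural parameter (as from [posterior_table()])
#' @param cohort the fitted [pk_cohort()] (source of covariate values)
#' @param covariates which covariates to screen
#' @return data.frame with columns `parameter`, `covariate`, `slope`, `r2`,
#'   `degenerate`
#' @export
screen_covariates <- function(posteriors, cohort,
                              covariates = c("age", "wt", "ccr", "alb", "apache2")) {
  if (nrow(posteriors) < 3) stop("screen_covariates: need at least 3 subjects")
  subj <- cohort$subjects[match(posteriors$id,
                                vapply(cohort$subjects, `[[`, "", "id"))]
  covmat <- sapply(covariates, function(nm)
    vapply(subj, function(s) tryCatch(.cov_value(s$covariates, nm),
                                      error = function(e) NA_real_), 0))
  pars <- setdiff(names(posteriors), "id")
  out <- expand.grid(parameter = pars, covariate = covariates,
                     stringsAsFactors = FALSE)
  res <- t(mapply(function(p, cv) {
    x <- covmat[, cv]; y <- posteriors[[p]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(slope = NA_real_, r2 = 0, degenerate = 1))
    fit <- stats::lm.fit(cbind(1, x), y)
    c(slope = fit$coefficients[2], r2 = stats::cor(x, y)^2, degenerate = 0)
  }, out$parameter, out$covariate))
  out$slope <- res[, 1]; out$r2 <- res[, 2]
  out$degenerate <- res[, 3] == 1
  out[order(out$parameter, -out$r2), ]
}
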