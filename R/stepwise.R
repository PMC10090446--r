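#' Chi-squared covariate-inclusion constant
#'
#' Threshold on the drop in -2LL for adding one covariate effect: the 99th
#' percentile of the chi-squared distribution with one degree of freedom
#' (p < 0.01, df = 1), rounded to two decimals: 6.63.  Acceptance requires
#' a drop strictly greater than this value.
#'
#' @return 6.63
#' @export
chisq_inclusion_threshold <- function() {
  round(stats::qchisq(0.99, df = 1), 2)
}

#' Stepwise covariate selection
#'
#' Refits the model with each candidate effect added to the base model and
#' accepts a candidate when the drop in -2LL exceeds
#' [chisq_inclusion_threshold()] (strictly) **or** the population fit value
#' R2(pop) improves over the base model.  When more than one candidate is
#' accepted, the combined model is also fitted and returned as the final
#' model.  A candidate whose refit does not converge is marked in the
#' comparison table rather than silently dropped.
#'
#' @param cohort a [pk_cohort()]
#' @param base_fit [run_npag()] fit of the base model
#' @param candidates list of [covariate_effect()] objects
#' @param control [npag_control()] for the refits (defaults to the base
#'   fit's control)
#' @return list with `model` (final [covariate_model()]), `fit` (final
#'   [run_npag()] fit), and `table` (one row per fitted model: label,
#'   parameters, -2LL, AICc, BIC, R2 pop/post, accepted, converged)
#' @export
stepwise_select <- function(cohort, base_fit, candidates,
                            control = base_fit$control) {
  base_model <- base_fit$model
  # polish the base with the same warm-started pass the candidates get, so
  # the comparison is symmetric in optimisation depth
  if (length(candidates) > 0) {
    polished <- run_npag(cohort, base_model, base_fit$space, control,
                         init_points = base_fit$support$points)
    if (polished$neg2ll <= base_fit$neg2ll) base_fit <- polished
  }
  base_metrics <- fit_metrics(base_fit, cohort)
  thr <- chisq_inclusion_threshold()
  describe <- function(cm) {
    if (length(cm$effects) == 0) return("base")
    paste(vapply(cm$effects, function(e)
      sprintf("%s~%s^%.2f", e$target, e$covariate, e$exponent), ""),
      collapse = " + ")
  }
  row_of <- function(label, metrics, accepted, converged) {
    data.frame(model = label, neg2ll = metrics$neg2ll,
               aicc = unname(metrics$aicc), bic = unname(metrics$bic),
               r2_pop = metrics$r2_pop, r2_post = metrics$r2_post,
               accepted = accepted, converged = converged,
               stringsAsFactors = FALSE)
  }
  rows <- list(row_of(describe(base_model$covariates), base_metrics, NA, base_fit$converged))
  base_keys <- vapply(base_model$covariates$effects,
                      function(e) paste(e$target, e$covariate), character(1))
  accepted <- list()
  fits <- list()
  for (cand in candidates) {
    key <- paste(cand$target, cand$covariate)
    if (key %in% base_keys) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = sprintf("%s~%s (duplicate)", cand$target, cand$covariate),
        neg2ll = NA, aicc = NA, bic = NA, r2_pop = NA, r2_post = NA,
        accepted = FALSE, converged = NA)
      next
    }
    m <- base_model
    m$covariates <- covariate_model(c(base_model$covariates$effects, list(cand)))
    # warm-start from the base support: sequential model building keeps the
    # search error correlated between the models being compared
    fit <- run_npag(cohort, m, base_fit$space, control,
                    init_points = base_fit$support$points)
    met <- fit_metrics(fit, cohort)
    ok <- (base_metrics$neg2ll - met$neg2ll > thr) ||
      (met$r2_pop > base_metrics$r2_pop)
    rows[[length(rows) + 1L]] <- row_of(describe(m$covariates), met, ok,
                                        fit$converged)
    if (ok) {
      accepted[[length(accepted) + 1L]] <- cand
      fits[[length(fits) + 1L]] <- fit
    }
  }
  if (length(accepted) == 0) {
    final_model <- base_model$covariates
    final_fit <- base_fit
  } else if (length(accepted) == 1) {
    final_model <- covariate_model(c(base_model$covariates$effects, accepted))
    final_fit <- fits[[1]]
  } else {
    m <- base_model
    m$covariates <- covariate_model(c(base_model$covariates$effects, accepted))
    final_fit <- run_npag(cohort, m, base_fit$space, control,
                          init_points = base_fit$support$points)
    met <- fit_metrics(final_fit, cohort)
    rows[[length(rows) + 1L]] <- row_of(describe(m$covariates), met, TRUE,
                                        final_fit$converged)
    final_model <- m$covariates
  }
  list(model = final_model, fit = final_fit,
       table = do.call(rbind, rows))
}
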