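#' Pipeline configuration
#'
#' Assembles (and optionally reads from a YAML file) the configuration for
#' the end-to-end workflow.  Every default equals the documented default of
#' the module that owns it; values given in `...` (or in the YAML file)
#' override defaults by name, e.g.
#' `pipeline_config(fit = list(seed = 7), pta = list(n = 500))`.
#'
#' Sections: `simulate` (cohort design arguments), `fit` (compartments,
#' error coefficients, starting gamma, bounds, NPAG budgets, seed),
#' `covariates` (candidate effects), `validate` (bootstrap B, split
#' fraction, VPC n_sim/bins, seeds), `pta` (targets, n, seed), `lloq`.
#'
#' @param path optional YAML file; its entries override the defaults, and
#'   `...` overrides both
#' @param ... named section overrides
#' @return nested list of class `pipeline_config`
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    lloq = 0.19,
    simulate = list(n_subjects = 22, n_obs_total = 64, sampling = "sparse",
                    seed = 1L),
    fit = list(n_compartments = 2,
               error = list(c0 = 0.1, c1 = 0.15, c2 = 0, c3 = 0, gamma = 5),
               bounds = list(CL = c(0.05, 8), Vc = c(1, 120),
                             Q = c(0.05, 30), Vp = c(1, 300)),
               control = list(max_cycles = 50, tol = 0.01, seed = 1L)),
    covariates = list(candidates = list(
      list(target = "Vc", covariate = "age", reference = 68, exponent = 0.95),
      list(target = "CL", covariate = "alb", reference = 31.45,
           exponent = -0.95))),
    validate = list(bootstrap_B = 200, split_fraction = 0.8, vpc_n_sim = 1000,
                    vpc_bins = 6, seed = 1L),
    pta = list(n = 1000, seed = 1L, mic_grid = c(0.25, 0.5, 1, 2, 4)))
  cfg <- defaults
  merge_in <- function(cfg, upd) {
    for (nm in names(upd)) {
      cfg[[nm]] <- if (is.list(upd[[nm]]) && is.list(cfg[[nm]]))
        merge_in(cfg[[nm]], upd[[nm]]) else upd[[nm]]
    }
    cfg
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  cfg <- merge_in(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

.cfg_space <- function(cfg) {
  b <- cfg$fit$bounds
  nms <- if (cfg$fit$n_compartments == 2) c("CL", "Vc", "Q", "Vp") else c("CL", "Vc")
  parameter_space(nms, vapply(b[nms], `[`, 0, 1), vapply(b[nms], `[`, 0, 2))
}

.cfg_model <- function(cfg, covariates = covariate_model()) {
  e <- cfg$fit$error
  model_spec(cfg$fit$n_compartments, covariates,
             error_spec(e$c0, e$c1, e$c2, e$c3, e$gamma))
}

.cfg_control <- function(cfg) do.call(npag_control, cfg$fit$control)

# run manifest written next to every command's outputs
.write_manifest <- function(cfg, out_dir, command, seed) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- list(command = command, seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(utils::packageVersion("polybpk")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a synthetic cohort to disk
#'
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, paths of the cohort and truth CSVs
#' @export
cmd_simulate <- function(cfg = pipeline_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulate
  design <- cohort_design(n_subjects = sim$n_subjects,
                          n_obs_total = sim$n_obs_total,
                          sampling = sim$sampling, lloq = cfg$lloq)
  gen <- generate_cohort(design, seed = sim$seed)
  cohort_path <- file.path(out_dir, "cohort.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_cohort(gen$cohort, cohort_path)
  utils::write.csv(gen$truth, truth_path, row.names = FALSE)
  .write_manifest(cfg, out_dir, "simulate", sim$seed)
  invisible(c(cohort = cohort_path, truth = truth_path))
}

#' Fit the base population model
#'
#' @param cfg a [pipeline_config()]
#' @param cohort_csv event-record CSV (as produced by [cmd_simulate()])
#' @param out_dir output directory
#' @return invisibly, the [run_npag()] fit (also serialised to
#'   `fit.json` and per-observation predictions to `predictions.csv`)
#' @export
cmd_fit <- function(cfg = pipeline_config(), cohort_csv, out_dir = ".") {
  if (!file.exists(cohort_csv))
    stop("cmd_fit: cohort file not found (run cmd_simulate first): ",
         cohort_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_csv, lloq = cfg$lloq)
  fit <- run_npag(cohort, .cfg_model(cfg), .cfg_space(cfg), .cfg_control(cfg))
  met <- fit_metrics(fit, cohort)
  gof <- gof_table(fit, cohort)
  report <- list(
    support = list(points = apply(fit$support$points, 1, as.list),
                   weights = fit$support$weights),
    gamma = fit$gamma, neg2ll = fit$neg2ll, converged = fit$converged,
    metrics = list(aicc = unname(met$aicc), bic = unname(met$bic),
                   r2_pop = met$r2_pop, r2_post = met$r2_post),
    parameters = met$parameters, cycle_log = fit$cycle_log)
  jsonlite::write_json(report, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.csv(gof$records, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  .write_manifest(cfg, out_dir, "fit", cfg$fit$control$seed)
  invisible(fit)
}

#' Covariate screening and stepwise selection
#'
#' @param cfg a [pipeline_config()]
#' @param cohort a [pk_cohort()]
#' @param base_fit the [cmd_fit()] result
#' @param out_dir output directory
#' @return invisibly, the [stepwise_select()] result (comparison table
#'   written to `covariate_comparison.csv`, screening regressions to
#'   `covariate_screen.csv`)
#' @export
cmd_covariates <- function(cfg = pipeline_config(), cohort, base_fit,
                           out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  screen <- screen_covariates(posterior_table(base_fit, cohort), cohort)
  cands <- lapply(cfg$covariates$candidates, function(cd)
    covariate_effect(cd$target, cd$covariate, cd$reference, cd$exponent))
  sel <- stepwise_select(cohort, base_fit, cands)
  utils::write.csv(screen, file.path(out_dir, "covariate_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(sel$table, file.path(out_dir, "covariate_comparison.csv"),
                   row.names = FALSE)
  .write_manifest(cfg, out_dir, "covariates", cfg$fit$control$seed)
  invisible(sel)
}

#' Model validation: bootstrap, data splitting, VPC, goodness of fit
#'
#' @param cfg a [pipeline_config()]
#' @param cohort a [pk_cohort()]
#' @param final_fit the selected model's fit
#' @param out_dir output directory
#' @return invisibly, a list of the four output tables
#' @export
cmd_validate <- function(cfg = pipeline_config(), cohort, final_fit,
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- cfg$validate
  boot <- pk_bootstrap(cohort, final_fit$model, final_fit$space,
                       B = v$bootstrap_B, control = final_fit$control,
                       seed = v$seed)
  split <- split_validate(cohort, final_fit$model, final_fit$space,
                          fraction = v$split_fraction,
                          control = final_fit$control, seed = v$seed)
  vp <- vpc(final_fit, cohort, n_sim = v$vpc_n_sim, bins = v$vpc_bins,
            seed = v$seed)
  gof <- gof_table(final_fit, cohort)
  utils::write.csv(boot$summary, file.path(out_dir, "bootstrap.csv"),
                   row.names = FALSE)
  utils::write.csv(split, file.path(out_dir, "split_validation.csv"),
                   row.names = FALSE)
  utils::write.csv(vp$table, file.path(out_dir, "vpc.csv"), row.names = FALSE)
  utils::write.csv(gof$records, file.path(out_dir, "gof.csv"),
                   row.names = FALSE)
  .write_manifest(cfg, out_dir, "validate", v$seed)
  invisible(list(bootstrap = boot, split = split, vpc = vp, gof = gof))
}

#' Monte Carlo dosing simulation
#'
#' With `final_fit = NULL` the published parameter table is used
#' ([published_model()]), so this command needs no fit artifact.
#'
#' @param cfg a [pipeline_config()]
#' @param final_fit optional `npag_fit`
#' @param out_dir output directory
#' @return invisibly, the [dosing_report()] (PTA table written to
#'   `pta.csv`, recommendations to `recommendations.json`)
#' @export
cmd_pta <- function(cfg = pipeline_config(), final_fit = NULL,
                    out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (is.null(final_fit)) published_model() else final_fit
  rep <- dosing_report(model, n = cfg$pta$n, seed = cfg$pta$seed,
                       mic_grid = cfg$pta$mic_grid)
  utils::write.csv(rep$table, file.path(out_dir, "pta.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep$recommendations,
                       file.path(out_dir, "recommendations.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  .write_manifest(cfg, out_dir, "pta", cfg$pta$seed)
  invisible(rep)
}
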