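#' Subject record
#'
#' One patient: a dosing history, sparse concentration observations and a
#' covariate set, all on a time axis of hours since that subject's first
#' dose.
#'
#' @param id subject identifier (character)
#' @param doses data.frame from [dose_events()]
#' @param observations data.frame with columns `time` (h), `conc` (total
#'   polymyxin B, mg/L) and logical `blq` (below the lower limit of
#'   quantification)
#' @param covariates named list: `age` (years), `wt` (kg), `sex`
#'   ("male"/"female"), `scr` (serum creatinine, umol/L), `alb` (albumin,
#'   g/L), `apache2` (APACHE-II score); any may be `NA`
#' @return object of class `pk_subject`
#' @export
pk_subject <- function(id, doses, observations = NULL, covariates = list()) {
  if (is.null(observations))
    observations <- data.frame(time = numeric(0), conc = numeric(0),
                               blq = logical(0))
  if (is.null(observations$blq)) observations$blq <- FALSE
  observations <- observations[order(observations$time), , drop = FALSE]
  if (nrow(observations) > 0) {
    if (any(observations$time < 0))
      stop(sprintf("subject %s: negative observation time", id))
    if (any(observations$conc < 0, na.rm = TRUE))
      stop(sprintf("subject %s: negative concentration", id))
    if (nrow(doses) == 0 || min(observations$time) < min(doses$time))
      stop(sprintf("subject %s: first observation precedes first dose", id))
  }
  defaults <- list(age = NA_real_, wt = NA_real_, sex = NA_character_,
                   scr = NA_real_, alb = NA_real_, apache2 = NA_real_)
  covariates <- utils::modifyList(defaults, covariates[!vapply(covariates, is.null, TRUE)])
  num <- unlist(covariates[c("age", "wt", "scr", "alb", "apache2")])
  if (any(!is.na(num) & num <= 0))
    stop(sprintf("subject %s: covariates must be positive where present", id))
  structure(list(id = as.character(id), doses = doses,
                 observations = observations, covariates = covariates),
            class = "pk_subject")
}

#' Cohort of subjects
#'
#' @param subjects list of [pk_subject()] objects
#' @return object of class `pk_cohort`
#' @export
pk_cohort <- function(subjects) {
  ids <- vapply(subjects, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("pk_cohort: duplicate subject ids")
  structure(list(subjects = subjects), class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  cat(sprintf("pk_cohort: %d subjects, %d observations (%d BLQ)\n",
              length(x$subjects), n_obs(x),
              sum(vapply(x$subjects, function(s) sum(s$observations$blq), 0L))))
  invisible(x)
}

#' Total observation count of a cohort
#' @param cohort a [pk_cohort()]
#' @param blq include below-quantification observations? default TRUE
#' @return integer count
#' @export
n_obs <- function(cohort, blq = TRUE) {
  sum(vapply(cohort$subjects, function(s) {
    if (blq) nrow(s$observations) else sum(!s$observations$blq)
  }, numeric(1)))
}

.cohort_columns <- c("id", "time", "dose_amt", "dose_dur", "conc",
                     "age", "wt", "sex", "scr", "alb", "apache2")

#' Read a cohort from an event-record CSV
#'
#' The format is a NONMEM/Pmetrics-style event table: one row per dose or
#' observation, columns `id, time, dose_amt, dose_dur, conc, age, wt, sex,
#' scr, alb, apache2` (header required, UTF-8; empty cells mean "not
#' applicable").  Rows with `dose_amt > 0` become dosing events; rows with a
#' non-missing `conc` become observations.  Covariates are taken from the
#' first row of each subject on which they appear.
#'
#' @param path CSV file path
#' @param lloq lower limit of quantification for total polymyxin B, mg/L;
#'   observations below it are flagged `blq`
#' @return a [pk_cohort()]
#' @export
read_cohort <- function(path, lloq = 0.19) {
  if (!file.exists(path)) stop("read_cohort: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  required <- c("id", "time", "dose_amt", "dose_dur", "conc")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("read_cohort: missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in setdiff(.cohort_columns, names(df))) df[[col]] <- NA
  subjects <- lapply(split(df, factor(df$id, levels = unique(df$id))), function(d) {
    id <- d$id[1]
    if (any(d$time < 0))
      stop(sprintf("read_cohort: negative time for subject %s", id))
    if (is.unsorted(d$time))
      stop(sprintf("read_cohort: times not non-decreasing for subject %s", id))
    is_dose <- !is.na(d$dose_amt) & d$dose_amt > 0
    doses <- dose_events(d$time[is_dose], d$dose_amt[is_dose],
                         d$dose_dur[is_dose])
    is_obs <- !is.na(d$conc)
    obs <- data.frame(time = d$time[is_obs], conc = d$conc[is_obs],
                      blq = d$conc[is_obs] < lloq)
    first <- function(x) {
      x <- x[!is.na(x)]
      if (is.character(x)) x <- x[nzchar(x)]
      if (length(x)) x[1] else NA
    }
    cov <- list(age = first(d$age), wt = first(d$wt),
                sex = first(as.character(d$sex)), scr = first(d$scr),
                alb = first(d$alb), apache2 = first(d$apache2))
    pk_subject(id, doses, obs, cov)
  })
  pk_cohort(unname(subjects))
}

#' Write a cohort to an event-record CSV
#'
#' Inverse of [read_cohort()]: deterministic column order, floats at full
#' precision (15 significant digits), ids quoted so that delimiter
#' characters round-trip exactly.
#'
#' @param cohort a [pk_cohort()]
#' @param path output CSV path
#' @return invisibly, the path
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "pk_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    nd <- nrow(s$doses); no <- nrow(s$observations)
    d <- data.frame(
      id = rep(s$id, nd + no),
      time = c(s$doses$time, s$observations$time),
      dose_amt = c(s$doses$amount, rep(NA_real_, no)),
      dose_dur = c(s$doses$duration, rep(NA_real_, no)),
      conc = c(rep(NA_real_, nd), s$observations$conc),
      age = s$covariates$age, wt = s$covariates$wt,
      sex = s$covariates$sex, scr = s$covariates$scr,
      alb = s$covariates$alb, apache2 = s$covariates$apache2,
      stringsAsFactors = FALSE)
    d[order(d$time, is.na(d$dose_amt)), , drop = FALSE]
  })
  out <- do.call(rbind, rows)[, .cohort_columns]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) signif(x, 15))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = which(!num), na = "")
    TRUE
  }, error = function(e) stop("write_cohort: cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
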