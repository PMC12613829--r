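# Orchestration: a validated run configuration, the full analysis pipeline,
# and the sensitivity suite, with machine-readable outputs and provenance.

#' Configuration for a full mediation analysis run
#'
#' Exactly one input source must be given: a cohort CSV (`input`) or a
#' generator configuration (`generator`).
#'
#' @param input path to a cohort CSV (see [read_cohort()]).
#' @param generator a [cohort_config()]; the cohort is generated on the fly.
#' @param scheme dichotomization scheme, `"main"` or `"strict"`.
#' @param subset `"all"`, `"oa"`, or `"ra"`.
#' @param fu_class_column follow-up classification column (set to an
#'   alternative pre-computed column for the meal-preparation-excluded
#'   outcome variant).
#' @param ordering mediator ordering, `"ds_first"` (primary) or
#'   `"pa_first"`.
#' @param B bootstrap resamples.
#' @param seed integer seed for cohort generation (if any) and bootstrap.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param restandardize per-resample re-standardization flag (see
#'   [bootstrap_mediation()]).
#' @param log_offset depression log-transform offset.
#' @param digits_logor,digits_pct report rounding for log ORs and
#'   percentages (estimates in the returned object are never rounded).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL,
                       scheme = c("main", "strict"),
                       subset = c("all", "oa", "ra"),
                       fu_class_column = "adl_class_followup",
                       ordering = c("ds_first", "pa_first"),
                       B = 5000, seed = 1, outdir = NULL,
                       restandardize = FALSE, log_offset = 1,
                       digits_logor = 3, digits_pct = 1) {
  scheme <- match.arg(scheme)
  subset <- match.arg(subset)
  ordering <- match.arg(ordering)
  if (is.null(input) == is.null(generator))
    config_error("input/generator",
                 "exactly one input source must be supplied")
  if (!is.null(input) && (!is.character(input) || length(input) != 1L))
    config_error("input", "must be a single file path")
  if (!is.null(generator) && !inherits(generator, "cohort_config"))
    config_error("generator", "must be a 'cohort_config' object")
  if (!is.numeric(B) || length(B) != 1L || B < 1)
    config_error("B", "must be an integer >= 1")
  cfg <- list(input = input, generator = generator, scheme = scheme,
              subset = subset, fu_class_column = fu_class_column,
              ordering = ordering, B = as.integer(B),
              seed = as.integer(seed), outdir = outdir,
              restandardize = isTRUE(restandardize),
              log_offset = log_offset,
              digits_logor = digits_logor, digits_pct = digits_pct)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Reads the fields of [run_config()] from a YAML file; a `generator`
#' mapping is passed to [cohort_config()].
#'
#' @param path YAML file path.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) y$generator <- do.call(cohort_config,
                                                    y$generator)
  do.call(run_config, y)
}

run_stage <- function(stage, config_hash, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s, config %s] %s", stage, config_hash,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full serial mediation analysis
#'
#' Executes the pipeline: load or generate the cohort, build the analysis
#' frame (scoring, exclusions, standardization), estimate the seven paths,
#' decompose the indirect effect, and attach percentile-bootstrap intervals.
#' When `config$outdir` is set, writes `report.json`, `paths.csv` (the
#' path-coefficient table), `decomposition.csv`, and `run.log` (exclusion
#' counts, seed, config hash, package version).
#'
#' @param config a [run_config()] object.
#' @return an object of class `mediation_report`: list with `frame` summary
#'   info, `paths`, `decomposition`, `bootstrap`, `exclusions`,
#'   `config_hash`, `seed`, `version`, `timestamp`.
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "run_config"))
    stop("config must be a 'run_config' object", call. = FALSE)
  hash <- object_hash(config[setdiff(names(config), "outdir")])

  cohort <- run_stage("input", hash, {
    if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$generator, seed = config$seed)
  })
  frame <- run_stage("prepare", hash, build_analysis_frame(
    cohort, scheme = config$scheme, subset = config$subset,
    fu_class_column = config$fu_class_column,
    log_offset = config$log_offset))
  paths <- run_stage("estimate", hash, {
    if (config$ordering == "ds_first") estimate_paths(frame)
    else attr(alternate_ordering(frame), "paths")
  })
  dec <- run_stage("decompose", hash, {
    if (config$ordering == "ds_first") decompose_indirect(paths)
    else alternate_ordering(frame)
  })
  boot <- run_stage("bootstrap", hash, bootstrap_mediation(
    frame, B = config$B, seed = config$seed,
    restandardize = config$restandardize))

  report <- list(
    n = frame$n, scheme = config$scheme, subset = config$subset,
    fu_class_column = config$fu_class_column, ordering = config$ordering,
    exclusions = frame$exclusions, scaling = frame$scaling,
    paths = paths, decomposition = dec, bootstrap = boot,
    config_hash = hash, seed = config$seed,
    version = as.character(utils::packageVersion("serialmed")),
    timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "mediation_report"
  if (!is.null(config$outdir)) write_report(report, config)
  report
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("Serial mediation report (n = %d, scheme = %s, subset = %s)\n",
              x$n, x$scheme, x$subset))
  print(x$paths)
  print(x$decomposition)
  print(x$bootstrap)
  invisible(x)
}

report_json <- function(report) {
  list(
    n = report$n, scheme = report$scheme, subset = report$subset,
    fu_class_column = report$fu_class_column, ordering = report$ordering,
    exclusions = as.list(report$exclusions),
    paths = report$paths$paths,
    path_ci_type = "model-based (t for linear paths, Wald z for log-odds paths)",
    indirect = list(
      ind_ds = report$decomposition$ind_ds,
      ind_pa = report$decomposition$ind_pa,
      ind_serial = report$decomposition$ind_serial,
      total_indirect = report$decomposition$total_indirect,
      pct_mediated_total = report$decomposition$pct_mediated_total,
      pct_of_total = as.list(report$decomposition$pct_of_total),
      pct_of_indirect = as.list(report$decomposition$pct_of_indirect)),
    bootstrap = list(
      B = report$bootstrap$B, seed = report$bootstrap$seed,
      n_failed_and_redrawn = report$bootstrap$n_failed_and_redrawn,
      ci_type = "percentile",
      ci = report$bootstrap$ci),
    config_hash = report$config_hash, seed = report$seed,
    version = report$version, timestamp = report$timestamp)
}

write_report <- function(report, config) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$paths$paths, file.path(outdir, "paths.csv"),
                   row.names = FALSE)
  dec <- report$decomposition
  dec_tab <- merge(
    data.frame(quantity = c("ind_ds", "ind_pa", "ind_serial",
                            "total_indirect"),
               pct_of_total = c(unname(dec$pct_of_total),
                                sum(dec$pct_of_total)),
               pct_of_indirect = c(unname(dec$pct_of_indirect), 100)),
    report$bootstrap$ci, by = "quantity", sort = FALSE)
  utils::write.csv(dec_tab, file.path(outdir, "decomposition.csv"),
                   row.names = FALSE)
  writeLines(c(
    sprintf("serialmed %s", report$version),
    sprintf("timestamp: %s", report$timestamp),
    sprintf("config hash: %s", report$config_hash),
    sprintf("seed: %d", report$seed),
    sprintf("n analyzed: %d", report$n),
    sprintf("excluded (>=2 missing CESD items): %d",
            report$exclusions[["cesd_missing"]]),
    sprintf("excluded (listwise): %d", report$exclusions[["listwise"]]),
    sprintf("bootstrap resamples failed and redrawn: %d",
            report$bootstrap$n_failed_and_redrawn)),
    file.path(outdir, "run.log"))
  invisible(outdir)
}

#' Run the main analysis and its four sensitivity variants
#'
#' Runs the configured main analysis plus: the strict dichotomization
#' scheme; the alternative follow-up classification column (a stand-in for
#' the meal-preparation-excluded outcome, default
#' `adl_class_followup_alt`); the osteoarthritis subset; and the rheumatoid
#' subset.  Per-variant failures are recorded and the remaining variants
#' still run.
#'
#' @param config base [run_config()] (its `scheme`/`subset` define the main
#'   analysis).
#' @param alt_column name of the alternative classification column.
#' @return an object of class `sensitivity_suite`: list with `table` (one
#'   row per variant x pathway: estimate, percentile CI, significance flag),
#'   `reports` (per-variant `mediation_report`s), `errors` (per-variant
#'   error messages).
#' @export
run_sensitivity_suite <- function(config,
                                  alt_column = "adl_class_followup_alt") {
  if (!inherits(config, "run_config"))
    stop("config must be a 'run_config' object", call. = FALSE)
  base <- config
  base$outdir <- NULL
  variants <- list(
    main = base,
    strict_classification = utils::modifyList(base, list(scheme = "strict")),
    alt_outcome_column = utils::modifyList(base, list(
      fu_class_column = alt_column)),
    osteoarthritis = utils::modifyList(base, list(subset = "oa")),
    rheumatoid = utils::modifyList(base, list(subset = "ra")))
  variants <- lapply(variants, function(v) {
    class(v) <- "run_config"
    v
  })

  reports <- list()
  errors <- list()
  rows <- list()
  for (nm in names(variants)) {
    res <- tryCatch(run_analysis(variants[[nm]]), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      next
    }
    reports[[nm]] <- res
    ci <- res$bootstrap$ci
    ci <- ci[ci$quantity %in% c("ind_ds", "ind_pa", "ind_serial",
                                "total_indirect"), ]
    rows[[nm]] <- data.frame(variant = nm, n = res$n, ci, row.names = NULL)
  }
  out <- list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              reports = reports, errors = errors)
  class(out) <- "sensitivity_suite"
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$table,
                     file.path(config$outdir, "sensitivity.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.sensitivity_suite <- function(x, digits = 3, ...) {
  cat("Sensitivity suite (indirect pathways, percentile 95% CI)\n")
  tab <- x$table
  for (cl in c("estimate", "ci_lower", "ci_upper"))
    tab[[cl]] <- round(tab[[cl]], digits)
  print(tab, row.names = FALSE)
  if (length(x$errors)) {
    cat("Variants that failed:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm,
                                            x$errors[[nm]]))
  }
  invisible(x)
}
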