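# Serial two-mediator path estimation, log-OR indirect-effect decomposition,
# and percentile-bootstrap inference.

frame_data <- function(frame) {
  df <- if (inherits(frame, "analysis_frame")) frame$data else frame
  need <- c("pain", "ds_z", "pa_z", "age_z", "sex", "dep_base", "dep_fu")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("analysis frame lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyNA(df[need]))
    stop("analysis frame must be listwise complete", call. = FALSE)
  df
}

fit_labeled <- function(expr, path_label) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("estimation failed for %s: %s", path_label,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Estimate the seven paths of the serial mediation model
#'
#' Fits the four regressions of the two-mediator serial model of a binary
#' exposure (pain) on a binary outcome (follow-up functional dependence),
#' all adjusted for standardized age, sex, and baseline dependence:
#'
#' * total effect `c`: outcome ~ pain + covariates (logistic);
#' * `a1`: depression ~ pain + covariates (linear);
#' * `a2`, `a3`: activity ~ pain + depression + covariates (linear);
#' * `c'`, `b1`, `b2`: outcome ~ pain + depression + activity + covariates
#'   (logistic).
#'
#' Mediator paths are beta coefficients in SD units; outcome paths are log
#' odds ratios.  With `outcome_family = "gaussian"` the two outcome models
#' are fit by least squares instead, the closed-form limit in which total,
#' direct, and indirect effects are exactly additive.
#'
#' @param frame an [build_analysis_frame()] result, or a data frame with
#'   columns `pain`, `ds_z`, `pa_z`, `age_z`, `sex`, `dep_base`, `dep_fu`.
#' @param outcome_family `"binomial"` (default) or `"gaussian"`.
#' @return an object of class `path_estimates`: list with `paths` (a table
#'   of the seven path coefficients with SE, 95% CI, p, and source model),
#'   `fits` (the four underlying fit objects), `outcome_family`, `n`.
#' @export
estimate_paths <- function(frame, outcome_family = c("binomial",
                                                     "gaussian")) {
  outcome_family <- match.arg(outcome_family)
  df <- frame_data(frame)
  fit_outcome <- function(formula, label) {
    if (outcome_family == "binomial")
      fit_labeled(fit_logistic(formula, df), label)
    else fit_labeled(fit_linear(formula, df), label)
  }
  f_c <- fit_outcome(dep_fu ~ pain + age_z + sex + dep_base,
                     "path c (total-effect model)")
  f_a1 <- fit_labeled(fit_linear(ds_z ~ pain + age_z + sex + dep_base, df),
                      "path a1 (depression model)")
  f_a23 <- fit_labeled(
    fit_linear(pa_z ~ pain + ds_z + age_z + sex + dep_base, df),
    "paths a2/a3 (activity model)")
  f_full <- fit_outcome(dep_fu ~ pain + ds_z + pa_z + age_z + sex + dep_base,
                        "paths b1/b2/c' (full outcome model)")

  pick <- function(fit, term, path, model) {
    row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
    data.frame(path = path, term = term, estimate = row$estimate,
               se = row$se, ci_lower = row$ci_lower,
               ci_upper = row$ci_upper, p_value = row$p_value,
               model = model, row.names = NULL)
  }
  paths <- rbind(
    pick(f_a1, "pain", "a1", "depression"),
    pick(f_a23, "pain", "a2", "activity"),
    pick(f_a23, "ds_z", "a3", "activity"),
    pick(f_full, "ds_z", "b1", "outcome_full"),
    pick(f_full, "pa_z", "b2", "outcome_full"),
    pick(f_c, "pain", "c", "outcome_total"),
    pick(f_full, "pain", "c_prime", "outcome_full"))
  out <- list(paths = paths,
              fits = list(total = f_c, depression = f_a1, activity = f_a23,
                          full = f_full),
              outcome_family = outcome_family, n = nrow(df))
  class(out) <- "path_estimates"
  out
}

#' @export
print.path_estimates <- function(x, digits = 3, ...) {
  cat(sprintf("Serial mediation path estimates (n = %d, outcome: %s)\n",
              x$n, x$outcome_family))
  tab <- x$paths[, c("path", "estimate", "ci_lower", "ci_upper", "p_value")]
  tab$estimate <- round(tab$estimate, digits)
  tab$ci_lower <- round(tab$ci_lower, digits)
  tab$ci_upper <- round(tab$ci_upper, digits)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  if (x$outcome_family == "binomial")
    cat(sprintf(
      "McFadden R2: total-effect model %.3f, full model %.3f\n",
      x$fits$total$mcfadden_r2, x$fits$full$mcfadden_r2))
  invisible(x)
}

path_vector <- function(x) {
  if (inherits(x, "path_estimates")) {
    stats::setNames(x$paths$estimate, x$paths$path)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else if (is.list(x)) {
    unlist(x)
  } else {
    stop("supply a path_estimates object or a named vector of coefficients",
         call. = FALSE)
  }
}

#' Decompose the indirect effect on the log odds ratio scale
#'
#' Product-of-coefficients decomposition of the indirect effect of the
#' exposure into the three pathways of the serial model, each a log odds
#' ratio:
#' `ind_ds = a1 * b1` (through depressive symptoms),
#' `ind_pa = a2 * b2` (through physical activity),
#' `ind_serial = a1 * a3 * b2` (through both, in series), and their sum
#' `total_indirect`.  Percentage-mediated summaries use the total and direct
#' effects: `pct_mediated_total = 100 (c - c') / c`, each pathway's share of
#' the total effect (`100 pathway / c`) and of the indirect effect
#' (`100 pathway / total_indirect`).  Shares are `NA` when their denominator
#' is zero or unavailable.  On the log-odds scale the pathway products need
#' not sum to `c - c'` (non-collapsibility); the identity
#' `total_indirect = ind_ds + ind_pa + ind_serial` holds exactly by
#' construction.
#'
#' @param paths a [estimate_paths()] result, or a named numeric vector /
#'   list with elements `a1`, `a2`, `a3`, `b1`, `b2`, `c`, `c_prime`.
#' @return an object of class `indirect_decomposition`: list with the three
#'   pathway effects, `total_indirect`, `pct_mediated_total`,
#'   `pct_of_total`, `pct_of_indirect`, and the input coefficients.
#' @export
#' @examples
#' # worked example from printed path coefficients
#' dec <- decompose_indirect(c(a1 = 0.356, a2 = -0.083, a3 = -0.030,
#'                             b1 = 0.358, b2 = -0.598,
#'                             c = 0.791, c_prime = 0.607))
#' print(dec)
decompose_indirect <- function(paths) {
  cf <- path_vector(paths)
  need <- c("a1", "a2", "a3", "b1", "b2", "c", "c_prime")
  missing_cf <- setdiff(need, names(cf))
  if (length(missing_cf))
    stop("missing path coefficients: ", paste(missing_cf, collapse = ", "),
         call. = FALSE)
  cf <- cf[need]
  ind_ds <- cf[["a1"]] * cf[["b1"]]
  ind_pa <- cf[["a2"]] * cf[["b2"]]
  ind_serial <- cf[["a1"]] * cf[["a3"]] * cf[["b2"]]
  total <- ind_ds + ind_pa + ind_serial
  cc <- cf[["c"]]
  pct_total_ok <- is.finite(cc) && cc != 0
  pct_ind_ok <- is.finite(total) && total != 0
  pw <- c(ds = ind_ds, pa = ind_pa, serial = ind_serial)
  out <- list(
    ind_ds = ind_ds, ind_pa = ind_pa, ind_serial = ind_serial,
    total_indirect = total,
    pct_mediated_total = if (pct_total_ok)
      100 * (cc - cf[["c_prime"]]) / cc else NA_real_,
    pct_of_total = if (pct_total_ok) 100 * pw / cc else
      stats::setNames(rep(NA_real_, 3), names(pw)),
    pct_of_indirect = if (pct_ind_ok) 100 * pw / total else
      stats::setNames(rep(NA_real_, 3), names(pw)),
    coefficients = cf)
  class(out) <- "indirect_decomposition"
  out
}

#' @export
print.indirect_decomposition <- function(x, ...) {
  ord <- attr(x, "ordering")
  cat("Indirect effect decomposition (log OR scale",
      if (!is.null(ord) && ord == "pa_first")
        ", activity-first ordering" else "", ")\n", sep = "")
  cat(sprintf("  through depressive symptoms (a1*b1):      %7.3f\n",
              x$ind_ds))
  cat(sprintf("  through physical activity (a2*b2):        %7.3f\n",
              x$ind_pa))
  cat(sprintf("  serial, both mediators (a1*a3*b2):        %7.3f\n",
              x$ind_serial))
  cat(sprintf("  total indirect effect:                    %7.3f\n",
              x$total_indirect))
  if (is.finite(x$pct_mediated_total))
    cat(sprintf("  percentage mediated, 100*(c - c')/c:      %6.1f%%\n",
                x$pct_mediated_total))
  if (all(is.finite(x$pct_of_total)))
    cat(sprintf(
      "  share of total effect: ds %.1f%%, pa %.1f%%, serial %.1f%%\n",
      x$pct_of_total[["ds"]], x$pct_of_total[["pa"]],
      x$pct_of_total[["serial"]]))
  if (all(is.finite(x$pct_of_indirect)))
    cat(sprintf(
      "  share of indirect effect: ds %.1f%%, pa %.1f%%, serial %.1f%%\n",
      x$pct_of_indirect[["ds"]], x$pct_of_indirect[["pa"]],
      x$pct_of_indirect[["serial"]]))
  invisible(x)
}

boot_quantities <- c("a1", "a2", "a3", "b1", "b2", "c", "c_prime",
                     "ind_ds", "ind_pa", "ind_serial", "total_indirect")

frame_design <- function(df) {
  cbind(intercept = 1, pain = df$pain, ds_z = df$ds_z, pa_z = df$pa_z,
        age_z = df$age_z, sex = df$sex, dep_base = df$dep_base)
}

#' Percentile-bootstrap inference for the mediation quantities
#'
#' Resamples rows of the prepared analysis frame with replacement (`n` rows
#' per resample), re-estimates all four path models and the indirect-effect
#' decomposition on each resample, and returns percentile 95% confidence
#' intervals for every path and indirect quantity.  A quantity is flagged
#' significant when its interval excludes zero.  Standardization constants
#' are frozen at their full-sample values unless `restandardize = TRUE`, in
#' which case the three standardized columns are re-scaled within each
#' resample.
#'
#' Resamples on which estimation fails (single-class outcome, separation,
#' singular system) are redrawn with the next draws of the seeded stream and
#' counted, so the number of retained resamples always equals `B`; more
#' than `50 * B` total draws aborts with a pipeline error.
#'
#' @param frame analysis frame (see [estimate_paths()]).
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed; the resampling stream is fully reproducible.
#' @param outcome_family `"binomial"` or `"gaussian"`.
#' @param restandardize re-standardize mediators and age within each
#'   resample.
#' @param conf_level confidence level of the percentile intervals.
#' @param newton_tol stopping tolerance (maximum coefficient change) of the
#'   warm-started Newton refits inside the loop.  Each refit starts at the
#'   full-sample solution, so the default leaves resampled coefficients
#'   within about `1e-4` of their optimum -- orders of magnitude below
#'   resampling noise at any realistic sample size; tighten it if you need
#'   resampled coefficients to machine precision.
#' @return an object of class `mediation_boot`: list with `point` (full-
#'   sample estimates), `ci` (quantity/lower/upper/significant table),
#'   `draws` (a `B x 11` matrix), `B`, `seed`,
#'   `n_resamples_requested`, `n_failed_and_redrawn`.
#' @export
bootstrap_mediation <- function(frame, B = 5000, seed = 1,
                                outcome_family = c("binomial", "gaussian"),
                                restandardize = FALSE, conf_level = 0.95,
                                newton_tol = 0.02) {
  outcome_family <- match.arg(outcome_family)
  if (!is.numeric(B) || length(B) != 1L || B < 2)
    stop("B must be an integer >= 2", call. = FALSE)
  B <- as.integer(B)
  df <- frame_data(frame)

  Z <- frame_design(df)
  fam <- if (outcome_family == "binomial") 0L else 1L
  if (fam == 0L) {
    if (!all(df$dep_fu %in% c(0, 1)))
      stop("outcome must be coded 0/1", call. = FALSE)
    if (length(unique(df$dep_fu)) < 2L)
      stop("outcome has a single class; cannot bootstrap", call. = FALSE)
    fc <- logistic_fit_cpp(Z[, c(1L, 2L, 5L, 6L, 7L), drop = FALSE],
                           df$dep_fu, rep(0, 5))
    ff <- logistic_fit_cpp(Z, df$dep_fu, rep(0, 7))
    if (!isTRUE(fc$ok) || !isTRUE(ff$ok))
      stop("full-sample outcome model failed to converge (separation or singular design)",
           call. = FALSE)
    start_c <- drop(fc$beta)
    start_full <- drop(ff$beta)
  } else {
    start_c <- rep(0, 5)
    start_full <- rep(0, ncol(Z))
  }
  # full-sample point estimates through the same kernel the resamples use
  # (equal to the lm/glm route to numerical precision; see the test suite)
  pt <- fit_paths_cpp(Z, df$dep_fu, fam, start_c, start_full, tol = 1e-10)
  if (!isTRUE(pt$ok))
    stop("full-sample path estimation failed (singular design?)",
         call. = FALSE)
  dec <- decompose_indirect(pt$paths)
  point <- c(pt$paths,
             ind_ds = dec$ind_ds, ind_pa = dec$ind_pa,
             ind_serial = dec$ind_serial,
             total_indirect = dec$total_indirect)[boot_quantities]

  set.seed(as.integer(seed))
  res <- boot_paths_cpp(Z, df$dep_fu, B, fam, max_draws = 50L * B,
                        start_c = start_c, start_full = start_full,
                        restandardize = restandardize, tol = newton_tol)
  if (!isTRUE(res$ok))
    stop(sprintf(
      "bootstrap aborted: %d of %d resamples failed estimation (cap of %d total draws exceeded)",
      res$n_failed, res$n_failed + res$completed, 50L * B), call. = FALSE)
  draws <- res$draws
  colnames(draws) <- boot_quantities

  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  qs <- apply(draws, 2, stats::quantile, probs = probs, names = FALSE)
  ci <- data.frame(quantity = boot_quantities,
                   estimate = unname(point),
                   ci_lower = qs[1, ], ci_upper = qs[2, ],
                   significant = qs[1, ] > 0 | qs[2, ] < 0,
                   row.names = NULL)
  out <- list(point = point, ci = ci, draws = draws, B = B,
              seed = as.integer(seed), conf_level = conf_level,
              outcome_family = outcome_family,
              restandardize = restandardize,
              n_resamples_requested = B,
              n_failed_and_redrawn = res$n_failed)
  class(out) <- "mediation_boot"
  out
}

#' @export
print.mediation_boot <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Percentile bootstrap (B = %d, seed = %d, %d failed resamples redrawn)\n",
    x$B, x$seed, x$n_failed_and_redrawn))
  tab <- x$ci
  for (cl in c("estimate", "ci_lower", "ci_upper"))
    tab[[cl]] <- round(tab[[cl]], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Decomposition under the swapped mediator ordering
#'
#' Re-estimates the serial model with physical activity as the first
#' mediator and depressive symptoms as the second (activity regressed on
#' pain; depression regressed on pain and activity), and decomposes the
#' indirect effect accordingly.  The outcome model is unchanged, so the
#' total indirect effect agrees exactly with the primary ordering (an
#' in-sample algebraic identity); only its split between the single-mediator
#' and serial pathways depends on the assumed ordering.
#'
#' @inheritParams estimate_paths
#' @return an `indirect_decomposition` whose `ind_ds` / `ind_pa` /
#'   `ind_serial` components refer to the depression pathway, the activity
#'   pathway, and the serial pain -> activity -> depression pathway, with
#'   attribute `ordering = "pa_first"` and the swapped `path_estimates`
#'   attached as attribute `paths`.
#' @export
alternate_ordering <- function(frame, outcome_family = c("binomial",
                                                         "gaussian")) {
  outcome_family <- match.arg(outcome_family)
  df <- frame_data(frame)
  swapped <- df
  swapped$ds_z <- df$pa_z
  swapped$pa_z <- df$ds_z
  paths <- estimate_paths(swapped, outcome_family = outcome_family)
  dec_sw <- decompose_indirect(paths)
  out <- dec_sw
  # in the swapped frame the "ds" slot is the activity-first pathway
  out$ind_pa <- dec_sw$ind_ds
  out$ind_ds <- dec_sw$ind_pa
  out$pct_of_total <- dec_sw$pct_of_total[c(pa = "ds", ds = "pa",
                                            serial = "serial")]
  names(out$pct_of_total) <- c("pa", "ds", "serial")
  out$pct_of_indirect <- dec_sw$pct_of_indirect[c("ds", "pa", "serial")]
  names(out$pct_of_indirect) <- c("pa", "ds", "serial")
  attr(out, "ordering") <- "pa_first"
  attr(out, "paths") <- paths
  out
}
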