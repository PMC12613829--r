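# Instrument scoring and derivation of the model-ready analysis frame.

#' Score the CESD-10 depression scale with single-item imputation
#'
#' Sums the 10 item responses (each 0-3).  A single missing item is imputed
#' with the mean of the nine observed items before summing (so the result can
#' be non-integer and is not rounded); two or more missing items yield `NA`,
#' the exclusion signal consumed by [build_analysis_frame()].
#'
#' @param items either a length-10 vector of item responses, or an `n x 10`
#'   matrix / data.frame of responses (one row per participant).  Present
#'   responses must lie in `{0, 1, 2, 3}`; missing responses are `NA`.
#' @return a numeric score in `[0, 30]` per participant, `NA` where more
#'   than one item is missing.
#' @export
#' @examples
#' score_cesd(rep(1, 10))              # 10
#' score_cesd(c(rep(1, 9), NA))        # 9 + mean of the nine = 10
#' score_cesd(c(rep(3, 8), NA, NA))    # NA: excluded
score_cesd <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) {
    if (length(items) != 10L)
      stop("CESD-10 requires exactly 10 item responses", call. = FALSE)
    items <- matrix(as.numeric(items), nrow = 1L)
  }
  if (ncol(items) != 10L)
    stop("CESD-10 requires exactly 10 item responses per row", call. = FALSE)
  storage.mode(items) <- "numeric"
  bad <- !is.na(items) & !(items %in% 0:3)
  if (any(bad))
    stop("CESD-10 item responses must be in {0, 1, 2, 3} or missing",
         call. = FALSE)
  n_miss <- rowSums(is.na(items))
  s <- rowSums(items, na.rm = TRUE)
  score <- ifelse(n_miss == 0L, s,
                  ifelse(n_miss == 1L, s * 10 / 9, NA_real_))
  as.numeric(score)
}

#' Log-transform a depression score
#'
#' The CESD-10 sum score is strongly right-skewed and includes zeros, so the
#' analysis uses `log(score + offset)`.  The offset defaults to 1 (defined at
#' zero, order preserving); it is exposed because downstream standardization
#' absorbs any monotone rescaling but not the choice of offset itself.
#'
#' @param score numeric score(s), `>= 0` (`NA` passed through).
#' @param offset positive offset added before taking the log.
#' @return `log(score + offset)`.
#' @export
log_cesd <- function(score, offset = 1) {
  offset <- check_positive(offset, "offset")
  if (any(score < 0, na.rm = TRUE))
    stop("depression scores must be non-negative", call. = FALSE)
  log(score + offset)
}

#' Default PASE-style activity weight table
#'
#' A versioned weight table for the simplified physical-activity composite
#' implemented by [score_pase()].  Five activity categories (walking, light,
#' moderate, strenuous, exercise) each contribute
#' `weight * frequency factor * duration factor`; the weights are chosen so
#' that the maximum attainable score is exactly 485, the documented upper end
#' of the PASE composite.
#'
#' @return a named numeric vector of per-activity weights with attributes
#'   `version`, `freq_factor` (for frequency codes 1-4: never ... often) and
#'   `dur_factor` (for duration codes 1-5: <30 min ... 4 h or more).
#' @export
pase_weights <- function() {
  w <- c(walking = 100, light = 80, moderate = 100, strenuous = 120,
         exercise = 85)
  attr(w, "version") <- "serialmed-1"
  attr(w, "freq_factor") <- c(0, 0.25, 0.5, 1)
  attr(w, "dur_factor") <- c(0.2, 0.4, 0.6, 0.8, 1)
  w
}

#' Score a PASE-style physical-activity composite
#'
#' Computes a weighted activity composite from frequency (1 = never to
#' 4 = often, 5-7 days) and duration (1 = under 30 minutes to 5 = 4 hours or
#' more) responses for five activity categories, clipped to the documented
#' `[0, 485]` range.  The exact published scoring scheme lives in an
#' instrument manual; this implementation is a configurable weighted sum
#' whose default table ([pase_weights()]) reaches the same range, and any
#' weight table with the same shape can be supplied.
#'
#' @param freq `n x 5` matrix/data.frame (or length-5 vector) of frequency
#'   codes in 1-4.
#' @param dur `n x 5` matrix/data.frame (or length-5 vector) of duration
#'   codes in 1-5.
#' @param weights weight table as returned by [pase_weights()].
#' @return numeric score(s) in `[0, 485]`.
#' @export
score_pase <- function(freq, dur, weights = pase_weights()) {
  as_mat <- function(x, k) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
    if (ncol(x) != k)
      stop(sprintf("expected %d activity columns", k), call. = FALSE)
    storage.mode(x) <- "numeric"
    x
  }
  k <- length(weights)
  freq <- as_mat(freq, k)
  dur <- as_mat(dur, k)
  if (nrow(freq) != nrow(dur))
    stop("frequency and duration tables must have the same rows",
         call. = FALSE)
  ff <- attr(weights, "freq_factor")
  df_ <- attr(weights, "dur_factor")
  if (any(!(freq %in% seq_along(ff))))
    stop(sprintf("frequency responses must be integers in 1-%d",
                 length(ff)), call. = FALSE)
  if (any(!(dur %in% seq_along(df_))))
    stop(sprintf("duration responses must be integers in 1-%d",
                 length(df_)), call. = FALSE)
  contrib <- matrix(ff[freq], nrow(freq)) * matrix(df_[dur], nrow(dur))
  score <- as.numeric(contrib %*% as.numeric(weights))
  pmin(485, pmax(0, score))
}

#' Dichotomize the 1-5 functional-limitation classification
#'
#' The main scheme classifies no or mild limitations (classes 1-2) as
#' functionally independent (0) and moderate, severe, or total limitations
#' (classes 3-5) as dependent (1).  The `strict` sensitivity scheme counts
#' only class 1 as independent.
#'
#' @param adl_class integer class(es) in 1-5 (`NA` passed through).
#' @param scheme `"main"` or `"strict"`.
#' @return binary 0/1 per class.
#' @export
dichotomize_dependence <- function(adl_class, scheme = c("main", "strict")) {
  scheme <- match.arg(scheme)
  ok <- is.na(adl_class) | adl_class %in% 1:5
  if (!all(ok))
    stop("functional-limitation classes must be integers in 1-5",
         call. = FALSE)
  cut <- if (scheme == "main") 3L else 2L
  as.numeric(adl_class >= cut)
}

#' Build the model-ready analysis frame
#'
#' Applies, in order: the arthritis-subtype filter; CESD-10 scoring with
#' single-item imputation (rows with two or more missing items are excluded
#' and counted); the depression log transform; the activity composite (the
#' `pase_score` column if present, otherwise [score_pase()] on
#' `pase_freq_1..5` / `pase_dur_1..5` columns); both dichotomizations of the
#' baseline and follow-up classifications; listwise deletion of any
#' remaining incomplete rows (counted); and standardization of depression,
#' activity, and age on the included analysis sample.
#'
#' The returned scaling constants allow the "1 SD" unit to be held fixed
#' across bootstrap resamples.
#'
#' @param cohort a cohort `data.frame` (see [generate_cohort()] for the
#'   column dictionary).
#' @param scheme dichotomization scheme, `"main"` or `"strict"`.
#' @param subset `"all"`, `"oa"` (osteoarthritis flag), or `"ra"`
#'   (rheumatoid flag); subsets are non-exclusive filters.
#' @param fu_class_column name of the follow-up classification column;
#'   point it at an alternative pre-computed classification (e.g. one
#'   re-derived without meal preparation) to run that sensitivity variant.
#' @param log_offset offset of the depression log transform.
#' @param weights activity weight table, used only when scoring from
#'   components.
#' @return an object of class `analysis_frame`: a list with `data` (columns
#'   `pain`, `ds_z`, `pa_z`, `age_z`, `sex`, `dep_base`, `dep_fu`),
#'   `scaling` (per-variable center/scale/n_used), `exclusions` (named
#'   counts), and the options used.
#' @export
build_analysis_frame <- function(cohort,
                                 scheme = c("main", "strict"),
                                 subset = c("all", "oa", "ra"),
                                 fu_class_column = "adl_class_followup",
                                 log_offset = 1,
                                 weights = pase_weights()) {
  scheme <- match.arg(scheme)
  subset <- match.arg(subset)
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  if (!fu_class_column %in% names(cohort))
    stop(sprintf("cohort has no column '%s'", fu_class_column),
         call. = FALSE)

  keep <- switch(subset,
                 all = rep(TRUE, nrow(cohort)),
                 oa = cohort$oa == 1,
                 ra = cohort$ra == 1)
  keep[is.na(keep)] <- FALSE
  ch <- cohort[keep, , drop = FALSE]
  if (nrow(ch) == 0L)
    stop(sprintf("no participants left after subset filter '%s'", subset),
         call. = FALSE)

  score <- score_cesd(ch[, paste0("cesd_", 1:10)])
  excl_cesd <- sum(is.na(score))

  if ("pase_score" %in% names(ch)) {
    pase <- ch$pase_score
  } else if (all(paste0("pase_freq_", 1:5) %in% names(ch)) &&
             all(paste0("pase_dur_", 1:5) %in% names(ch))) {
    pase <- score_pase(ch[, paste0("pase_freq_", 1:5)],
                       ch[, paste0("pase_dur_", 1:5)], weights)
  } else {
    stop("cohort has neither 'pase_score' nor activity component columns",
         call. = FALSE)
  }

  dep_base <- dichotomize_dependence(ch$adl_class_baseline, scheme)
  dep_fu <- dichotomize_dependence(ch[[fu_class_column]], scheme)

  df <- data.frame(pain = ch$pain, cesd_score = score, pase = pase,
                   age = ch$age_years, sex = ch$sex,
                   dep_base = dep_base, dep_fu = dep_fu)
  complete <- stats::complete.cases(df) & !is.na(score)
  excl_listwise <- sum(!complete) - excl_cesd
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no complete participants left after exclusions", call. = FALSE)

  ds <- log_cesd(df$cesd_score, offset = log_offset)
  zd <- standardize(ds)
  zp <- standardize(df$pase)
  za <- standardize(df$age)

  out <- list(
    data = data.frame(pain = df$pain, ds_z = zd$z, pa_z = zp$z,
                      age_z = za$z, sex = df$sex, dep_base = df$dep_base,
                      dep_fu = df$dep_fu),
    scaling = list(
      ds = list(center = zd$center, scale = zd$scale, n_used = nrow(df)),
      pa = list(center = zp$center, scale = zp$scale, n_used = nrow(df)),
      age = list(center = za$center, scale = za$scale, n_used = nrow(df))),
    exclusions = c(cesd_missing = excl_cesd, listwise = excl_listwise),
    scheme = scheme, subset = subset, fu_class_column = fu_class_column,
    log_offset = log_offset, n = nrow(df))
  class(out) <- "analysis_frame"
  out
}

#' @export
print.analysis_frame <- function(x, ...) {
  cat(sprintf(
    "Analysis frame: n = %d (scheme = %s, subset = %s)\n", x$n, x$scheme,
    x$subset))
  cat(sprintf("  excluded: %d (>=2 missing CESD items), %d (listwise)\n",
              x$exclusions[["cesd_missing"]], x$exclusions[["listwise"]]))
  cat(sprintf("  outcome prevalence: %.2f%%; pain prevalence: %.2f%%\n",
              100 * mean(x$data$dep_fu), 100 * mean(x$data$pain)))
  invisible(x)
}

#' Write an analysis frame and its scaling sidecar
#'
#' Writes the model-ready columns as CSV and the scaling constants plus
#' exclusion counts as a JSON sidecar (`<path>.json`).
#'
#' @param frame an `analysis_frame`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_frame <- function(frame, path) {
  stopifnot(inherits(frame, "analysis_frame"))
  utils::write.csv(frame$data, path, row.names = FALSE)
  side <- list(scaling = frame$scaling,
               exclusions = as.list(frame$exclusions),
               scheme = frame$scheme, subset = frame$subset,
               fu_class_column = frame$fu_class_column,
               log_offset = frame$log_offset, n = frame$n)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
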