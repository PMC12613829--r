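#' Configuration for the synthetic arthritis cohort generator
#'
#' Builds and validates the full parameter set of the synthetic-cohort
#' generator. The defaults reproduce the study conditions of a large
#' community-dwelling arthritis cohort: ~53% usual pain, right-skewed CESD-10
#' depression scores (mean 5.5, SD 4.6 on the 0-30 scale), PASE activity
#' scores around 185 (SD 75.8) on the 0-485 scale, rare functional dependence
#' at baseline (<1% moderate or worse), ~59% female, ages 45-85, and a
#' logistic structural model for follow-up dependence.
#'
#' Structural coefficients are expressed on the scales the estimator reports:
#' `alpha1` is the pain effect on the latent depression scale (unit residual
#' SD), `alpha2`/`alpha3` the pain and depression effects on the latent
#' activity scale (unit residual SD), and `beta1`, `beta2`, `gamma_*`,
#' `intercept_outcome` are log-odds effects in the outcome model, applied to
#' the standardized mediators actually derived from the generated instrument
#' scores. Use [cohort_truth()] to obtain the implied recoverable path values.
#'
#' @param n_participants number of participants (>= 1).
#' @param seed integer RNG seed; identical (config, seed) pairs reproduce
#'   byte-identical cohorts.
#' @param p_pain probability of usual pain or discomfort at baseline.
#' @param alpha1 pain -> depression latent shift (residual-SD units).
#' @param alpha2,alpha3 pain -> activity and depression -> activity latent
#'   shifts (residual-SD units).
#' @param beta1,beta2 log-odds effects of standardized depression and
#'   activity on follow-up dependence.
#' @param gamma_direct direct log-odds effect of pain on follow-up dependence.
#' @param gamma_age,gamma_sex,gamma_base log-odds effects of standardized
#'   age, male sex, and baseline dependence.
#' @param intercept_outcome log-odds intercept of the outcome model.
#' @param depression_mean,depression_sd target marginal mean/SD of the
#'   CESD-10 sum score (0-30 scale).
#' @param activity_mean,activity_sd target marginal mean/SD of the PASE
#'   composite (0-485 scale).
#' @param p_female probability of female sex (sex is coded 0 = female,
#'   1 = male).
#' @param age_range numeric length-2, min < max, in years; age is drawn
#'   uniformly on this range.
#' @param p_base_dependent probability of moderate-or-worse functional
#'   limitation (classes 3-5) at baseline.
#' @param p_oa,p_ra,p_other arthritis-subtype flag prevalences
#'   (non-exclusive; rows with no flag are assigned `other_arthritis = 1`).
#' @param p_item_missing probability that a participant has exactly one
#'   missing CESD-10 item (the generator never produces two or more).
#' @param log_offset offset used in `log(score + offset)` when the generator
#'   builds the depression scale its outcome model acts on; must match the
#'   offset used at analysis time.
#'
#' @return an object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()], [cohort_truth()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 500, seed = 42)
#' cohort <- generate_cohort(cfg)
#' head(cohort)
cohort_config <- function(n_participants = 6972,
                          seed = 1L,
                          p_pain = 0.528,
                          alpha1 = 0.356,
                          alpha2 = -0.083,
                          alpha3 = -0.030,
                          beta1 = 0.358,
                          beta2 = -0.598,
                          gamma_direct = 0.607,
                          gamma_age = 0.640,
                          gamma_sex = -0.009,
                          gamma_base = 2.886,
                          intercept_outcome = -4.684,
                          depression_mean = 5.5,
                          depression_sd = 4.6,
                          activity_mean = 185.0,
                          activity_sd = 75.8,
                          p_female = 0.587,
                          age_range = c(45, 85),
                          p_base_dependent = 0.0073,
                          p_oa = 0.707,
                          p_ra = 0.0995,
                          p_other = 0.30,
                          p_item_missing = 0.02,
                          log_offset = 1) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      is.na(n_participants) || n_participants < 1 ||
      n_participants != floor(n_participants))
    config_error("n_participants", "must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed))
    config_error("seed", "must be an integer")
  for (f in c("p_pain", "p_female", "p_base_dependent", "p_oa", "p_ra",
              "p_other", "p_item_missing")) {
    assign(f, check_prob(get(f), f))
  }
  for (f in c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "gamma_direct",
              "gamma_age", "gamma_sex", "gamma_base", "intercept_outcome",
              "depression_mean", "activity_mean")) {
    assign(f, check_number(get(f), f))
  }
  for (f in c("depression_sd", "activity_sd", "log_offset")) {
    assign(f, check_positive(get(f), f))
  }
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      any(!is.finite(age_range)) || age_range[1] >= age_range[2])
    config_error("age_range", "must be c(min, max) with min < max")
  if (depression_mean < 0 || depression_mean > 30)
    config_error("depression_mean", "must lie in [0, 30]")
  if (activity_mean < 0 || activity_mean > 485)
    config_error("activity_mean", "must lie in [0, 485]")

  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    p_pain = p_pain, alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
    beta1 = beta1, beta2 = beta2, gamma_direct = gamma_direct,
    gamma_age = gamma_age, gamma_sex = gamma_sex, gamma_base = gamma_base,
    intercept_outcome = intercept_outcome,
    depression_mean = depression_mean, depression_sd = depression_sd,
    activity_mean = activity_mean, activity_sd = activity_sd,
    p_female = p_female, age_range = as.numeric(age_range),
    p_base_dependent = p_base_dependent,
    p_oa = p_oa, p_ra = p_ra, p_other = p_other,
    p_item_missing = p_item_missing, log_offset = log_offset)
  class(cfg) <- "cohort_config"
  cfg
}

#' Write / read a generator configuration as YAML
#'
#' @param config a [cohort_config()] object.
#' @param path YAML file path.
#' @return `read_cohort_config` returns a validated `cohort_config`;
#'   `write_cohort_config` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a 'cohort_config' object", call. = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d, P(pain) = %.3f\n",
              x$n_participants, x$seed, x$p_pain))
  cat(sprintf("  mediator paths: alpha1 = %.3f, alpha2 = %.3f, alpha3 = %.3f\n",
              x$alpha1, x$alpha2, x$alpha3))
  cat(sprintf("  outcome model (log odds): pain %.3f, depression %.3f, activity %.3f, intercept %.3f\n",
              x$gamma_direct, x$beta1, x$beta2, x$intercept_outcome))
  cat(sprintf("  depression score %.1f (%.1f) on 0-30; activity %.1f (%.1f) on 0-485\n",
              x$depression_mean, x$depression_sd, x$activity_mean,
              x$activity_sd))
  invisible(x)
}
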