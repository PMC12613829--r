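# Shared fixtures, built in code.

# configuration with no structural effects (outcome depends on nothing but
# its intercept unless covariate effects are switched back on)
null_config <- function(n, seed = 1L, intercept = -3, ...) {
  cohort_config(n_participants = n, seed = seed,
                alpha1 = 0, alpha2 = 0, alpha3 = 0,
                beta1 = 0, beta2 = 0, gamma_direct = 0,
                gamma_age = 0, gamma_sex = 0, gamma_base = 0,
                intercept_outcome = intercept, ...)
}

# a model-ready frame with all paths structurally zero, built directly
make_null_frame <- function(n, seed, p_out = 0.05) {
  set.seed(seed)
  zs <- function(x) (x - mean(x)) / sd(x)
  data.frame(pain = rbinom(n, 1, 0.5),
             ds_z = zs(rnorm(n)), pa_z = zs(rnorm(n)), age_z = zs(runif(n)),
             sex = rbinom(n, 1, 0.4), dep_base = rbinom(n, 1, 0.02),
             dep_fu = rbinom(n, 1, p_out))
}

# frame with discrete covariates and a handful of outcome events placed on
# complementary covariate patterns (every covariate sees events at both
# levels, so the full-sample likelihood is well behaved while resamples
# that lose the events, or keep only one pattern, fail and are redrawn)
make_discrete_frame <- function(n, seed, events_per_pattern = 3) {
  set.seed(seed)
  zs <- function(x) (x - mean(x)) / sd(x)
  b <- function() rbinom(n, 1, 0.5)
  raw <- data.frame(pain = b(), dsb = b(), pab = b(), ageb = b(),
                    sex = b(), dep_base = b())
  k <- events_per_pattern
  raw[1:k, ] <- 0
  raw[(k + 1):(2 * k), ] <- 1
  data.frame(pain = raw$pain, ds_z = zs(raw$dsb), pa_z = zs(raw$pab),
             age_z = zs(raw$ageb), sex = raw$sex,
             dep_base = raw$dep_base,
             dep_fu = c(rep(1, 2 * k), rep(0, n - 2 * k)))
}

# random full-rank design plus gaussian response, for the OLS oracles
make_linear_data <- function(n, p, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), nrow = n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  beta <- rnorm(p)
  list(X = X, y = drop(X %*% beta + rnorm(n)),
       df = data.frame(y = drop(X %*% beta + rnorm(n)),
                       X[, -1, drop = FALSE]))
}

expand_2x2 <- function(n11, n10, n01, n00) {
  # exposed-event, exposed-nonevent, unexposed-event, unexposed-nonevent
  data.frame(
    y = c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00)),
    x = c(rep(1, n11 + n10), rep(0, n01 + n00)))
}
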