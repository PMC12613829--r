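test_that("linear fit recovers exact relationships", {
  d <- data.frame(x = c(0, 1, 2, 3), y = c(1, 3, 5, 7))
  # noiseless fixtures trigger lm's perfect-fit advisory
  f <- suppressWarnings(fit_linear(y ~ x, d))
  expect_equal(f$coefficients$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-12)

  # outcome identical to one predictor: unit coefficient, zero elsewhere
  set.seed(3)
  d2 <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d2$y <- d2$x1
  f2 <- suppressWarnings(fit_linear(y ~ x1 + x2, d2))
  expect_equal(f2$coefficients$estimate, c(0, 1, 0), tolerance = 1e-10)
  expect_equal(f2$adjusted_r2, 1, tolerance = 1e-10)
})

test_that("linear fit equals the normal-equations solution and reports honestly", {
  for (s in 1:5) {
    ld <- make_linear_data(20, 4, seed = s)
    f <- fit_linear(y ~ x1 + x2 + x3, ld$df)
    X <- cbind(1, as.matrix(ld$df[, c("x1", "x2", "x3")]))
    beta <- solve(crossprod(X), crossprod(X, ld$df$y))
    expect_lt(max(abs(f$coefficients$estimate - drop(beta))), 1e-8)
    # adjusted R2 from its defining formula
    res <- ld$df$y - drop(X %*% beta)
    r2 <- 1 - sum(res^2) / sum((ld$df$y - mean(ld$df$y))^2)
    expect_equal(f$adjusted_r2, 1 - (1 - r2) * 19 / (20 - 3 - 1),
                 tolerance = 1e-10)
    # CI brackets the estimate
    expect_true(all(f$coefficients$ci_lower <= f$coefficients$estimate &
                      f$coefficients$estimate <= f$coefficients$ci_upper))
  }
})

test_that("shifting a predictor by a constant changes only the intercept", {
  ld <- make_linear_data(60, 3, seed = 9)
  d <- ld$df
  d$y_b <- rbinom(60, 1, plogis(0.3 * d$x1 - 0.5 * d$x2))
  d2 <- d
  d2$x1 <- d2$x1 + 7

  f1 <- fit_linear(y ~ x1 + x2, d)
  f2 <- fit_linear(y ~ x1 + x2, d2)
  expect_lt(max(abs(f1$coefficients$estimate[-1] -
                      f2$coefficients$estimate[-1])), 1e-8)

  g1 <- fit_logistic(y_b ~ x1 + x2, d)
  g2 <- fit_logistic(y_b ~ x1 + x2, d2)
  expect_lt(max(abs(g1$coefficients$estimate[-1] -
                      g2$coefficients$estimate[-1])), 1e-8)
})

test_that("logistic fit matches closed forms and an independent optimizer", {
  # balanced outcome, intercept-only: zero intercept, zero McFadden R2
  d0 <- data.frame(y = rep(c(0, 1), 25))
  f0 <- fit_logistic(y ~ 1, d0)
  expect_lt(abs(f0$coefficients$estimate[1]), 1e-10)
  expect_lt(abs(f0$mcfadden_r2), 1e-12)

  # 2x2 table: slope is the closed-form log odds ratio
  d <- expand_2x2(10, 20, 30, 40)
  f <- fit_logistic(y ~ x, d)
  expect_equal(f$coefficients$estimate[2], log((10 * 40) / (20 * 30)),
               tolerance = 1e-9)
  # saturated model: fitted probabilities equal the cell frequencies
  mu <- fitted(f$fit)
  expect_lt(max(abs(mu[d$x == 1] - 10 / 30)), 1e-8)
  expect_lt(max(abs(mu[d$x == 0] - 30 / 70)), 1e-8)

  # 50-row fixture against a long-run quasi-Newton optimizer on the same
  # likelihood
  set.seed(14)
  X <- cbind(1, rnorm(50), rnorm(50))
  y <- rbinom(50, 1, plogis(X %*% c(-0.4, 0.8, -0.6)))
  df <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
  ff <- fit_logistic(y ~ x1 + x2, df)
  negll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
  opt <- optim(c(0, 0, 0), negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(ff$coefficients$estimate - opt$par)), 1e-6)
  # the fitted solution is at least as good as any probe point
  set.seed(15)
  for (i in 1:20)
    expect_gte(ff$loglik + 1e-10, -negll(opt$par + rnorm(3, 0, 0.5)))
  expect_true(ff$converged)
  expect_lt(ff$max_gradient, 1e-6)
})

test_that("estimation errors are detected and named", {
  d <- data.frame(y = rep(0, 20), x = rnorm(20))
  expect_error(fit_logistic(y ~ x, d), "single class")
  d2 <- data.frame(y = rnorm(20), a = rnorm(20))
  d2$b <- 2 * d2$a
  expect_error(fit_linear(y ~ a + b, d2), "collinear.*b")
  # complete separation
  d3 <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)),
                   y = rep(c(0, 1), each = 20))
  expect_error(fit_logistic(y ~ x, d3), "separation")
})

test_that("compiled kernel agrees with the lm/glm route", {
  set.seed(31)
  n <- 400
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n), rnorm(n))
  y <- rbinom(n, 1, plogis(X %*% c(-1, 0.5, 0.4, -0.3)))
  df <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3], x3 = X[, 4])

  kf <- serialmed:::logistic_fit_cpp(X, y, rep(0, 4), tol = 1e-12)
  gf <- fit_logistic(y ~ x1 + x2 + x3, df)
  expect_true(kf$ok)
  expect_lt(max(abs(drop(kf$beta) - gf$coefficients$estimate)), 1e-8)

  yl <- rnorm(n)
  ko <- serialmed:::ols_fit_cpp(X, yl)
  lf <- lm(yl ~ x1 + x2 + x3, data = df)
  expect_lt(max(abs(drop(ko$beta) - unname(coef(lf)))), 1e-10)

  # the bootstrap's fused path fit equals the four formula-based models
  ch <- generate_cohort(cohort_config(n_participants = 4000, seed = 32))
  fr <- build_analysis_frame(ch)
  dd <- fr$data
  Z <- cbind(1, dd$pain, dd$ds_z, dd$pa_z, dd$age_z, dd$sex, dd$dep_base)
  for (fam in c("binomial", "gaussian")) {
    yy <- if (fam == "binomial") dd$dep_fu else dd$pa_z + rnorm(nrow(dd))
    dd2 <- dd
    dd2$dep_fu <- yy
    kp <- serialmed:::fit_paths_cpp(Z, yy,
                                    if (fam == "binomial") 0L else 1L,
                                    rep(0, 5), rep(0, 7), tol = 1e-12)
    pe <- estimate_paths(dd2, outcome_family = fam)
    est <- setNames(pe$paths$estimate, pe$paths$path)
    expect_true(kp$ok)
    expect_lt(max(abs(kp$paths[names(est)] - est)), 1e-8)
  }
})
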