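# Linear and logistic fits with the reporting surface the path models need.
# Estimation is delegated to stats::lm / stats::glm; this layer adds strict
# design-rank checking, separation diagnostics, gradient bookkeeping, and
# the fit statistics used in mediation reports (adjusted R2, McFadden R2).

# error naming the collinear columns of a rank-deficient design
check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

coef_table <- function(est, se, crit, df = Inf) {
  stat <- est / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else
    2 * stats::pnorm(-abs(stat))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lower = unname(est - crit * se),
             ci_upper = unname(est + crit * se),
             statistic = unname(stat), p_value = unname(p),
             row.names = NULL)
}

#' Ordinary least squares fit for a mediator model
#'
#' Least-squares regression via [stats::lm()] with a full-rank design check,
#' t-based 95% confidence intervals, and the adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param conf_level confidence level for the intervals.
#' @return an object of class `linear_fit`: list with `coefficients` (a
#'   term/estimate/se/ci/p table), `adjusted_r2`, `sigma`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_linear <- function(formula, data, conf_level = 0.95) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  if (nrow(X) <= ncol(X))
    stop("n must exceed the number of predictors", call. = FALSE)
  check_full_rank(X)
  fit <- stats::lm(formula, data)
  s <- summary(fit)
  est <- stats::coef(fit)
  se <- s$coefficients[, "Std. Error"]
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  out <- list(coefficients = coef_table(est, se, crit, df = fit$df.residual),
              adjusted_r2 = s$adj.r.squared, r2 = s$r.squared,
              sigma = s$sigma, n = nrow(X), fit = fit)
  class(out) <- "linear_fit"
  out
}

#' Maximum-likelihood logistic fit for an outcome model
#'
#' Binomial regression via [stats::glm()] (iteratively reweighted least
#' squares, tight convergence tolerance, at most `maxit` iterations), with a
#' full-rank design check, Wald z confidence intervals, McFadden pseudo
#' R-squared `1 - l_model / l_null`, the score (gradient) norm at the
#' solution, and complete-separation detection: any coefficient exceeding
#' `sep_limit` in absolute value raises an estimation error, since on a
#' bounded-odds scale such values indicate divergence rather than signal.
#'
#' @param formula model formula; the response must be binary with both
#'   classes present.
#' @param data data frame.
#' @param conf_level confidence level for the Wald intervals.
#' @param maxit maximum IRLS iterations.
#' @param sep_limit absolute-coefficient threshold for the separation
#'   diagnostic.
#' @return an object of class `logistic_fit`: list with `coefficients`
#'   (Wald table of log odds ratios), `mcfadden_r2`, `loglik`,
#'   `loglik_null`, `converged`, `iterations`, `max_gradient`, `n`, and the
#'   underlying `glm` fit.
#' @export
fit_logistic <- function(formula, data, conf_level = 0.95, maxit = 100L,
                         sep_limit = 15) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1)))
    stop("logistic outcome must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("logistic outcome has a single class; cannot estimate",
         call. = FALSE)
  X <- stats::model.matrix(formula, mf)
  check_full_rank(X)
  fit <- suppressWarnings(stats::glm(
    formula, data = data, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = maxit)))
  est <- stats::coef(fit)
  if (any(abs(est) > sep_limit))
    stop("possible complete separation: |log OR| above ", sep_limit,
         " for ", paste(names(est)[abs(est) > sep_limit], collapse = ", "),
         call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  mu <- stats::fitted(fit)
  grad <- drop(crossprod(X, y - mu))
  ll <- as.numeric(stats::logLik(fit))
  pbar <- mean(y)
  ll0 <- sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  out <- list(coefficients = coef_table(est, se, crit),
              mcfadden_r2 = 1 - ll / ll0, loglik = ll, loglik_null = ll0,
              converged = fit$converged, iterations = fit$iter,
              max_gradient = max(abs(grad)), n = nrow(X), fit = fit)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.linear_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Linear model (n = %d, adjusted R2 = %.3f)\n", x$n,
              x$adjusted_r2))
  print(format_coef(x$coefficients, digits))
  invisible(x)
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Logistic model (n = %d, McFadden R2 = %.3f, %d IRLS iterations)\n",
    x$n, x$mcfadden_r2, x$iterations))
  print(format_coef(x$coefficients, digits))
  invisible(x)
}

format_coef <- function(tab, digits) {
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, digits))
  out
}
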