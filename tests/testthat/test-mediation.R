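test_that("decomposition identities and undefined-percentage markers", {
  set.seed(41)
  for (i in 1:20) {
    cf <- setNames(rnorm(7), c("a1", "a2", "a3", "b1", "b2", "c",
                               "c_prime"))
    dec <- decompose_indirect(cf)
    expect_identical(dec$total_indirect,
                     dec$ind_ds + dec$ind_pa + dec$ind_serial)
    expect_lt(abs(sum(dec$pct_of_indirect) - 100), 1e-9)
  }
  # all paths zero except c = c' = 1
  dec0 <- decompose_indirect(c(a1 = 0, a2 = 0, a3 = 0, b1 = 0, b2 = 0,
                               c = 1, c_prime = 1))
  expect_identical(dec0$total_indirect, 0)
  expect_identical(dec0$pct_mediated_total, 0)
  expect_true(all(is.na(dec0$pct_of_indirect)))
  # undefined shares when the total effect is zero
  decna <- decompose_indirect(c(a1 = 0.1, a2 = 0.1, a3 = 0.1, b1 = 0.1,
                                b2 = 0.1, c = 0, c_prime = 0.1))
  expect_true(is.na(decna$pct_mediated_total))
  expect_true(all(is.na(decna$pct_of_total)))
  expect_error(decompose_indirect(c(a1 = 1)), "missing path")
})

test_that("path estimation wires the four regressions correctly", {
  ch <- generate_cohort(cohort_config(n_participants = 4000, seed = 43))
  fr <- build_analysis_frame(ch)
  pe <- estimate_paths(fr)
  est <- setNames(pe$paths$estimate, pe$paths$path)
  d <- fr$data
  # independent refits, model by model
  expect_equal(est[["a1"]],
               unname(coef(lm(ds_z ~ pain + age_z + sex + dep_base, d))["pain"]),
               tolerance = 1e-10)
  m23 <- coef(lm(pa_z ~ pain + ds_z + age_z + sex + dep_base, d))
  expect_equal(est[["a2"]], unname(m23["pain"]), tolerance = 1e-10)
  expect_equal(est[["a3"]], unname(m23["ds_z"]), tolerance = 1e-10)
  mc <- coef(glm(dep_fu ~ pain + age_z + sex + dep_base, d,
                 family = binomial()))
  expect_equal(est[["c"]], unname(mc["pain"]), tolerance = 1e-7)
  mf <- coef(glm(dep_fu ~ pain + ds_z + pa_z + age_z + sex + dep_base, d,
                 family = binomial()))
  expect_equal(est[["c_prime"]], unname(mf["pain"]), tolerance = 1e-7)
  expect_equal(est[["b1"]], unname(mf["ds_z"]), tolerance = 1e-7)
  expect_equal(est[["b2"]], unname(mf["pa_z"]), tolerance = 1e-7)

  # degenerate exposure is reported as a labeled estimation error naming
  # the collinearity
  d2 <- d
  d2$pain <- 1
  expect_error(estimate_paths(d2), "estimation failed for path")
  expect_error(estimate_paths(d2), "collinear.*pain")
})

test_that("all paths vanish on a cohort with no structural effects", {
  cfg <- null_config(30000, seed = 45, intercept = -3)
  # keep covariate effects in the outcome so the adjustment is exercised
  cfg$gamma_age <- 0.5
  cfg$gamma_base <- 1.5
  fr <- build_analysis_frame(generate_cohort(cfg))
  pe <- estimate_paths(fr)
  expect_true(all(abs(pe$paths$estimate) <= 3 * pe$paths$se))
})

test_that("with a linear outcome model the decomposition is exactly additive", {
  ch <- generate_cohort(cohort_config(n_participants = 5000, seed = 47))
  fr <- build_analysis_frame(ch)
  d <- fr$data
  set.seed(48)
  d$dep_fu <- 0.4 * d$pain + 0.3 * d$ds_z - 0.2 * d$pa_z + 0.1 * d$age_z +
    rnorm(nrow(d))
  pe <- estimate_paths(d, outcome_family = "gaussian")
  dec <- decompose_indirect(pe)
  cf <- dec$coefficients
  expect_lt(abs((cf[["c"]] - cf[["c_prime"]]) - dec$total_indirect), 1e-8)
})

test_that("swapped mediator ordering preserves the total indirect effect", {
  ch <- generate_cohort(cohort_config(n_participants = 6000, seed = 51))
  fr <- build_analysis_frame(ch)
  dec <- decompose_indirect(estimate_paths(fr))
  alt <- alternate_ordering(fr)
  # exact in-sample identity: both orderings share the outcome model and
  # the OLS mediator fits satisfy the omitted-variable algebra
  expect_lt(abs(alt$total_indirect - dec$total_indirect), 1e-10)
  # wiring of the swapped first-mediator pathway
  d <- fr$data
  a1_sw <- unname(coef(lm(pa_z ~ pain + age_z + sex + dep_base, d))["pain"])
  b2 <- dec$coefficients[["b2"]]
  expect_equal(alt$ind_pa, a1_sw * b2, tolerance = 1e-8)
  expect_identical(attr(alt, "ordering"), "pa_first")
})

test_that("bootstrap resampling is seed-reproducible and seed-sensitive", {
  fr <- make_null_frame(800, seed = 53, p_out = 0.2)
  b1 <- bootstrap_mediation(fr, B = 5, seed = 99)
  b2 <- bootstrap_mediation(fr, B = 5, seed = 99)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_mediation(fr, B = 5, seed = 100)
  expect_false(identical(b1$draws, b3$draws))
  expect_true(all(b1$ci$ci_lower <= b1$ci$ci_upper))
  expect_identical(nrow(b1$draws), 5L)
  expect_error(bootstrap_mediation(fr, B = 1), "B must be")
})

test_that("failed resamples are redrawn and counted, keeping B fixed", {
  # 6 events among 300 rows: resamples that lose the events (or keep only
  # one covariate pattern of them) fail estimation and must be redrawn
  fr <- make_discrete_frame(300, seed = 55)
  bt <- bootstrap_mediation(fr, B = 400, seed = 7)
  expect_identical(nrow(bt$draws), 400L)
  expect_identical(bt$n_resamples_requested, 400L)
  expect_gt(bt$n_failed_and_redrawn, 0)
})

test_that("null indirect effects are covered by percentile intervals", {
  # all paths structurally zero: each indirect CI should contain 0 in at
  # least 19 of 20 seeds
  quantities <- c("ind_ds", "ind_pa", "ind_serial", "total_indirect")
  misses <- setNames(numeric(4), quantities)
  for (s in 1:20) {
    fr <- make_null_frame(5000, seed = 600 + s, p_out = 0.05)
    bt <- bootstrap_mediation(fr, B = 500, seed = s)
    ci <- bt$ci[match(quantities, bt$ci$quantity), ]
    misses <- misses + as.numeric(ci$ci_lower > 0 | ci$ci_upper < 0)
  }
  expect_true(all(misses <= 1))
})

test_that("stronger activity effects increase the recovered activity pathway", {
  ind_pa_at <- function(beta2, seed) {
    cfg <- cohort_config(n_participants = 8000, seed = seed, beta2 = beta2)
    dec <- decompose_indirect(estimate_paths(build_analysis_frame(
      generate_cohort(cfg))))
    abs(dec$ind_pa)
  }
  weak <- vapply(1:10, function(s) ind_pa_at(-0.3, 700 + s), numeric(1))
  strong <- vapply(1:10, function(s) ind_pa_at(-0.9, 700 + s), numeric(1))
  expect_gt(mean(strong), mean(weak))
})
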