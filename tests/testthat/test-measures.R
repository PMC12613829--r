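test_that("CESD scoring sums items and applies the single-item imputation rule", {
  expect_identical(score_cesd(rep(0, 10)), 0)
  expect_identical(score_cesd(rep(3, 10)), 30)
  # one missing item: sum of the nine present plus their mean
  expect_equal(score_cesd(c(rep(1, 9), NA)), 10)
  expect_equal(score_cesd(c(rep(3, 9), NA)), 30)
  items <- c(2, 0, 1, 3, 0, 0, 1, 2, 0, NA)
  expect_equal(score_cesd(items), 9 * 10 / 9)
  # result is not rounded
  expect_equal(score_cesd(c(rep(0, 8), 1, NA)), 1 * 10 / 9)

  # permutation invariance
  set.seed(4)
  for (i in 1:20) {
    v <- sample(c(0:3, NA), 10, replace = TRUE,
                prob = c(rep(0.24, 4), 0.04))
    expect_identical(score_cesd(v), score_cesd(sample(v)))
  }

  # matrix input scores row-wise identically to vector input
  M <- rbind(rep(1, 10), c(rep(2, 9), NA), rep(0, 10))
  expect_equal(score_cesd(M),
               c(score_cesd(M[1, ]), score_cesd(M[2, ]),
                 score_cesd(M[3, ])))
})

test_that("CESD exclusion signal and response validation", {
  expect_true(is.na(score_cesd(c(rep(1, 8), NA, NA))))
  expect_true(is.na(score_cesd(rep(NA_real_, 10))))
  expect_error(score_cesd(c(rep(1, 9), 4)), "0, 1, 2, 3")
  expect_error(score_cesd(c(rep(1, 9), -1)), "0, 1, 2, 3")
  expect_error(score_cesd(rep(1, 9)), "10 item")
})

test_that("depression log transform is anchored, monotone, and validated", {
  expect_identical(log_cesd(0), 0)
  expect_gt(log_cesd(10), log_cesd(5))
  # high-precision anchor for log(1 + 29)
  expect_equal(log_cesd(29), 3.401197381662155, tolerance = 1e-13)
  expect_equal(log_cesd(4, offset = 0.5), log(4.5))
  expect_error(log_cesd(-1), "non-negative")
  expect_error(log_cesd(3, offset = 0), "offset")
})

test_that("activity composite matches its weight table and is monotone", {
  expect_identical(score_pase(rep(1, 5), rep(1, 5)), 0)
  # maximum attainable score is the documented instrument ceiling
  expect_identical(score_pase(rep(4, 5), rep(5, 5)), 485)
  # fixed fixture, evaluated independently from the weight table by hand:
  # 100*.25*.6 + 80*0*1 + 100*.5*.4 + 120*1*.8 + 85*.25*.2
  expect_equal(score_pase(c(2, 1, 3, 4, 2), c(3, 5, 2, 4, 1)), 135.25)

  # raising any frequency or duration never decreases the score
  set.seed(11)
  for (i in 1:25) {
    freq <- sample(1:4, 5, replace = TRUE)
    dur <- sample(1:5, 5, replace = TRUE)
    base <- score_pase(freq, dur)
    k <- sample(5, 1)
    if (freq[k] < 4) {
      f2 <- freq; f2[k] <- f2[k] + 1
      expect_gte(score_pase(f2, dur), base)
    }
    if (dur[k] < 5) {
      d2 <- dur; d2[k] <- d2[k] + 1
      expect_gte(score_pase(freq, d2), base)
    }
  }

  expect_error(score_pase(c(5, 1, 1, 1, 1), rep(1, 5)), "frequency")
  expect_error(score_pase(rep(1, 5), c(1, 1, 6, 1, 1)), "duration")
})

test_that("functional-dependence dichotomization under both schemes", {
  expect_equal(dichotomize_dependence(1:5, "main"), c(0, 0, 1, 1, 1))
  expect_equal(dichotomize_dependence(1:5, "strict"), c(0, 1, 1, 1, 1))
  # strict never reclassifies a dependent person as independent
  expect_true(all(dichotomize_dependence(1:5, "strict") >=
                    dichotomize_dependence(1:5, "main")))
  expect_error(dichotomize_dependence(0), "1-5")
  expect_error(dichotomize_dependence(6), "1-5")
})

test_that("analysis frame standardizes on the analysis sample and is idempotent", {
  ch <- generate_cohort(cohort_config(n_participants = 2000, seed = 21))
  fr <- build_analysis_frame(ch)
  for (v in c("ds_z", "pa_z", "age_z")) {
    expect_lt(abs(mean(fr$data[[v]])), 1e-10)
    expect_lt(abs(sd(fr$data[[v]]) - 1), 1e-10)
    # re-standardizing an already standardized column changes nothing
    z2 <- serialmed:::standardize(fr$data[[v]])$z
    expect_lt(max(abs(z2 - fr$data[[v]])), 1e-10)
  }
  expect_false(anyNA(fr$data))
})

test_that("analysis frame applies exclusions and schemes as specified", {
  # 5-row hand-built cohort: keep, keep (1 missing item), drop (2 missing),
  # drop (missing activity), keep
  items <- rbind(rep(1, 10),
                 c(rep(2, 9), NA),
                 c(rep(1, 8), NA, NA),
                 rep(0:1, 5),
                 c(3, rep(0, 9)))
  ch <- data.frame(id = 1:5, pain = c(1, 0, 1, 0, 1))
  ch[paste0("cesd_", 1:10)] <- as.data.frame(items)
  ch$pase_score <- c(100, 200, 150, NA, 50)
  ch$adl_class_baseline <- c(1, 2, 1, 1, 3)
  ch$adl_class_followup <- c(1, 3, 1, 1, 2)
  ch$age_years <- c(50, 60, 70, 55, 80)
  ch$sex <- c(0, 1, 0, 1, 0)
  ch$oa <- c(1, 1, 1, 1, 0)
  ch$ra <- c(0, 1, 0, 0, 1)
  ch$other_arthritis <- c(0, 0, 0, 0, 1)

  fr <- build_analysis_frame(ch)
  expect_equal(fr$n, 3L)
  expect_equal(unname(fr$exclusions), c(1L, 1L))
  expect_equal(fr$data$pain, c(1, 0, 1))
  # row 2's depression score was imputed: 18 * 10 / 9 = 20
  expect_equal(fr$scaling$ds$center,
               mean(log(c(10, 20, 3) + 1)))
  # main vs strict scheme on the follow-up classes (1, 3, 2)
  expect_equal(fr$data$dep_fu, c(0, 1, 0))
  fr_strict <- build_analysis_frame(ch, scheme = "strict")
  expect_equal(fr_strict$data$dep_fu, c(0, 1, 1))
  expect_true(sum(fr_strict$data$dep_fu) >= sum(fr$data$dep_fu))
  # baseline dependence follows the same scheme
  expect_equal(fr_strict$data$dep_base, c(0, 1, 1))

  # subtype filters are plain flag filters
  fr_oa <- build_analysis_frame(ch, subset = "oa")
  expect_equal(fr_oa$n, 2L)
  expect_error(build_analysis_frame(ch[3, ], subset = "all"),
               "no complete participants")

  # a cohort where every row has two missing items cannot be analyzed
  ch2 <- ch
  ch2$cesd_1 <- NA
  ch2$cesd_2 <- NA
  expect_error(build_analysis_frame(ch2), "no complete participants")
})
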