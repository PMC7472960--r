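test_that("Kaplan-Meier matches the product-limit by hand", {
  cv <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cv$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(cv$n_risk, c(3, 2, 1))

  allc <- km_estimate(c(4, 7, 9), c(0, 0, 0))
  expect_true(all(allc$survival == 1))

  mix <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_survival_at(mix, c(0.5, 1, 2.5, 3)),
               c(1, 2 / 3, 2 / 3, 0))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "nonnegative")
  expect_error(km_estimate(c(1, 2), 1), "equal length")
})

test_that("KM without censoring is one minus the empirical CDF", {
  set.seed(8)
  tm <- round(rexp(40, 0.1), 2)
  cv <- km_estimate(tm, rep(1, 40))
  for (t in sort(unique(tm)))
    expect_equal(km_survival_at(cv, t), 1 - mean(tm <= t))
})

test_that("log-rank reproduces the by-hand worked example", {
  # A events at 1, 2; B events at 3, 4: O-E = 7/6, V = 17/36
  res <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-9)
  expect_equal(res$p, stats::pchisq(49 / 17, 1, lower.tail = FALSE))
  expect_lt(abs(res$p - 0.090), 0.001)

  # identical groups and label swap
  tm <- c(1, 3, 5, 7); ev <- c(1, 0, 1, 1)
  same <- logrank_test(tm, ev, tm, ev)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  swap <- logrank_test(c(3, 4), c(1, 1), c(1, 2), c(1, 1))
  expect_equal(swap$statistic, res$statistic)

  # invariant under a common strictly monotone re-timing
  res2 <- logrank_test(c(1, 2)^2, c(1, 1), c(3, 4)^2, c(1, 1))
  expect_equal(res2$statistic, res$statistic)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
               "no events")
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "nonempty")
})

test_that("stratification rules dichotomize and count exclusions", {
  rec <- make_records(6,
                      age = c(40, 56, 70, 55, NA, 60),
                      who_grade = c("I", "I", "II", "III", "I", "I"))
  coh <- cohort(rec)
  age_split <- split_threshold("age", "age", 56)
  s <- stratify_cohort(coh, age_split)
  expect_equal(s$nA, 3)  # >= 56
  expect_equal(s$nB, 2)
  expect_equal(s$excluded_n, 1)

  gr <- stratify_cohort(coh, split_levels("grade", "who_grade",
                                          c("II", "III"), "I"))
  expect_equal(gr$nA, 2)
  expect_equal(gr$nB, 4)

  g <- tiny_grid()
  masks <- list(lesion_mask("T001", g, 1:100),
                lesion_mask("T002", g, 1:10))
  names(masks) <- c("T001", "T002")
  vs <- split_volume(masks, cutoff_cm3 = 0.5)  # 100 voxels * 8 mm^3 = 0.8
  got <- vs$assign(rec[1:2, ])
  expect_equal(got, c("A", "B"))
})

test_that("grade-dependent recurrence yields inferior high-grade RFS", {
  rec <- make_records(3000,
                      who_grade = rep(c("I", "II", "III"),
                                      c(2700, 260, 40)))
  rec$patient_id <- sprintf("G%04d", seq_len(3000))
  rec <- simulate_recurrence(rec, c(0.028, 0.079, 0.538), 60, seed = 17)
  coh <- cohort(rec)
  res <- rfs_comparison(coh, split_levels("grade", "who_grade",
                                          c("II", "III"), "I"))
  expect_lt(res$test$p, 0.001)
  # high-grade curve sits below grade I at the horizon
  expect_lt(min(res$curve_a$survival), min(res$curve_b$survival))
})
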