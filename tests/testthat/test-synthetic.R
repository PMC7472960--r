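test_that("the region atlas is deterministic, complete and mirrored", {
  g <- default_grid()
  atlas <- build_region_atlas(g)
  expect_identical(sort(unique(as.vector(atlas$labels[atlas$labels > 0]))),
                   1:15)
  atlas2 <- build_region_atlas(g)
  expect_identical(atlas$labels, atlas2$labels)

  flip <- atlas$labels[g$shape[1]:1, , ]
  bilateral <- unique(atlas$components$category_id[
    atlas$components$side != "midline"])
  for (cid in bilateral)
    expect_identical(which(flip == cid), which(atlas$labels == cid))
  # midline categories have voxels on both sides of (or on) x = 0
  wx <- voxel_to_world(g, cbind(0:(g$shape[1] - 1), 0, 0))[, 1]
  for (cid in setdiff(1:15, bilateral)) {
    xs <- wx[arrayInd(which(atlas$labels == cid), g$shape)[, 1]]
    expect_lte(min(xs), 0)
    expect_gte(max(xs), 0)
  }
  expect_error(build_region_atlas(make_grid(c(4, 4, 4), c(4, 4, 4))),
               "too small")
})

test_that("generate_cohort is reproducible and structurally sound", {
  atlas <- build_region_atlas(default_grid())
  cfg <- simulation_config(n_patients = 20, seed = 11)
  g1 <- generate_cohort(cfg, atlas)
  g2 <- generate_cohort(cfg, atlas)
  expect_equal(g1$cohort$n, 20)
  expect_length(g1$masks, 20)
  expect_identical(g1$cohort$records, g2$cohort$records)
  expect_identical(lapply(g1$masks, `[[`, "indices"),
                   lapply(g2$masks, `[[`, "indices"))
  expect_true(all(vapply(g1$masks, `[[`, 0L, "voxel_count") > 0))
  # a different seed changes the cohort
  g3 <- generate_cohort(simulation_config(n_patients = 20, seed = 12),
                        atlas)
  expect_false(identical(g1$cohort$records$age, g3$cohort$records$age))
})

test_that("empirical location frequencies converge to the weights", {
  atlas <- build_region_atlas(default_grid())
  cfg <- simulation_config(n_patients = 10000, seed = 5)
  gen <- generate_cohort(cfg, atlas)
  share <- mean(gen$cohort$records$location_label == "convexity")
  # sampling weight 230/1107 = 20.8%; binomial SE ~ 0.4 pp at n = 10,000
  expect_lt(abs(share - 230 / 1107), 0.015)
  # sex and grade marginals land near their weights too
  expect_lt(abs(mean(gen$cohort$records$sex == "female") - 785 / 1107),
            0.02)
  expect_lt(abs(mean(gen$cohort$records$who_grade == "I") - 993 / 1107),
            0.02)
})

test_that("a planted effect tilts the phenotype's location draw", {
  atlas <- build_region_atlas(default_grid())
  eff <- effect_spec("who_grade", c("II", "III"), "falx", 8)
  gen <- generate_cohort(
    simulation_config(n_patients = 2000, seed = 9, effect = eff), atlas)
  r <- gen$cohort$records
  high <- r$who_grade %in% c("II", "III")
  rate_high <- mean(r$location_label[high] == "falx")
  rate_low <- mean(r$location_label[!high] == "falx")
  expect_gt(rate_high, 2 * rate_low)
  expect_error(effect_spec("who_grade", "II", "falx", 0), "odds_multiplier")
  expect_error(effect_spec("who_grade", "II", "amygdala", 2), "region")
})

test_that("recurrence simulation honours degenerate and target rates", {
  rec0 <- simulate_recurrence(make_records(50), c(0, 0, 0), 60, seed = 3)
  expect_true(all(rec0$recurrence == "no"))
  expect_true(all(rec0$followup_time == 60))
  rec1 <- simulate_recurrence(make_records(50), c(1, 1, 1), 60, seed = 3)
  expect_true(all(rec1$recurrence == "yes"))
  expect_true(all(rec1$followup_time <= 60 & rec1$followup_time > 0))

  # grade-stratified marginal fidelity at n = 5,000 per grade
  big <- make_records(15000,
                      who_grade = rep(c("I", "II", "III"), each = 5000))
  big$patient_id <- sprintf("S%05d", seq_len(15000))
  out <- simulate_recurrence(big, c(0.028, 0.079, 0.538), 60, seed = 21)
  r3 <- mean(out$recurrence[out$who_grade == "III"] == "yes")
  expect_lt(abs(r3 - 0.538), 0.04)
  r1 <- mean(out$recurrence[out$who_grade == "I"] == "yes")
  expect_lt(abs(r1 - 0.028), 0.01)

  expect_error(simulate_recurrence(make_records(2), c(-0.1, 0, 0), 60, 1),
               "rates")
  nog <- make_records(2, who_grade = c("I", NA))
  expect_error(simulate_recurrence(nog, c(0, 0, 0), 60, 1), "grade")
})

test_that("the marginal reference cohort realises its counts exactly", {
  coh <- marginal_cohort()
  expect_equal(coh$n, 1107)
  r <- coh$records
  expect_equal(sum(r$location_label == "convexity"), 230)
  expect_equal(sum(r$who_grade == "I"), 993)
  expect_equal(sum(r$sex == "female"), 785)
  expect_equal(sum(r$recurrence == "yes"), 43)
  expect_equal(sum(!is.na(r$eor)), 1050)
})
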