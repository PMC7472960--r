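test_that("overlap counts match the brute-force superposition oracle", {
  g <- tiny_grid()
  m1 <- lesion_mask("a", g, indices = c(1, 2, 3))
  m2 <- lesion_mask("b", g, indices = c(3, 4))
  m3 <- lesion_mask("c", g, indices = c(3, 9))
  fm <- build_frequency_map(list(m1, m2, m3))
  expect_equal(fm$counts[3], 3L)
  expect_equal(fm$percentage[3], 100)
  expect_equal(fm$counts[1], 1L)

  disjoint <- list(lesion_mask("a", g, indices = 1:5),
                   lesion_mask("b", g, indices = 6:10))
  expect_equal(max(build_frequency_map(disjoint)$counts), 1L)

  set.seed(42)
  masks <- lapply(1:7, function(i) random_mask(paste0("r", i), g))
  fm <- build_frequency_map(masks)
  expect_equal(array(fm$counts, dim = g$shape), oracle_counts(masks))
  expect_equal(sum(fm$counts),
               sum(vapply(masks, `[[`, 0L, "voxel_count")))
})

test_that("frequency maps are order-invariant and additive over halves", {
  g <- tiny_grid()
  set.seed(7)
  masks <- lapply(1:8, function(i) random_mask(paste0("m", i), g))
  full <- build_frequency_map(masks, n = 8)
  perm <- build_frequency_map(masks[sample(8)], n = 8)
  expect_identical(full$counts, perm$counts)
  left <- build_frequency_map(masks[1:4], n = 4)
  right <- build_frequency_map(masks[5:8], n = 4)
  expect_identical(full$counts, left$counts + right$counts)
})

test_that("mixed grids and empty inputs are rejected", {
  g <- tiny_grid()
  other <- make_grid(c(6, 6, 7), c(2, 2, 2))
  expect_error(build_frequency_map(list(lesion_mask("a", g, 1),
                                        lesion_mask("b", other, 1))),
               "grid mismatch")
  expect_error(build_frequency_map(list()), "no masks")
  expect_error(build_frequency_map(list(lesion_mask("a", g, 1)), n = 0),
               "n must")
})

test_that("display clipping caps percentages without altering the map", {
  g <- tiny_grid()
  masks <- lapply(1:10, function(i)
    lesion_mask(paste0("m", i), g, indices = if (i <= 7) 1L else 2L))
  fm <- build_frequency_map(masks)  # voxel 1 at 70%, voxel 2 at 30%
  capped <- clip_for_display(fm, cap = 5)
  expect_equal(capped[1], 5)
  expect_equal(capped[3], 0)
  expect_equal(fm$percentage[1], 70)  # underlying map untouched
  expect_equal(clip_for_display(fm, cap = 100), fm$percentage)
  expect_error(clip_for_display(fm, cap = 0), "cap")
})

test_that("location summary computes printed-style percentages", {
  one <- cohort(make_records(1, location_label = "tentorium"))
  s1 <- location_summary(one)
  expect_equal(s1$locations$percent[s1$locations$category == "tentorium"],
               100.0)

  # 3 of 16 = 18.75 -> 18.8 under round-half-away-from-zero
  rec <- make_records(16, location_label = rep(c("falx", "convexity"),
                                               c(3, 13)))
  s <- location_summary(cohort(rec))
  expect_equal(s$locations$percent[s$locations$category == "falx"], 18.8)
  expect_lte(abs(sum(s$locations$percent) - 100), 0.1 * 15)
  expect_error(location_summary(cohort(make_records(0))))
})
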