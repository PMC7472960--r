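test_that("grid construction derives voxel volume and honours overrides", {
  g <- make_grid(c(45, 54, 45), c(4, 4, 4))
  expect_equal(g$voxel_volume, 64)
  expect_equal(make_grid(c(10, 10, 10), c(2, 2, 2))$voxel_volume, 8)
  g8 <- make_grid(c(10, 10, 10), c(2, 2, 2), voxel_volume_override = 0.08)
  expect_equal(g8$voxel_volume, 0.08)
  # geometric volume identity (no override)
  expect_equal(g$voxel_volume * prod(g$shape),
               prod(g$shape * g$spacing))
  expect_error(make_grid(c(0, 5, 5), c(1, 1, 1)), "invalid grid")
  expect_error(make_grid(c(5, 5, 5), c(1, -1, 1)), "invalid grid")
})

test_that("the affine is RAS+ with the mid-sagittal plane at world x = 0", {
  g <- make_grid(c(45, 54, 45), c(4, 4, 4))
  # centre voxel of the odd x-axis sits exactly on x = 0
  expect_equal(voxel_to_world(g, c(22, 0, 0))[1, 1], 0)
  # +x is right: larger i means larger world x
  expect_gt(voxel_to_world(g, c(30, 0, 0))[1, 1],
            voxel_to_world(g, c(10, 0, 0))[1, 1])
  wx <- voxel_to_world(g, cbind(0:(g$shape[1] - 1), 0, 0))[, 1]
  expect_equal(sum(wx), 0)  # symmetric lattice
  # world_to_voxel inverts voxel_to_world
  ijk <- rbind(c(3, 7, 11), c(0, 0, 0))
  expect_equal(world_to_voxel(g, voxel_to_world(g, ijk)), ijk)
})

test_that("mask files round-trip and enforce grid geometry", {
  g <- tiny_grid()
  idx <- sample.int(prod(g$shape), 100)
  m <- lesion_mask("p1", g, indices = idx)
  expect_equal(m$voxel_count, 100)
  f <- tempfile(fileext = ".nii.gz")
  write_mask_file(m, f)
  m2 <- read_mask_file(f, g)
  expect_identical(m2$indices, m$indices)
  expect_equal(m2$voxel_count, 100)

  # interpolation-blurred values above threshold become occupied
  vals <- array(0, dim = g$shape)
  vals[c(1, 5, 9)] <- 0.7
  vals[c(2, 6)] <- 0.3
  f2 <- tempfile(fileext = ".nii.gz")
  write_map_file(vals, g, f2)
  expect_identical(read_mask_file(f2, g)$indices, c(1L, 5L, 9L))
  expect_identical(read_mask_file(f2, g, threshold = 0.2)$indices,
                   c(1L, 2L, 5L, 6L, 9L))

  other <- make_grid(c(7, 6, 6), c(2, 2, 2))
  expect_error(read_mask_file(f, other), "grid mismatch")
  expect_error(read_mask_file(tempfile(fileext = ".nii"), g),
               "cannot read")
})

test_that("scalar maps round-trip bit-exactly in double storage", {
  g <- tiny_grid()
  pvals <- array(runif(prod(g$shape)), dim = g$shape)
  f <- tempfile(fileext = ".nii.gz")
  write_map_file(pvals, g, f)
  back <- as.array(RNifti::readNifti(f))
  attributes(back) <- list(dim = dim(back))
  expect_identical(back, pvals)
  expect_error(write_map_file(array(0, c(2, 2, 2)), g, f), "shape")
})

test_that("cohort tables validate ids, vocabulary and missing EOR", {
  rec <- make_records(3, eor = c("GTR", "", "STR"))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rec, f, row.names = FALSE, na = "")
  coh <- read_cohort_table(f)
  expect_equal(coh$n, 3)
  expect_true(is.na(coh$records$eor[2]))
  s <- location_summary(coh)
  expect_equal(s$eor$evaluable_n, 2)
  expect_equal(s$eor$evaluable_n, coh$n - s$eor$missing)

  dup <- make_records(2)
  dup$patient_id <- c("X1", "X1")
  expect_error(cohort(dup), "duplicate patient_id")

  bad <- make_records(2)
  bad$location_label <- c("convexity", "parietal_lobe")
  expect_error(cohort(bad), "parietal_lobe")

  neg <- make_records(1, age = -3)
  expect_error(cohort(neg), "age")
})
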