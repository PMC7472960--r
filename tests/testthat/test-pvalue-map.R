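# build a tiny cohort whose two groups carry prescribed masks
two_group_cohort <- function(masks_a, masks_b, grid) {
  n <- length(masks_a) + length(masks_b)
  rec <- make_records(n, sex = rep(c("male", "female"),
                                   c(length(masks_a), length(masks_b))))
  masks <- c(masks_a, masks_b)
  names(masks) <- rec$patient_id
  for (i in seq_len(n)) masks[[i]]$patient_id <- rec$patient_id[i]
  list(cohort = cohort(rec, grid), masks = masks,
       split = split_levels("sex", "sex", "male", "female"))
}

test_that("identical group membership patterns give p = 1 everywhere", {
  g <- tiny_grid()
  ma <- list(lesion_mask("x", g, 1:10), lesion_mask("y", g, 5:20))
  mb <- list(lesion_mask("z", g, 1:10), lesion_mask("w", g, 5:20))
  tg <- two_group_cohort(ma, mb, g)
  pm <- compute_pvalue_map(tg$cohort, tg$masks, tg$split)
  expect_true(all(pm$p == 1))
  expect_equal(sum(pm$tested), length(unique(c(1:10, 5:20))))
})

test_that("the map equals direct per-voxel Fisher tests (dual route)", {
  g <- tiny_grid()
  set.seed(13)
  ma <- lapply(1:5, function(i) random_mask(paste0("a", i), g, 0.15))
  mb <- lapply(1:7, function(i) random_mask(paste0("b", i), g, 0.25))
  tg <- two_group_cohort(ma, mb, g)
  pm <- compute_pvalue_map(tg$cohort, tg$masks, tg$split, min_count = 1)
  ca <- oracle_counts(ma)
  cb <- oracle_counts(mb)
  for (v in which(ca + cb >= 1)) {
    expect_equal(pm$p[v], oracle_fisher(ca[v], cb[v], 5 - ca[v],
                                        7 - cb[v]))
  }
  expect_true(all(pm$p[ca + cb == 0] == 1))
  expect_false(any(pm$tested[ca + cb == 0]))
  expect_lte(pm$n_distinct_tables, sum(ca + cb >= 1))
})

test_that("min_count excludes sparse voxels and FDR maps dominate p", {
  g <- tiny_grid()
  set.seed(14)
  ma <- lapply(1:6, function(i) random_mask(paste0("a", i), g, 0.2))
  mb <- lapply(1:6, function(i) random_mask(paste0("b", i), g, 0.2))
  tg <- two_group_cohort(ma, mb, g)
  pm <- compute_pvalue_map(tg$cohort, tg$masks, tg$split, min_count = 3,
                           fdr = TRUE)
  totals <- oracle_counts(ma) + oracle_counts(mb)
  expect_identical(as.vector(pm$tested), as.vector(totals >= 3))
  expect_true(all(pm$q[pm$tested] >= pm$p[pm$tested]))
  expect_true(all(pm$q[!pm$tested] == 1))
})

test_that("an empty split group is an error naming the split", {
  g <- tiny_grid()
  rec <- make_records(3, sex = "female")
  masks <- lapply(seq_len(3), function(i)
    lesion_mask(rec$patient_id[i], g, i))
  names(masks) <- rec$patient_id
  expect_error(
    suppressWarnings(
      compute_pvalue_map(cohort(rec, g), masks,
                         split_levels("sex", "sex", "male", "female"))),
    "sex")
})

make_pmap <- function(p, tested, grid, alpha = 0.05) {
  structure(list(p = p, tested = tested, alpha = alpha, q = NULL,
                 nA = 1, nB = 1, split_name = "manual",
                 n_distinct_tables = 0L, grid = grid),
            class = "pvalue_map")
}

test_that("cluster extraction respects connectivity and ordering", {
  g <- tiny_grid()
  p <- array(1, g$shape)
  tested <- array(TRUE, g$shape)

  p[2, 2, 2] <- 0.01
  pm <- make_pmap(p, tested, g)
  cl <- extract_significant_clusters(pm, connectivity = 26)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_voxels, 1)
  expect_equal(cl$peak_neglog10_p, -log10(0.01))

  # two voxels sharing only a corner
  p2 <- array(1, g$shape)
  p2[2, 2, 2] <- 0.01
  p2[3, 3, 3] <- 0.02
  pm2 <- make_pmap(p2, tested, g)
  expect_equal(nrow(extract_significant_clusters(pm2, connectivity = 6)),
               2)
  expect_equal(nrow(extract_significant_clusters(pm2, connectivity = 18)),
               2)
  cl26 <- extract_significant_clusters(pm2, connectivity = 26)
  expect_equal(nrow(cl26), 1)
  expect_equal(cl26$n_voxels, 2)

  # an edge-sharing pair joins already at 18-connectivity
  p3 <- array(1, g$shape)
  p3[2, 2, 2] <- 0.01
  p3[3, 3, 2] <- 0.02
  pm3 <- make_pmap(p3, tested, g)
  expect_equal(nrow(extract_significant_clusters(pm3, connectivity = 6)),
               2)
  expect_equal(nrow(extract_significant_clusters(pm3, connectivity = 18)),
               1)

  # clusters sort by size, and untested voxels never enter clusters
  p4 <- array(1, g$shape)
  p4[1:3, 1, 1] <- 0.01
  p4[6, 6, 6] <- 0.001
  tested4 <- tested
  tested4[6, 6, 6] <- FALSE
  cl4 <- extract_significant_clusters(make_pmap(p4, tested4, g),
                                      connectivity = 26)
  expect_equal(nrow(cl4), 1)
  expect_equal(cl4$n_voxels[1], 3)

  empty <- extract_significant_clusters(make_pmap(array(1, g$shape),
                                                  tested, g))
  expect_equal(nrow(empty), 0)
})

test_that("cluster centroids take atlas labels from their location", {
  g <- default_grid()
  atlas <- build_region_atlas(g)
  p <- array(1, g$shape)
  falx_vox <- which(atlas$labels == 3L)
  p[falx_vox[1:5]] <- 1e-4
  pm <- make_pmap(p, array(TRUE, g$shape), g)
  cl <- extract_significant_clusters(pm, atlas, connectivity = 26)
  expect_true("falx" %in% cl$region)
})
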