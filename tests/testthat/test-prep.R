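test_that("slice normalization maps to [0,1] and inverts exactly", {
  coh <- tiny_cohort()
  vol <- coh$subjects[[1]]$scans[[1]]$volume
  st <- normalize_slices(vol, 3)
  expect_equal(dim(st$slices), c(16, 16, 3))
  for (j in 1:3) {
    expect_equal(min(st$slices[, , j]), 0)
    expect_equal(max(st$slices[, , j]), 1)
  }
  back <- denormalize_slices(st)
  orig <- vol[, , st$slice_index]
  expect_lt(max(abs(back - orig)) / diff(range(orig)), 1e-6)
  # full-depth extraction keeps every slice
  expect_equal(dim(normalize_slices(vol, 4)$slices)[3], 4)
  expect_error(normalize_slices(vol, 10), "depth")
  expect_error(normalize_slices(array(0.5, c(8, 8, 4)), 2),
               "degenerate scale")
})

test_that("equal-width age bins have the documented geometry", {
  ages <- seq(63, 87, length.out = 100)
  b <- build_age_bins(ages, 10)
  expect_equal(length(b$edges), 11)
  expect_equal(unique(round(diff(b$edges), 10)), 2.4)
  expect_equal(b$A, 10L)
  # every centre lies inside its bin
  for (i in 1:10) {
    expect_gte(b$centers[i], b$edges[i])
    expect_lte(b$centers[i], b$edges[i + 1])
  }
  expect_true(all(b$sigma > 0))
  # sigma scales with the width factor
  b2 <- build_age_bins(ages, 10, width_factor = 0.5)
  expect_equal(b2$sigma, 0.5 * b$delta)
  expect_error(build_age_bins(rep(70, 50), 5), "degenerate")
  expect_error(build_age_bins(ages, 1), "at least 2")
})

test_that("fuzzy membership is a Gaussian peaked at the bin centre", {
  b <- build_age_bins(seq(60, 80, by = 0.5), 4)
  for (i in 1:4) {
    expect_equal(membership(b, b$centers[i], i), 1)
    expect_equal(membership(b, b$centers[i] + b$sigma[i], i), exp(-1 / 2),
                 tolerance = 1e-12)
  }
  # monotone decreasing in |theta - m_i|, values in (0, 1]
  th <- b$centers[2] + seq(0, 10, by = 0.5)
  mu <- membership(b, th, 2)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu > 0 & mu <= 1))
  expect_error(membership(b, 70, 9), "out of range")
  b$sigma[1] <- 0
  expect_error(membership(b, 70, 1), "degenerate")
})

test_that("age-bin assignment ties to the lower bin", {
  b <- build_age_bins(seq(60, 80, by = 1), 4)
  expect_equal(assign_bin(b, b$edges[1]), 1L)
  expect_equal(assign_bin(b, b$edges[2]), 1L)   # edge belongs to lower bin
  expect_equal(assign_bin(b, b$edges[2] + 1e-9), 2L)
  expect_equal(assign_bin(b, b$edges[5]), 4L)
})

test_that("region sets are augmented by erosion and dilation", {
  atlas <- quadrant_atlas(8)
  rs <- build_region_set(atlas, n = 1, radii = 1L)
  expect_equal(rs$R, 12L)                       # 4 labels x (base + 2)
  expect_equal(length(rs$masks), rs$R)
  expect_equal(rs$sizes, vapply(rs$masks, sum, 0L))
  # morphology monotonicity: eroded <= base <= dilated per label
  for (lab in 1:4) {
    sz <- rs$sizes[grep(sprintf("^%d", lab), rs$labels)]
    base <- rs$sizes[rs$labels == sprintf("%d", lab)]
    expect_true(all(sz[grep("er", rs$labels[grep(sprintf("^%d", lab),
                                                 rs$labels)])] <= base))
    expect_true(all(sz[grep("di", rs$labels[grep(sprintf("^%d", lab),
                                                 rs$labels)])] >= base))
  }
  # a 1-voxel region's erosion is discarded, dilation kept
  one <- matrix(0L, 8, 8); one[4, 4] <- 1L
  rs1 <- build_region_set(one, radii = 1L)
  expect_equal(rs1$R, 2L)
  expect_false(any(grepl("er", rs1$labels)))
  expect_error(build_region_set(matrix(0L, 8, 8)), "no regions")
  # overlapping variants cover at least the labelled area
  expect_gte(sum(rs$sizes), sum(atlas > 0))
})

test_that("cohort preprocessing assembles consistent containers", {
  pp <- tiny_prepped()
  expect_s3_class(pp, "prepped_cohort")
  expect_equal(length(pp$stacks), nrow(pp$meta))
  expect_equal(pp$n_slices, 3L)
  expect_equal(length(pp$region_sets), 3L)
  expect_equal(pp$image_dim, c(16L, 16L))
  expect_equal(pp$binning$A, 3L)
})
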