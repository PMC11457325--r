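test_that("dice matches direct voxel counting and handles edge cases", {
  a <- random_blob(1)
  expect_equal(dice(a, a), 1.0)
  b <- volume_grid(!a$values, spacing = a$spacing) # complement: disjoint
  expect_equal(dice(a, b), 0.0)
  m1 <- array(FALSE, c(4, 4, 4)); m1[1:2, 1:2, 1:2] <- TRUE # 8 voxels
  m2 <- array(FALSE, c(4, 4, 4)); m2[2:3, 1:2, 1:2] <- TRUE # 8, overlap 4
  expect_equal(dice(volume_grid(m1), volume_grid(m2)), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  empty <- volume_grid(array(FALSE, dim(a$values)), spacing = a$spacing)
  expect_error(dice(empty, empty), "both masks empty")
  moved <- volume_grid(a$values, spacing = a$spacing,
                       origin = a$origin + 1)
  expect_error(dice(a, moved), "different grid frames")
})

test_that("relative volume is 100 * V_auto / V_clin", {
  a <- random_blob(2)
  expect_equal(relative_volume_pct(a, a), 100)
  m1 <- array(FALSE, c(10, 10, 10)); m1[1:39] <- TRUE
  m2 <- array(FALSE, c(10, 10, 10)); m2[1:50] <- TRUE
  expect_equal(relative_volume_pct(volume_grid(m1), volume_grid(m2)), 78)
  empty <- volume_grid(array(FALSE, c(10, 10, 10)))
  expect_equal(relative_volume_pct(empty, volume_grid(m2)), 0)
  expect_error(relative_volume_pct(volume_grid(m2), empty),
               "clinical mask empty")
})

test_that("boundary points are face-connected surface voxel centers", {
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(nrow(boundary_points(volume_grid(single))), 1)
  blk3 <- array(FALSE, c(5, 5, 5)); blk3[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(boundary_points(volume_grid(blk3))), 26)
  blk5 <- volume_grid(array(TRUE, c(5, 5, 5)))
  expect_equal(nrow(boundary_points(blk5)), 125 - 27)
})

test_that("pooled surface distances equal the all-pairs brute-force oracle
           on random anisotropic blobs", {
  for (seed in 1:12) {
    a <- random_blob(seed)
    b <- random_blob(seed + 100)
    fast <- sort(pooled_surface_distances(a, b))
    slow <- sort(brute_surface_distances(a, b))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("surface-distance basics: identity, symmetric pair, swap
           symmetry, translation invariance", {
  a <- random_blob(5)
  expect_true(all(pooled_surface_distances(a, a) == 0))
  m1 <- array(FALSE, c(9, 3, 3)); m1[2, 2, 2] <- TRUE
  m2 <- array(FALSE, c(9, 3, 3)); m2[7, 2, 2] <- TRUE
  g1 <- volume_grid(m1); g2 <- volume_grid(m2)
  expect_equal(pooled_surface_distances(g1, g2), c(5, 5))
  b <- random_blob(6)
  expect_equal(sort(pooled_surface_distances(a, b)),
               sort(pooled_surface_distances(b, a)))
  shift1 <- function(g) {
    m <- g$values
    m2 <- array(FALSE, dim(m))
    m2[-1, , ] <- m[-dim(m)[1], , ]
    volume_grid(m2, spacing = g$spacing, origin = g$origin)
  }
  a_in <- random_blob(7); b_in <- random_blob(8)
  a_in$values[dim(a_in$values)[1], , ] <- FALSE # keep shift lossless
  b_in$values[dim(b_in$values)[1], , ] <- FALSE
  d0 <- pooled_surface_distances(a_in, b_in)
  d1 <- pooled_surface_distances(shift1(a_in), shift1(b_in))
  expect_equal(sort(d0), sort(d1))
})

test_that("hd95 uses linear interpolation of order statistics and mda the
           arithmetic mean; both bounded by the maximum", {
  expect_equal(hd95(rep(0, 10)), 0)
  expect_equal(hd95(c(5, 5)), 5)
  expect_equal(hd95(1:5), 4.8)
  expect_equal(mda(c(5, 5)), 5)
  expect_equal(mda(c(0, 0, 3, 3)), 1.5)
  expect_error(hd95(numeric(0)), "empty")
  expect_error(mda(numeric(0)), "empty")
  for (seed in 1:5) {
    d <- abs(rnorm(50, 2))
    expect_lte(hd95(d), max(d))
    expect_lte(mda(d), max(d))
    expect_gte(hd95(d), median(d))
  }
})

test_that("two digitized spheres 5 mm apart reproduce the analytic
           lens-overlap Dice within 0.02", {
  r <- 20; d <- 5
  a <- sphere_mask(r, spacing = 1, dim = c(51, 51, 51),
                   center = c(-d / 2, 0, 0))
  b <- sphere_mask(r, spacing = 1, dim = c(51, 51, 51),
                   center = c(d / 2, 0, 0))
  vol <- 4 / 3 * pi * r^3
  dsc_analytic <- 2 * sphere_lens_volume(r, d) / (2 * vol)
  expect_lt(abs(dice(a, b) - dsc_analytic), 0.02)
})

test_that("eroding one voxel shell from a sphere lowers DSC and volume but
           keeps MDA within a voxel diagonal", {
  s <- sphere_mask(20, spacing = 1)
  inner <- volume_grid(s$values & !attr(boundary_points(s), "array"),
                       spacing = s$spacing, origin = s$origin)
  rec_d <- pooled_surface_distances(inner, s)
  expect_lt(dice(inner, s), 1)
  expect_lt(relative_volume_pct(inner, s), 100)
  expect_lte(mda(rec_d), sqrt(3))
  expect_gt(mda(rec_d), 0)
})

test_that("dilating a contained mask toward the reference cannot decrease
           Dice", {
  ref <- sphere_mask(12, spacing = 2)
  cur <- sphere_mask(6, spacing = 2, dim = dim(ref$values))
  prev <- dice(cur, ref)
  for (i in 1:3) {
    cur <- expand_margin(cur, 2)
    cur <- volume_grid(cur$values & ref$values, spacing = ref$spacing,
                       origin = ref$origin)
    now <- dice(cur, ref)
    expect_gte(now, prev)
    prev <- now
  }
})

test_that("geometric_record on identical arms gives the identity values", {
  s <- make_toy_session()
  rec <- geometric_record(s, "bladder")
  expect_equal(rec$dsc, 1)
  expect_equal(rec$relative_volume, 100)
  expect_equal(rec$hd95, 0)
  expect_equal(rec$mda, 0)
  expect_equal(rec$v_auto, rec$v_clin)
})
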