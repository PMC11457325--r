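frame_grid <- function(dim = c(6, 6, 6), spacing = c(2, 2, 2),
                       origin = c(0, 0, 0)) {
  volume_grid(array(FALSE, dim), spacing = spacing, origin = origin)
}

test_that("dose resampling: constant fields, node identity, linear
           midpoints and outside-grid zeros", {
  dose <- volume_grid(array(3, c(5, 5, 5)), spacing = c(2, 2, 2),
                      origin = c(0, 0, 0), kind = "dose")
  fr <- frame_grid(c(4, 4, 4), c(1.7, 1.3, 2.1), c(0.3, 0.4, 0.5))
  rs <- resample_dose(dose, fr)
  expect_equal(max(abs(rs$values - 3)), 0, tolerance = 1e-12)
  expect_equal(rs$n_outside, 0L)

  grad <- array(rep(seq(0, 8, by = 2), each = 1), c(5, 5, 5))
  for (k in 1:5) grad[, , k] <- matrix(rep(seq(0, 8, by = 2), 5), 5)
  dose2 <- volume_grid(grad, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                       kind = "dose")
  same <- frame_grid(c(5, 5, 5), c(2, 2, 2), c(0, 0, 0))
  expect_identical(resample_dose(dose2, same)$values, grad)
  # x = 3 mm sits midway between the nodes valued 2 and 4 Gy
  mid <- frame_grid(c(1, 1, 1), c(1, 1, 1), c(3, 4, 4))
  expect_equal(as.vector(resample_dose(dose2, mid)$values), 3)
  far <- frame_grid(c(2, 1, 1), c(1, 1, 1), c(30, 0, 0))
  rs_far <- resample_dose(dose2, far)
  expect_true(all(rs_far$values == 0))
  expect_equal(rs_far$n_outside, 2L)
})

test_that("coverage thresholds follow the two prescription levels on both
           evaluation scales", {
  pf <- prescription_config()
  expect_equal(coverage_threshold("CTV_elective", pf), 1.9)
  expect_equal(coverage_threshold("PTV_elective", pf), 1.9)
  expect_equal(coverage_threshold("CTV_boost", pf), 2.6125)
  expect_equal(coverage_threshold("GTV", pf), 2.6125)
  tot <- prescription_config(evaluation_scale = "total")
  expect_equal(coverage_threshold("CTV_boost", tot), 52.25)
  expect_equal(coverage_threshold("CTV_elective", tot), 38)
  expect_error(coverage_threshold("rectum", pf), "not a target")
})

test_that("V-at-threshold is inclusive and matches the analytic half-slab
           for a linear gradient", {
  dim <- c(10, 10, 10)
  mask <- volume_grid(array(TRUE, dim), spacing = c(2, 2, 2))
  expect_equal(v_at_threshold(mask, array(2.75, dim), 2.6125)$percent, 100)
  expect_equal(v_at_threshold(mask, array(2.0, dim), 2.6125)$percent, 0)
  expect_equal(v_at_threshold(mask, array(2.6125, dim), 2.6125)$percent,
               100) # inclusive at the threshold
  t <- 1.5
  grad <- array(rep(seq(0, 2 * t, length.out = dim[1]), times = 100), dim)
  half <- v_at_threshold(mask, grad, t)$percent
  expect_lt(abs(half - 50), 100 / dim[1] + 1e-9) # within one voxel layer
  empty <- volume_grid(array(FALSE, dim), spacing = c(2, 2, 2))
  expect_error(v_at_threshold(empty, grad, t), "empty")
})

test_that("spill outside the target is body minus target V95 and respects
           containment", {
  dim <- c(10, 10, 10)
  body <- volume_grid(array(TRUE, dim), spacing = c(2, 2, 2))
  tgt_m <- array(FALSE, dim); tgt_m[4:7, 4:7, 4:7] <- TRUE
  tgt <- volume_grid(tgt_m, spacing = c(2, 2, 2))
  vox <- voxel_volume_cm3(body)
  inside_only <- array(0, dim); inside_only[tgt_m] <- 3
  expect_equal(v95_out(body, tgt, inside_only, 2), 0)
  everywhere <- array(3, dim)
  expect_equal(v95_out(body, tgt, everywhere, 2),
               (1000 - 64) * vox)
  not_contained <- volume_grid(!tgt_m, spacing = c(2, 2, 2))
  expect_error(v95_out(tgt, not_contained, everywhere, 2),
               "not contained")
})

test_that("requirement flag is inclusive at 98% and identical dose arms
           give identical records", {
  dim <- c(14, 14, 14)
  # dose hot on an exact fraction of the CTV_boost voxels
  s <- make_toy_session(dim = dim)
  ctv <- s$contours_clin$masks$CTV_boost
  n <- sum(ctv$values)
  hot_a <- array(0, dim)
  idx <- which(ctv$values)
  n98 <- round(0.98 * n)
  hot_a[idx[seq_len(n98)]] <- 2.75
  s98 <- make_toy_session(dose_clin_gy = hot_a, dose_auto_gy = hot_a,
                          dim = dim)
  rec <- dosimetric_record(s98, "CTV_boost", "D_clin")
  expect_equal(rec$v95_percent, 100 * n98 / n)
  expect_true(rec$meets_requirement)
  hot_b <- hot_a
  hot_b[idx[n98]] <- 0 # one voxel below the 98% count
  s97 <- make_toy_session(dose_clin_gy = hot_b, dose_auto_gy = hot_b,
                          dim = dim)
  rec2 <- dosimetric_record(s97, "CTV_boost", "D_clin")
  expect_lt(rec2$v95_percent, 98)
  expect_false(rec2$meets_requirement)
  ra <- dosimetric_record(s98, "CTV_boost", "D_auto")
  expect_equal(rec[setdiff(names(rec), "arm")],
               ra[setdiff(names(ra), "arm")])
})

test_that("conservation and scale invariance hold for dosimetric records", {
  set.seed(9)
  dim <- c(14, 14, 14)
  noise <- array(runif(prod(dim), 0, 3), dim)
  s <- make_toy_session(dose_clin_gy = noise, dose_auto_gy = noise * 0.9,
                        dim = dim)
  for (role in target_roles()) {
    for (arm in c("D_clin", "D_auto")) {
      r <- dosimetric_record(s, role, arm)
      expect_equal(r$v95_body_abs, r$v95_abs + r$v95_out_abs)
      expect_gte(r$v95_out_abs, 0)
    }
  }
  # doubling dose and prescriptions together changes nothing
  s2 <- make_toy_session(dose_clin_gy = 2 * noise,
                         dose_auto_gy = 2 * noise * 0.9, dim = dim)
  p1 <- prescription_config()
  p2 <- prescription_config(elective_total = 80, boost_extra = 30)
  r1 <- dosimetric_record(s, "CTV_boost", "D_clin", p1)
  r2 <- dosimetric_record(s2, "CTV_boost", "D_clin", p2)
  expect_equal(r1$v95_percent, r2$v95_percent)
  expect_equal(r1$v95_out_abs, r2$v95_out_abs)
})

test_that("per-fraction and total scales agree when dose grids are exact
           multiples", {
  set.seed(10)
  dim <- c(14, 14, 14)
  fx_dose <- array(runif(prod(dim), 0, 3), dim)
  s_fx <- make_toy_session(dose_clin_gy = fx_dose, dose_auto_gy = fx_dose,
                           dim = dim)
  s_tot <- make_toy_session(dose_clin_gy = fx_dose * 20,
                            dose_auto_gy = fx_dose * 20, dim = dim)
  pf <- prescription_config()
  pt <- prescription_config(evaluation_scale = "total")
  for (role in c("CTV_boost", "CTV_elective")) {
    expect_equal(dosimetric_record(s_fx, role, "D_clin", pf)$v95_percent,
                 dosimetric_record(s_tot, role, "D_clin", pt)$v95_percent)
  }
})

test_that("cumulative DVH is non-increasing, starts at 100% and matches
           v_at_threshold on its dose grid", {
  set.seed(11)
  dim <- c(8, 8, 8)
  mask <- volume_grid(array(TRUE, dim), spacing = c(2, 2, 2))
  dose <- array(runif(prod(dim), 0, 3), dim)
  dvh <- cumulative_dvh(mask, dose, bin_width = 0.25)
  expect_equal(dvh$volume_pct[1], 100)
  expect_true(all(diff(dvh$volume_pct) <= 0))
  for (i in seq_len(nrow(dvh)))
    expect_equal(dvh$volume_pct[i],
                 v_at_threshold(mask, dose, dvh$dose_gy[i])$percent)
  u <- cumulative_dvh(mask, array(2, dim), bin_width = 0.5)
  expect_true(all(u$volume_pct[u$dose_gy <= 2] == 100))
  expect_true(all(u$volume_pct[u$dose_gy > 2] == 0))
})
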