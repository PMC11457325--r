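test_that("margin expansion matches the lattice-offset enumeration oracle
           for a single voxel", {
  m <- array(FALSE, c(21, 21, 21)); m[11, 11, 11] <- TRUE
  g <- volume_grid(m)
  ex <- expand_margin(g, 5)
  off <- expand.grid(x = -6:6, y = -6:6, z = -6:6)
  n_oracle <- sum(off$x^2 + off$y^2 + off$z^2 <= 25)
  expect_equal(sum(ex$values), n_oracle)
  expect_equal(n_oracle, 515)
  expect_identical(expand_margin(g, 0)$values, g$values)
})

test_that("margin expansion of a sphere approximates the enlarged sphere
           and respects anisotropic spacing", {
  # 0.5 mm voxels: coarser grids leave the surface-quantization bias of
  # center-to-center dilation above the continuum-convergence tolerance
  s10 <- sphere_mask(10, spacing = 0.5, dim = c(69, 69, 69))
  v15 <- 4 / 3 * pi * 15^3 / 1000
  expect_lt(abs(mask_volume_cm3(expand_margin(s10, 5)) - v15) / v15, 0.02)
  # anisotropic: a 4 mm margin at 2 mm z-spacing reaches 2 voxels in z
  m <- array(FALSE, c(11, 11, 11)); m[6, 6, 6] <- TRUE
  g <- volume_grid(m, spacing = c(1, 1, 2))
  ex <- expand_margin(g, 4)
  expect_true(ex$values[6, 6, 8])   # 4 mm away in z
  expect_false(ex$values[6, 6, 9])  # 6 mm away in z
  expect_true(ex$values[10, 6, 6])  # 4 mm away in x
})

test_that("reference anatomy hits target volumes, keeps the containment
           chain, and is seed-deterministic", {
  cfg <- tiny_phantom(seed = 21)
  for (pt in 1:2) {
    ref <- generate_reference_anatomy(cfg, pt)
    m <- ref$structures$masks
    vb <- mask_volume_cm3(m$bladder)
    expect_lt(abs(vb - ref$reference_volumes[["bladder"]]) /
                ref$reference_volumes[["bladder"]], 0.02)
    expect_true(all(m$GTV$values <= m$CTV_boost$values))
    expect_true(all(m$CTV_boost$values <= m$PTV_boost$values))
    expect_true(all(m$bladder$values <= m$CTV_elective$values))
    expect_true(all(m$PTV_elective$values <= m$body$values))
  }
  a <- generate_reference_anatomy(cfg, 1)
  b <- generate_reference_anatomy(cfg, 1)
  expect_identical(a$structures$masks$bladder$values,
                   b$structures$masks$bladder$values)
})

test_that("bladder filling grows the mask by rate x time within
           voxelization tolerance", {
  cfg <- tiny_phantom()
  bl <- generate_reference_anatomy(cfg, 1)$structures$masks$bladder
  v0 <- mask_volume_cm3(bl)
  filled <- simulate_filling(bl, rate_ml_min = 2, minutes = 10)
  expect_lt(abs(mask_volume_cm3(filled) - (v0 + 20)) / (v0 + 20), 0.02)
  expect_identical(simulate_filling(bl, 0, 30)$values, bl$values)
  big <- simulate_filling(bl, 4, 25)
  expect_lt(abs(mask_volume_cm3(big) - (v0 + 100)) / (v0 + 100), 0.02)
})

test_that("level-set perturbation is identity at zero amplitude, bounded
           in MDA, and monotone in amplitude", {
  cfg <- tiny_phantom()
  bl <- generate_reference_anatomy(cfg, 1)$structures$masks$bladder
  expect_identical(perturb_contour(bl, 0, seed = 5)$values, bl$values)
  p3 <- perturb_contour(bl, 3, seed = 5)
  d3 <- pooled_surface_distances(bl, p3)
  vox_diag <- sqrt(sum(bl$spacing^2))
  expect_gt(mda(d3), 0)
  expect_lte(mda(d3), 3 + vox_diag)
  dscs <- vapply(c(1, 3, 6), function(a)
    dice(bl, perturb_contour(bl, a, seed = 5)), numeric(1))
  expect_true(all(diff(dscs) < 0))
  expect_lt(mask_volume_cm3(perturb_contour(bl, 2, seed = 5,
                                            bias_mm = 3)),
            mask_volume_cm3(bl)) # positive bias shrinks
})

test_that("synthetic SIB dose meets both prescription levels inside their
           PTVs and halves at the half-distance", {
  cfg <- tiny_phantom()
  ss <- generate_reference_anatomy(cfg, 1)$structures
  pres <- prescription_config()
  dose <- synth_dose(ss$masks$PTV_boost, ss$masks$PTV_elective, pres,
                     d_half_mm = 5)
  expect_true(all(dose$values[ss$masks$PTV_boost$values] >= 2.75 - 1e-9))
  expect_true(all(dose$values[ss$masks$PTV_elective$values] >= 2 - 1e-9))
  v95 <- v_at_threshold(ss$masks$PTV_elective, dose$values,
                        coverage_threshold("PTV_elective", pres))
  expect_equal(v95$percent, 100)
  # a voxel d_half outside PTV_elective and far from the boost sees half
  # the elective prescription
  dm <- distance_map_mm(ss$masks$PTV_elective)
  db <- distance_map_mm(ss$masks$PTV_boost)
  sel <- abs(dm - 5) < 0.4 & db > 30
  expect_true(any(sel))
  expect_equal(mean(dose$values[sel]), 1.0, tolerance = 0.06)
})

test_that("generated sessions validate, are deterministic, and degenerate
           to identical arms at zero amplitude", {
  cfg <- tiny_phantom(seed = 31)
  g <- generate_session(cfg, 1, 2)
  expect_s3_class(g$session, "rt_session")
  expect_silent(validate_session(g$session))
  g2 <- generate_session(cfg, 1, 2)
  expect_identical(g$session$contours_auto$masks$CTV_boost$values,
                   g2$session$contours_auto$masks$CTV_boost$values)
  expect_identical(g$session$dose_auto$values, g2$session$dose_auto$values)
  expect_equal(g$truth, g2$truth)

  z <- generate_session(tiny_phantom(seed = 31,
                                     perturb_amplitude = c(0, 0)), 1, 2)
  expect_identical(z$session$contours_auto$masks$bladder$values,
                   z$session$contours_clin$masks$bladder$values)
  expect_identical(z$session$dose_auto$values, z$session$dose_clin$values)
})

test_that("cohorts have patients x fractions sessions and a matching
           ground-truth log", {
  cfg <- tiny_phantom(seed = 41, patients = 2, fractions = 3)
  co <- generate_cohort(cfg)
  expect_length(co$sessions, 6)
  expect_equal(nrow(co$truth), 6)
  expect_equal(unique(co$truth$patient_id), c("P01", "P02"))
  # bundle-writing path produces readable manifests
  dir <- file.path(tempdir(), "cohort-io")
  unlink(dir, recursive = TRUE)
  co2 <- generate_cohort(tiny_phantom(seed = 41, patients = 1,
                                      fractions = 2), out_dir = dir)
  expect_length(co2$manifests, 2)
  s <- read_session(co2$manifests[1])
  expect_s3_class(s, "rt_session")
})
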