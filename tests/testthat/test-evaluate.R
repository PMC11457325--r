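test_that("run_evaluation produces the full table skeleton", {
  res <- run_evaluation(tiny_phantom(seed = 51, patients = 2,
                                     fractions = 2))
  expect_setequal(unique(res$geometric$structure),
                  c("bladder", "rectum", "CTV_boost"))
  expect_equal(nrow(res$geometric), 4 * 3)
  expect_setequal(unique(res$dosimetric$structure), target_roles())
  expect_equal(nrow(res$dosimetric), 4 * 5 * 2)
  expect_equal(nrow(res$tests), 10) # 5 targets x 2 dosimetric metrics
  expect_named(res$summary$geometric$bladder,
               c("dsc", "relative_volume", "hd95", "mda"))
  expect_true(all(c("CTV_boost_by_bladder", "CTV_boost_by_rectum",
                    "CTV_elective_by_bladder", "CTV_elective_by_rectum")
                  %in% names(res$summary$stratification)))
  expect_named(res$summary$correction_frequencies_pct,
               c("bladder", "rectum", "GTV", "none"))
})

test_that("a zero-perturbation cohort reports perfect agreement and no
           arm differences", {
  res <- run_evaluation(tiny_phantom(seed = 52, patients = 2,
                                     fractions = 2,
                                     perturb_amplitude = c(0, 0)))
  expect_true(all(res$geometric$dsc == 1))
  expect_true(all(res$geometric$mda == 0))
  d <- res$dosimetric
  for (role in target_roles()) {
    v_clin <- d$v95_percent[d$structure == role & d$arm == "D_clin"]
    v_auto <- d$v95_percent[d$structure == role & d$arm == "D_auto"]
    expect_equal(v_auto, v_clin)
  }
  expect_true(all(res$sessions$meets_CTV_boost))
  expect_true(all(res$sessions$meets_CTV_elective))
  expect_true(all(res$tests$method == "degenerate"))
})

test_that("evaluation from bundles matches in-memory evaluation", {
  dir <- file.path(tempdir(), "eval-bundles")
  unlink(dir, recursive = TRUE)
  cfg <- tiny_phantom(seed = 53, patients = 1, fractions = 2)
  co <- generate_cohort(cfg, out_dir = dir)
  res_files <- run_evaluation(co$manifests)
  res_mem <- run_evaluation(generate_cohort(cfg)$sessions)
  expect_equal(res_files$geometric, res_mem$geometric, tolerance = 1e-6)
  expect_equal(res_files$dosimetric$v95_percent,
               res_mem$dosimetric$v95_percent, tolerance = 1e-6)
})

test_that("invalid sessions fail fast by default and are skipped only on
           request", {
  good <- make_toy_session()
  bad <- good
  bad$contours_clin$arm <- "auto"
  expect_error(run_evaluation(list(good, bad)), "mislabelled")
  expect_warning(res <- run_evaluation(list(good, bad),
                                       skip_invalid = TRUE),
                 "skipping")
  expect_equal(res$summary$n_sessions, 1L)
})

test_that("cli subcommands cover help, simulate, evaluate and report", {
  expect_equal(rtadapt_cli(character()), 0L)
  expect_equal(rtadapt_cli("--help"), 0L)
  expect_equal(rtadapt_cli("frobnicate"), 2L)
  expect_equal(rtadapt_cli(c("simulate", "--bogus")), 2L)
  expect_equal(rtadapt_cli(c("evaluate", "--in", "/no/such/dir",
                             "--out", tempdir())), 1L)

  base <- file.path(tempdir(), "cli-e2e")
  unlink(base, recursive = TRUE)
  sim_dir <- file.path(base, "cohort")
  out1 <- file.path(base, "report1")
  out2 <- file.path(base, "report2")
  expect_equal(rtadapt_cli(c("simulate", "--seed", "5", "--out", sim_dir,
                             "--patients", "1", "--fractions", "2")), 0L)
  expect_true(file.exists(file.path(sim_dir, "ground_truth.csv")))
  expect_equal(rtadapt_cli(c("evaluate", "--in", sim_dir, "--out", out1)),
               0L)
  expect_true(all(file.exists(file.path(out1,
                                        c("geometric.csv", "dosimetric.csv",
                                          "sessions.csv",
                                          "summary.json")))))
  expect_equal(rtadapt_cli(c("report", "--in", out1, "--out", out2)), 0L)
  expect_identical(readLines(file.path(out2, "geometric.csv")),
                   readLines(file.path(out1, "geometric.csv")))
})
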