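test_that("the simulator is exact when noiseless and deterministic under a seed", {
  x <- demo_doses()
  sim <- simulate_plate(demo_truth(), x, n_replicates = 3, noise_sd = 0, seed = 4)
  expected <- logistic4(sim$data$test, 0, 100, 1, 1.5)
  expect_equal(sim$data$value, expected, tolerance = 1e-12)

  a <- simulate_plate(demo_truth(), x, n_replicates = 4, noise_sd = 2,
                      outlier_frac = 0.05, seed = 99)
  b <- simulate_plate(demo_truth(), x, n_replicates = 4, noise_sd = 2,
                      outlier_frac = 0.05, seed = 99)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$outliers, b$truth$outliers)

  c_ <- simulate_plate(demo_truth(), x, n_replicates = 4, noise_sd = 2, seed = 100)
  expect_false(identical(a$data$value, c_$data$value))
})

test_that("injected outlier counts follow the requested fraction", {
  doses <- seq(1, 12) # 12 x 8 = 96 wells
  sim <- simulate_plate(list(intercept = 1, slope = 2), doses,
                        n_replicates = 8, noise_sd = 0.5, outlier_frac = 0.05,
                        model = "linear", seed = 2)
  expect_equal(nrow(sim$truth$outliers), floor(0.05 * 96))
  # displaced wells really are displaced by the recorded delta
  joined <- dplyr::inner_join(sim$data, sim$truth$outliers,
                              by = c("group", "well"))
  expect_true(all(abs(joined$delta) > 0))
})

test_that("linear-model simulation follows the line", {
  sim <- simulate_plate(list(intercept = 2, slope = -0.5), doses = 0:5,
                        n_replicates = 2, noise_sd = 0, model = "linear", seed = 1)
  expect_equal(sim$data$value, 2 - 0.5 * sim$data$test, tolerance = 1e-12)
})

test_that("simulated datasets survive the file round trip bit-exactly", {
  td <- withr::local_tempdir()
  sim <- simulate_plate(demo_truth(), demo_doses(), n_replicates = 4,
                        noise_sd = 2, outlier_frac = 0.05, n_groups = 2, seed = 12)
  write_inputs(sim$layout, sim$data,
               file.path(td, "layout.csv"), file.path(td, "data.csv"))
  rt <- read_inputs(file.path(td, "layout.csv"), file.path(td, "data.csv"))
  expect_identical(layout_matrix(rt$layout), layout_matrix(sim$layout))
  expect_equal(rt$data$value, sim$data$value, tolerance = 0)
  expect_equal(rt$data$group, sim$data$group)
})

test_that("score_run compares flags and parameters against the truth", {
  sim <- simulate_plate(demo_truth(), demo_doses(), n_replicates = 4,
                        noise_sd = 2, outlier_frac = 0.06, seed = 31)
  scr <- screen_outliers(sim$data)
  f <- fit_series(aggregate_replicates(scr, "sem"), "logistic4")
  sc <- score_run(sim$truth, outlier_report(scr), f,
                  expected_hash = sim$truth$spec_hash)
  expect_gte(sc$sensitivity, 0)
  expect_lte(sc$sensitivity, 1)
  expect_true(all(c("rel_err_ec50", "rel_err_hill") %in% names(sc)))

  # no outliers injected, none flagged: sensitivity undefined, FP 0
  clean <- simulate_plate(demo_truth(), demo_doses(), n_replicates = 4,
                          noise_sd = 0, seed = 1)
  sc0 <- score_run(clean$truth, outlier_report(screen_outliers(clean$data)), NULL)
  expect_true(is.na(sc0$sensitivity))
  expect_equal(sc0$false_positives, 0L)

  expect_error(score_run(sim$truth, NULL, NULL, expected_hash = "nope"),
               "spec mismatch")
})

test_that("errors vanish as noise vanishes", {
  sim <- simulate_plate(demo_truth(), demo_doses(), n_replicates = 4,
                        noise_sd = 0, seed = 8)
  f <- fit_series(aggregate_replicates(sim$data, "sem"), "logistic4")
  sc <- score_run(sim$truth, NULL, f)
  expect_lt(sc$rel_err_ec50, 1e-6)
  expect_lt(sc$rel_err_hill, 1e-6)
  expect_lt(sc$rel_err_top, 1e-6)
})

test_that("gross outliers are caught with high sensitivity and few false alarms", {
  # gross displacements (6 response ranges), 2%-of-range noise, 4 replicates
  hits <- vapply(1:60, function(seed) {
    sim <- simulate_plate(demo_truth(), demo_doses(), n_replicates = 4,
                          noise_sd = 2, outlier_frac = 0.04, seed = seed)
    scr <- screen_outliers(sim$data)
    sc <- score_run(sim$truth, outlier_report(scr), NULL)
    n_sets <- length(demo_doses())
    clean_sets <- n_sets - nrow(sim$truth$outliers)
    c(sens = sc$sensitivity, fp_rate = sc$false_positives / clean_sets)
  }, double(2))
  expect_gte(mean(hits["sens", ], na.rm = TRUE), 0.8)
  expect_lte(mean(hits["fp_rate", ]), 0.06)
})
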