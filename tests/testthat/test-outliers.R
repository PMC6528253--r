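test_that("the Grubbs statistic picks the farthermost value", {
  # frozen oracle: mean 15.2, s = sqrt(278.8/4), G = 14.8/s
  g <- grubbs_statistic(c(10, 11, 12, 13, 30))
  expect_equal(g$G, 1.7727411516681704, tolerance = 1e-12)
  expect_equal(g$index, 5L)

  g2 <- grubbs_statistic(c(10, 11, 12, 13, 14))
  expect_equal(g2$G, 1.2649110640673518, tolerance = 1e-12)

  expect_equal(grubbs_statistic(c(7, 7, 7, 7))$G, 0) # zero spread
  expect_error(grubbs_statistic(c(1, 2)), "fewer than 3")

  # symmetric tie in deviation: earliest value wins
  tie <- grubbs_statistic(c(-1, 0, 0, 1))
  expect_equal(tie$index, 1L)
})

test_that("the Grubbs statistic is invariant under positive affine maps", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    if (sd(x) == 0) next
    a <- runif(1, 0.1, 10)
    b <- runif(1, -5, 5)
    g0 <- grubbs_statistic(x)
    g1 <- grubbs_statistic(a * x + b)
    expect_equal(g1$G, g0$G, tolerance = 1e-10)
    expect_equal(g1$index, g0$index)
  }
})

test_that("critical values match the published two-sided 5% and 1% tables", {
  # printed to 3-4 decimals in standard Grubbs tables
  tab05 <- c(`3` = 1.155, `4` = 1.481, `5` = 1.715, `6` = 1.887, `7` = 2.020,
             `8` = 2.127, `9` = 2.215, `10` = 2.290, `15` = 2.548, `20` = 2.708,
             `30` = 2.908)
  tab01 <- c(`3` = 1.155, `4` = 1.496, `5` = 1.764, `6` = 1.973, `7` = 2.139,
             `8` = 2.274, `9` = 2.387, `10` = 2.482, `15` = 2.806, `20` = 3.001,
             `30` = 3.236)
  n <- as.integer(names(tab05))
  expect_equal(unname(grubbs_critical(n, 0.05)), unname(tab05), tolerance = 5e-4)
  expect_equal(unname(grubbs_critical(n, 0.01)), unname(tab01), tolerance = 5e-4)
})

test_that("critical values agree with a brute-force t-quantile inversion", {
  for (alpha in c(0.01, 0.05, 0.10)) {
    for (n in 3:30) {
      expect_equal(
        grubbs_critical(n, alpha),
        grubbs_critical_oracle(n, alpha),
        tolerance = 1e-9
      )
    }
  }
  expect_error(grubbs_critical(2, 0.05), "n >= 3")
  expect_error(grubbs_critical(5, 1.5), "alpha")
})

test_that("critical values grow with n and shrink as alpha grows", {
  for (alpha in c(0.01, 0.05, 0.10)) {
    crit <- grubbs_critical(3:30, alpha)
    expect_true(all(diff(crit) > 0))
  }
  expect_true(grubbs_critical(5, 0.30) < grubbs_critical(5, 0.05))
  expect_true(grubbs_critical(5, 0.001) > grubbs_critical(5, 0.05))
})

test_that("screening masks only significant farthermost values, one per set", {
  m <- rbind(c(10, 11, 12, 13, 30), c(10, 11, 12, 13, 14))
  scr <- screen_outliers(row_group(m), alpha = 0.05)
  rep <- outlier_report(scr)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$well, "A5")
  expect_equal(rep$value, 30)
  expect_true(rep$G > rep$G_crit)
  expect_true(scr$masked[scr$well == "A5"])
  expect_equal(sum(scr$masked), 1L)

  # two wild values in one set: single pass flags at most one
  wild <- matrix(c(10, 11, 12, 13, -500, 500), nrow = 1)
  rep2 <- outlier_report(screen_outliers(row_group(wild)))
  expect_lte(nrow(rep2), 1L)
})

test_that("small and constant sets are skipped with a reason", {
  m <- rbind(c(2, 9, NA, NA), c(7, 7, 7, 7))
  scr <- screen_outliers(row_group(m))
  expect_equal(nrow(outlier_report(scr)), 0L)
  sk <- attr(scr, "outlier_skipped")
  expect_setequal(sk$reason, c("n too small", "zero spread"))
})

test_that("manual masks are honoured by the screen", {
  g <- row_group(matrix(c(10, 11, 12, 13, 30), nrow = 1))
  pre <- mask_wells(g, "A5")
  scr <- screen_outliers(pre)
  # the remaining set {10,11,12,13} is clean: nothing new flagged
  expect_equal(nrow(outlier_report(scr)), 0L)
  expect_identical(scr$masked, pre$masked)
})

test_that("flagging decisions are affine-invariant at the set level", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(5)
    a <- runif(1, 0.5, 20)
    b <- runif(1, -10, 10)
    f0 <- outlier_report(screen_outliers(row_group(matrix(x, nrow = 1))))
    f1 <- outlier_report(screen_outliers(row_group(matrix(a * x + b, nrow = 1))))
    expect_equal(nrow(f0), nrow(f1))
    if (nrow(f0)) expect_equal(f0$well, f1$well)
  }
})

test_that("the null flagging rate stays at or below alpha", {
  set.seed(100)
  n_sets <- 2000L
  lay <- parse_layout(matrix(rep(seq_len(n_sets), each = 4), ncol = 4, byrow = TRUE))
  g <- bind_group(lay, "null", matrix(rnorm(4 * n_sets), ncol = 4))
  rate <- nrow(outlier_report(screen_outliers(g, 0.05))) / n_sets
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_sets))
})
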