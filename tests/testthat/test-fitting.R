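test_that("the 4PL curve has the midpoint, limit and monotonicity properties", {
  expect_equal(logistic4(2, bottom = 10, top = 90, ec50 = 2, hill = 3), 50) # midpoint
  expect_equal(logistic4(3, 0, 1, 1, 1), 0.25)
  expect_equal(logistic4(0, 5, 80, 1, 2), 80)   # hill > 0: x = 0 limit is top
  expect_equal(logistic4(0, 5, 80, 1, -2), 5)   # hill < 0: limit is bottom
  expect_error(logistic4(-1, 0, 1, 1, 1), "non-negative")

  x <- exp(seq(log(1e-3), log(1e3), length.out = 400))
  for (hill in c(-2, 0.5, 3)) {
    y <- logistic4(x, 0, 100, 1, hill)
    if (hill > 0) expect_true(all(diff(y) < 0)) else expect_true(all(diff(y) > 0))
  }
})

test_that("the linear model is what it says", {
  expect_equal(linear_eval(0, 1, 2), 1)
  expect_equal(linear_eval(c(1, 5), 3, 0), c(3, 3))
  x1 <- 2.5; x2 <- -4
  expect_equal(
    linear_eval(x1, 1, 2) + linear_eval(x2, 1, 2),
    linear_eval(x1 + x2, 1, 2) + 1
  )
})

test_that("4PL start guesses respect direction and range", {
  x <- demo_doses()
  dec <- tibble::tibble(test = x, mean = logistic4(x, 0, 100, 1, 1.5))
  gd <- guess_logistic4(dec)
  expect_equal(unname(gd["hill"]), 1)
  expect_gte(gd[["ec50"]], min(x))
  expect_lte(gd[["ec50"]], max(x))

  inc <- tibble::tibble(test = x, mean = logistic4(x, 0, 100, 1, -1.5))
  expect_equal(unname(guess_logistic4(inc)["hill"]), -1)

  flat <- tibble::tibble(test = x, mean = rep(5, length(x)))
  expect_warning(gf <- guess_logistic4(flat), "poorly determined")
  expect_equal(gf[["top"]], gf[["bottom"]])
  expect_equal(gf[["ec50"]], exp(mean(log(x))))

  expect_error(guess_logistic4(dec[1:3, ]), "under-determined")
})

test_that("linear fits reproduce the closed-form least-squares solution", {
  # exact interpolation through two points
  f <- fit_series(tibble::tibble(test = c(0, 1), mean = c(1, 3)), "linear")
  expect_equal(unname(f$params), c(1, 2), tolerance = 1e-12)
  expect_lt(f$ssr, 1e-20)

  # collinear points fit perfectly
  f3 <- fit_series(tibble::tibble(test = 1:3, mean = c(2, 4, 6)), "linear")
  expect_lt(f3$ssr, 1e-20)
  expect_equal(f3$r2, 1, tolerance = 1e-12)

  set.seed(17)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- sort(runif(n, 0, 60))
    y <- rnorm(n, 2 + 0.5 * x, 1)
    ours <- fit_series(tibble::tibble(test = x, mean = y), "linear")
    ols <- stats::lm(y ~ x)
    expect_equal(unname(ours$params), unname(coef(ols)), tolerance = 1e-9)
    expect_equal(unname(ours$param_se),
                 unname(summary(ols)$coefficients[, "Std. Error"]),
                 tolerance = 1e-6)
    expect_equal(ours$r2, summary(ols)$r.squared, tolerance = 1e-9)
  }
})

test_that("noiseless 4PL data are recovered to numerical precision", {
  x <- demo_doses()
  truth <- demo_truth()
  s <- tibble::tibble(test = x, mean = logistic4(x, 0, 100, 1, 1.5))
  f <- fit_series(s, "logistic4")
  expect_true(f$converged)
  for (nm in names(truth)) {
    denom <- max(abs(truth[[nm]]), 1)
    expect_lt(abs(f$params[[nm]] - truth[[nm]]) / denom, 1e-6)
  }
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("refitting behaves like manual restarts", {
  x <- demo_doses()
  s <- tibble::tibble(test = x, mean = logistic4(x, 0, 100, 1, 1.5))
  truth_start <- c(bottom = 0, top = 100, ec50 = 1, hill = 1.5)
  f0 <- fit_series(s, "logistic4", start = truth_start)
  expect_true(f0$converged)
  expect_lte(f0$n_iter, 2L)
  expect_equal(unname(f0$params), unname(truth_start), tolerance = 1e-9)

  # far-off ec50 start on clean data still reaches the same optimum
  far <- fit_series(s, "logistic4",
                    start = c(bottom = 0, top = 100, ec50 = 100, hill = 1.5))
  base <- fit_series(s, "logistic4")
  expect_equal(unname(far$params), unname(base$params), tolerance = 1e-4)

  # linear least squares is start-independent
  y <- c(1.2, 2.9, 5.4, 6.1)
  sl <- tibble::tibble(test = 1:4, mean = y)
  fa <- fit_series(sl, "linear", start = c(intercept = 0, slope = 0))
  fb <- fit_series(sl, "linear", start = c(intercept = 1e4, slope = -1e3))
  expect_equal(unname(fa$params), unname(fb$params), tolerance = 1e-8)
})

test_that("the optimiser never finishes above its start and beats a grid search", {
  set.seed(5)
  x <- c(0.05, 0.3, 1, 5, 30)
  y <- logistic4(x, 0, 100, 1.2, 1.3) + rnorm(5, 0, 2)
  s <- tibble::tibble(test = x, mean = y)
  start <- c(bottom = -10, top = 120, ec50 = 3, hill = 0.7)
  f <- fit_series(s, "logistic4", start = start)
  expect_true(f$converged)
  expect_lte(f$ssr, gof_stats(s, "logistic4", start)$ssr)

  # brute-force oracle: dense grid over a box around the truth
  grid <- expand.grid(
    bottom = seq(-10, 10, length.out = 9),
    top = seq(90, 110, length.out = 9),
    ec50 = exp(seq(log(0.4), log(3.6), length.out = 17)),
    hill = seq(0.6, 2.0, length.out = 15)
  )
  ssr_grid <- min(vapply(seq_len(nrow(grid)), function(i) {
    sum((y - logistic4(x, grid$bottom[i], grid$top[i], grid$ec50[i], grid$hill[i]))^2)
  }, double(1)))
  expect_lte(f$ssr, ssr_grid * (1 + 1e-3))
})

test_that("fits agree with an independent Levenberg-Marquardt implementation", {
  set.seed(23)
  x <- demo_doses()
  y <- logistic4(x, 5, 95, 0.8, 1.7) + rnorm(length(x), 0, 1.5)
  s <- tibble::tibble(test = x, mean = y)
  ours <- fit_series(s, "logistic4")
  ref <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + (x / ec50)^hill),
    start = as.list(ours$start_params),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14)
  )
  expect_equal(unname(ours$params), unname(coef(ref)[c("bottom", "top", "ec50", "hill")]),
               tolerance = 1e-5)
  expect_equal(ours$ssr, sum(residuals(ref)^2), tolerance = 1e-8)
})

test_that("parameter recovery holds under realistic replicate noise", {
  # 8 doses, 4 replicates, noise 2% of range; median over seeds
  x <- demo_doses()
  errs <- vapply(1:50, function(seed) {
    sim <- simulate_plate(demo_truth(), x, n_replicates = 4, noise_sd = 2, seed = seed)
    f <- fit_series(aggregate_replicates(sim$data, "sem"), "logistic4")
    c(abs(f$params[["ec50"]] - 1), abs(f$params[["hill"]] - 1.5) / 1.5)
  }, double(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("goodness of fit is consistent for fitted and manual parameters", {
  s <- tibble::tibble(test = 1:4, mean = c(1, 3, 2, 6))
  const <- c(intercept = mean(s$mean), slope = 0)
  g <- gof_stats(s, "linear", const)
  expect_equal(g$r2, 0, tolerance = 1e-12) # constant-at-mean model: TSS identity
  worse <- gof_stats(s, "linear", c(intercept = 100, slope = -3))
  expect_lt(worse$r2, 0)

  f <- fit_series(s, "linear")
  gf <- gof_stats(s, "linear", f$params)
  expect_equal(gf$ssr, f$ssr, tolerance = 1e-12)
  expect_equal(gf$rmse, f$rmse, tolerance = 1e-12)

  # dof < 1: rmse is undefined
  g2 <- gof_stats(tibble::tibble(test = c(1, 2), mean = c(1, 2)), "linear",
                  c(intercept = 0, slope = 1))
  expect_true(is.na(g2$rmse))
})

test_that("fit objects tidy, glance, predict and plot", {
  x <- demo_doses()
  s <- tibble::tibble(test = x, mean = logistic4(x, 0, 100, 1, 1.5))
  f <- fit_series(s, "logistic4")
  td <- tidy(f)
  expect_equal(td$term, c("bottom", "top", "ec50", "hill"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(f)
  expect_equal(gl$n_points, 8L)
  expect_true(gl$converged)
  expect_equal(predict(f, 1), 50, tolerance = 1e-6)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
  expect_output(print(f), "logistic4 model")
})

test_that("fully masked points are excluded from fitting", {
  x <- demo_doses()
  sim <- simulate_plate(demo_truth(), x, n_replicates = 3, noise_sd = 0, seed = 1)
  agg <- aggregate_replicates(mask_test(sim$data, 0.3), "sem")
  f <- fit_series(agg, "logistic4")
  expect_equal(f$n_points, length(x) - 1L)
  expect_lt(abs(f$params[["ec50"]] - 1), 1e-6)
})
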