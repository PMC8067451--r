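test_that("noise-free trajectories are recovered to 0.1%", {
  fit <- fit_sigmoid(clean_trajectory(340, 18, 3))
  expect_lt(abs(fit$a - 340) / 340, 1e-3)
  expect_lt(abs(fit$x0 - 18) / 18, 1e-3)
  expect_lt(abs(fit$b - 3) / 3, 1e-3)
  expect_gt(fit$r_squared, 0.9999)
  expect_true(fit$converged)
  expect_equal(fit$n_points, 7L)
})

test_that("recovered parameters converge to truth as noise shrinks", {
  err_by_cv <- vapply(c(0.05, 0.01, 0.001), function(cv) {
    errs <- vapply(1:10, function(s) {
      fit <- fit_sigmoid(noisy_trajectory(s, cv))
      abs(fit$a - 340) / 340
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(err_by_cv) < 0))
  # error scales roughly linearly with the noise cv
  expect_lt(err_by_cv[3], 0.005)
})

test_that("fit quality degrades monotonically with noise, on average", {
  mean_r2 <- vapply(c(0.02, 0.10), function(cv) {
    mean(vapply(1:30, function(s) {
      fit_sigmoid(noisy_trajectory(s, cv))$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_r2[1], mean_r2[2])
})

test_that("degenerate trajectories raise informative errors", {
  flat <- data.frame(day = imaging_days, pcs = rep(100, 7))
  expect_error(fit_sigmoid(flat), "no growth signal")
  zeros <- data.frame(day = imaging_days, pcs = rep(0, 7))
  expect_error(fit_sigmoid(zeros), "no growth signal")
  expect_error(fit_sigmoid(clean_trajectory(days = c(4, 7, 11))),
               "4 distinct")
  neg <- data.frame(day = imaging_days, pcs = c(-1, 2, 5, 9, 14, 18, 20))
  expect_error(fit_sigmoid(neg), "non-negative")
})

test_that("daily prediction evaluates the logistic on integer days", {
  fit <- fit_sigmoid(clean_trajectory(340, 18, 3))
  daily <- predict_daily(fit, 27)
  expect_equal(nrow(daily), 28L)
  expect_equal(daily$day, 0:27)
  expect_true(all(diff(daily$pcs) > 0))
  expect_true(all(daily$pcs < fit$a))
  # frozen values from direct evaluation
  truth <- predict_daily(c(a = 340, x0 = 18, b = 3), 27)
  expect_equal(truth$pcs[truth$day == 18], 170)
  expect_equal(truth$pcs[truth$day == 0], 0.8406918733, tolerance = 1e-9)

  expect_error(predict_daily(fit, 0), ">= 1")
  bad <- fit; bad$converged <- FALSE
  expect_error(predict_daily(bad, 27), "unconverged")
})

test_that("the logistic symmetry identity holds for fitted curves", {
  fit <- fit_sigmoid(noisy_trajectory(4, 0.05))
  for (t in c(0.5, 2, 5, 11)) {
    expect_equal(sigmoid(fit$x0 + t, fit$a, fit$x0, fit$b) +
                   sigmoid(fit$x0 - t, fit$a, fit$x0, fit$b),
                 fit$a)
  }
})

test_that("group-wise fitting returns one converged fit per unit", {
  exp <- generate_experiment(experiment_config(seed = 12))
  fits <- fit_sigmoids(exp$pcs_long)
  expect_equal(nrow(fits), 36L)
  expect_true(all(fits$converged))
  expect_true(all(fits$a > 0 & fits$b > 0))
  # tidy/glance accessors work on the unit fits
  td <- tidy(fits$fit[[1]])
  expect_setequal(td$term, c("a", "x0", "b"))
  expect_named(glance(fits$fit[[1]]),
               c("r.squared", "sigma", "nobs", "converged"))

  daily <- predict_daily_all(fits)
  expect_equal(nrow(daily), sum(ifelse(fits$species == "mizuna", 28, 29)))
  expect_error(predict_daily_all(dplyr::mutate(fits, species = "kale")),
               "harvest day")
})
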