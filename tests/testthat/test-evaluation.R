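test_that("Kaplan-Meier estimator matches the worked product-limit table", {
  d <- tibble::tibble(time = c(2, 4, 5, 6), event = c(1, 0, 1, 1))
  km <- km_estimator(d, t = 5)
  # S(5) = (1 - 1/4)(1 - 1/2) = 0.375, event probability 0.625
  expect_equal(km$event_prob, 0.625, tolerance = 1e-12)

  # before the first event the probability is 0
  expect_equal(km_estimator(d, t = 1)$event_prob, 0)

  # no censoring: 1 - S_KM equals the empirical CDF at every event time
  tt <- c(1.2, 2.5, 3.1, 4.8, 6.4)
  dd <- tibble::tibble(time = tt, event = 1)
  for (x in tt) {
    expect_equal(km_estimator(dd, t = x)$event_prob, mean(tt <= x),
                 tolerance = 1e-12)
  }
  expect_error(km_estimator(dd[0, ], t = 1), "No observations")
})

test_that("Harrell's C handles the perfect, chance and oracle cases", {
  # perfect inverse ordering of score and time, no censoring
  d <- tibble::tibble(time = c(1, 2, 3, 4, 5), event = 1,
                      score = c(5, 4, 3, 2, 1))
  expect_equal(harrell_c(d)$c_statistic, 1)
  # constant score: exactly 0.5
  d$score <- 2
  expect_equal(harrell_c(d)$c_statistic, 0.5)

  # brute-force pair-enumeration oracle on censored data (incl. score ties)
  for (seed in 1:5) {
    dd <- withr::with_seed(seed, tibble::tibble(
      time = rexp(300, 0.2) + 0.01,
      event = rbinom(300, 1, 0.7),
      score = round(rnorm(300), 1)
    ))
    expect_equal(harrell_c(dd)$c_statistic,
                 bf_concordance(dd$time, dd$event, dd$score),
                 tolerance = 1e-12)
  }

  dd1 <- withr::with_seed(31, tibble::tibble(
    time = rexp(200, 0.2), event = rbinom(200, 1, 0.6), score = rnorm(200)
  ))
  c1 <- harrell_c(dd1)$c_statistic
  # complement symmetry on tie-free data
  dd2 <- dd1
  dd2$score <- -dd2$score
  expect_equal(harrell_c(dd2)$c_statistic, 1 - c1, tolerance = 1e-12)
  # invariance to strictly increasing transformations of the score
  dd3 <- dd1
  dd3$score <- exp(3 * dd3$score) + 2
  expect_equal(harrell_c(dd3)$c_statistic, c1, tolerance = 1e-12)
  # CI contains the estimate
  res <- harrell_c(dd1)
  expect_gte(res$c_statistic, res$conf_low)
  expect_lte(res$c_statistic, res$conf_high)
})

test_that("calibration by tenths partitions the cohort and aggregates exactly", {
  n <- 2000
  dat <- withr::with_seed(41, {
    p <- runif(n, 0.001, 0.2)
    surv <- simulate_event_times(log(p / mean(p)), 1, 30, 7, 0, seed = 42)
    tibble::tibble(predicted = p, time = surv$time, event = surv$event)
  })
  tab <- calibration_by_tenths(dat, horizon = 5)
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$n), n)
  expect_true(max(tab$n) - min(tab$n) <= 1)
  expect_true(all(diff(tab$mean_predicted) > 0))
  # weighted group means reproduce the overall mean predicted risk
  expect_equal(sum(tab$n * tab$mean_predicted) / n, mean(dat$predicted),
               tolerance = 1e-12)

  # degenerate ranking: equal predictions grouped by stable input order
  same <- dat
  same$predicted <- 0.05
  tab0 <- calibration_by_tenths(same, horizon = 5)
  expect_true(all(abs(tab0$mean_predicted - 0.05) < 1e-15))
  expect_equal(sum(tab0$n), n)

  expect_error(calibration_by_tenths(dat[1:5, ], horizon = 5), "at least")
  bad <- dat
  bad$predicted[1] <- 1.4
  expect_error(calibration_by_tenths(bad, horizon = 5), "\\[0, 1\\]")
})

test_that("over-predicted risks fall above the observed curve in the top tenth", {
  n <- 40000
  lp <- withr::with_seed(43, rnorm(n, 0, 0.6))
  surv <- simulate_event_times(lp, 1.2, 25, 7, 0, seed = 44)
  h5 <- (5 / 25)^1.2
  truth <- 1 - exp(-h5 * exp(lp))
  dat <- tibble::tibble(time = surv$time, event = surv$event)
  # doubling the log HR inflates predictions for extreme participants
  dat$predicted <- 1 - exp(-h5 * exp(2 * lp))
  tab <- calibration_by_tenths(dat, horizon = 5)
  expect_gt(tab$mean_predicted[10], tab$conf_high[10])  # observed < predicted
  # whereas the true predictions calibrate in the top tenth
  dat$predicted <- truth
  tab_ok <- calibration_by_tenths(dat, horizon = 5)
  expect_gt(tab_ok$mean_predicted[10], tab_ok$conf_low[10])
  expect_lt(tab_ok$mean_predicted[10], tab_ok$conf_high[10])
})

test_that("relative-risk calibration curves read the slope of the predictor", {
  n <- 30000
  lp <- withr::with_seed(45, rnorm(n, 0, 0.5))
  surv <- simulate_event_times(lp, 1.2, 30, 7, 0, seed = 46)
  d <- tibble::tibble(pred_log_hr = lp, time = surv$time, event = surv$event)
  curve <- rr_calibration(d, df_curve = 2)
  # well-specified: the identity lies within the pointwise CI across the grid
  inside <- curve$pred_hr >= curve$conf_low & curve$pred_hr <= curve$conf_high
  expect_gt(mean(inside), 0.9)
  # the reference point has estimated HR 1 by construction
  ref_idx <- which.min(abs(curve$pred_log_hr))
  expect_lt(abs(curve$est_log_hr[ref_idx]), 0.05)

  # inflated predictions: estimated HR falls below the predicted HR at the top
  d2 <- d
  d2$pred_log_hr <- 1.6 * lp
  curve2 <- rr_calibration(d2, df_curve = 2)
  top <- nrow(curve2)
  expect_lt(curve2$est_hr[top], curve2$pred_hr[top])

  # constant predictor is rejected
  d3 <- d
  d3$pred_log_hr <- 0.3
  expect_error(rr_calibration(d3), "variation")
})

test_that("autoplot methods return ggplot objects", {
  d <- tibble::tibble(risk_base = runif(50, 0, 0.05),
                      risk_augmented = runif(50, 0, 0.05))
  expect_s3_class(ggplot2::autoplot(delta_risk_summary(d)), "ggplot")
  dat <- withr::with_seed(47, tibble::tibble(
    predicted = runif(100, 0, 0.3),
    time = rexp(100, 0.1) + 0.01, event = rbinom(100, 1, 0.5)
  ))
  expect_s3_class(ggplot2::autoplot(calibration_by_tenths(dat, horizon = 5)),
                  "ggplot")
})
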