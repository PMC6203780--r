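# A small well-specified cohort: hazard driven by a known log HR, so the
# base model's predictions are correct up to baseline calibration.
make_recal_cohort <- function(n, seed, lp_sd = 0.6, scale = 40,
                              shape = 1.2, inflate = 1, horizon_admin = 7) {
  lp <- withr::with_seed(seed, rnorm(n, 0, lp_sd))
  surv <- simulate_event_times(lp, shape, scale, horizon_admin, 0.005,
                               seed = seed + 1)
  tibble::tibble(base_log_hr = inflate * lp, lp_true = lp,
                 time = surv$time, event = surv$event)
}

test_that("offset-mode initial calibration reproduces the cohort incidence", {
  d <- make_recal_cohort(20000, seed = 201)
  init <- initial_calibration(d, df = 2, horizon = 5)
  km <- km_estimator(d, t = 5)
  expect_gt(mean(init$risks$risk), km$conf_low)
  expect_lt(mean(init$risks$risk), km$conf_high)

  # degenerate predictor: everyone gets the same risk
  d0 <- d
  d0$base_log_hr <- 0
  init0 <- initial_calibration(d0, df = 2, horizon = 5)
  expect_equal(length(unique(init0$risks$risk)), 1)

  # doubling the baseline hazard: recalibrated risks track the new incidence
  d_hi <- make_recal_cohort(20000, seed = 202, scale = 40 / 2^(1 / 1.2))
  init_hi <- initial_calibration(d_hi, df = 2, horizon = 5)
  km_hi <- km_estimator(d_hi, t = 5)
  expect_gt(mean(init_hi$risks$risk), km_hi$conf_low)
  expect_lt(mean(init_hi$risks$risk), km_hi$conf_high)
  expect_gt(mean(init_hi$risks$risk), 1.5 * mean(init$risks$risk))
})

test_that("free-slope refit never decreases the offset-mode log-likelihood", {
  d <- make_recal_cohort(4000, seed = 203)
  kn <- rcs_knots(log(d$time[d$event == 1]), df = 2)
  off <- initial_calibration(d, df = 2, knots = kn)
  free <- fit_fpsm(d, covariates = "base_log_hr", df = 2, knots = kn)
  expect_gte(free$loglik, off$fit$loglik - 1e-8)
})

test_that("recalibration recovers the GRS slope and handles degenerate GRS", {
  n <- 20000
  base_lp <- withr::with_seed(204, rnorm(n, 0, 0.5))
  grs_true <- withr::with_seed(205, rnorm(n, 0, 0.5))
  surv <- simulate_event_times(base_lp + grs_true, 1.2, 35, 7, 0.005,
                               seed = 206)
  d <- tibble::tibble(base_log_hr = base_lp, grs = grs_true,
                      time = surv$time, event = surv$event)
  rec <- recalibrate_with_grs(d, df = 2, horizon = 5)
  sl <- rec$slopes[rec$slopes$term == "grs", ]
  expect_lt(abs(sl$estimate - 1), 3 * sl$std_error)

  # GRS identically zero: augmented risks equal base risks
  dz <- d
  dz$grs <- 0
  recz <- suppressMessages(recalibrate_with_grs(dz, df = 2, horizon = 5))
  expect_lt(max(abs(recz$risks$risk_base - recz$risks$risk_augmented)), 1e-10)
  expect_true(is.na(recz$slopes$estimate[recz$slopes$term == "grs"]))

  # collinear covariates are rejected
  dc <- d
  dc$grs <- dc$base_log_hr * 2 + 1e-9
  expect_error(recalibrate_with_grs(dc), "collinear")

  # tidy/glance accessors
  expect_identical(tidy(rec), rec$slopes)
  expect_equal(glance(rec)$n, n)
})

test_that("delta_risk_summary matches hand enumeration and its tie rule", {
  d <- tibble::tibble(risk_base = c(0.001, 0.02),
                      risk_augmented = c(0.0045, 0.021))
  out <- delta_risk_summary(d, threshold = 0.003, high_risk_cutoff = 0.01)
  expect_equal(out$prop_exceeding, 0.5)
  expect_equal(out$prop_exceeding_high_risk, 0)
  expect_equal(out$n_high_risk, 1)

  # identical vectors: all proportions zero
  same <- tibble::tibble(risk_base = c(0.01, 0.02), risk_augmented = c(0.01, 0.02))
  out0 <- delta_risk_summary(same)
  expect_equal(out0$prop_exceeding, 0)
  expect_equal(out0$prop_exceeding_high_risk, 0)

  # threshold 0 counts any nonzero change
  outz <- delta_risk_summary(d, threshold = 0, high_risk_cutoff = 0.01)
  expect_equal(outz$prop_exceeding, 1)

  # exact tie counts as exceeding
  tie <- tibble::tibble(risk_base = 0.005, risk_augmented = 0.008)
  expect_equal(delta_risk_summary(tie, threshold = 0.003)$prop_exceeding, 1)

  # proportion non-increasing in the threshold
  dd <- withr::with_seed(207, tibble::tibble(
    risk_base = runif(500, 0, 0.05),
    risk_augmented = runif(500, 0, 0.05)
  ))
  props <- vapply(c(0.001, 0.003, 0.01, 0.03),
                  function(th) delta_risk_summary(dd, threshold = th)$prop_exceeding,
                  numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("a truly null GRS yields slope near zero and vanishing deltas", {
  n <- 20000
  base_lp <- withr::with_seed(208, rnorm(n, 0, 0.5))
  grs_null <- withr::with_seed(209, rnorm(n, 0, 0.5))  # no effect on hazard
  surv <- simulate_event_times(base_lp, 1.2, 35, 7, 0.005, seed = 210)
  d <- tibble::tibble(base_log_hr = base_lp, grs = grs_null,
                      time = surv$time, event = surv$event)
  rec <- recalibrate_with_grs(d, df = 2, horizon = 5)
  sl <- rec$slopes[rec$slopes$term == "grs", ]
  expect_lt(abs(sl$estimate), 3 * sl$std_error)
  expect_lt(mean(abs(rec$risks$delta)), 0.005)
})
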