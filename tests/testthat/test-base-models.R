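simple_rates <- function(rate = 0.001) {
  age_rate_table(tibble::tibble(
    age_lower = c(40, 50, 60), age_upper = c(50, 60, 75),
    rate = rep(rate, 3)
  ))
}
simple_rr <- function() {
  family_history_rr(tibble::tibble(fh_category = c("0", "1", "2"),
                                   rr = c(1, 2, 4)))
}

test_that("Taylor-style absolute risk matches the closed form", {
  spec <- taylor_model_spec(simple_rates(0.001), simple_rr())
  d <- tibble::tibble(age = 55, fh_category = "1")
  out <- taylor_absolute_risk(d, spec, horizon = 5)
  # constant rate 0.001/yr, RR = 2, 5 years: 1 - exp(-0.01)
  expect_equal(out$risk, 1 - exp(-0.01), tolerance = 1e-12)
  expect_equal(out$log_rel_hazard, log(2))

  # zero rates give zero risk
  spec0 <- taylor_model_spec(simple_rates(0), simple_rr())
  expect_equal(taylor_absolute_risk(d, spec0, horizon = 5)$risk, 0)

  # reference category reduces to the baseline cumulative risk
  d0 <- tibble::tibble(age = 55, fh_category = "0")
  expect_equal(taylor_absolute_risk(d0, spec, horizon = 5)$risk,
               1 - exp(-0.005), tolerance = 1e-12)

  # uncovered ages are named
  expect_error(taylor_absolute_risk(tibble::tibble(age = 72, fh_category = "0"),
                                    spec, horizon = 5), "covers")
  expect_error(
    taylor_absolute_risk(tibble::tibble(age = 55, fh_category = "9"), spec, 5),
    "9"
  )
})

test_that("band-overlap integration is exact for piecewise-constant rates", {
  rates <- age_rate_table(tibble::tibble(
    age_lower = c(40, 45, 55, 62), age_upper = c(45, 55, 62, 80),
    rate = c(0.001, 0.003, 0.002, 0.006)
  ))
  spec <- taylor_model_spec(rates, simple_rr())
  rate_fun <- function(a) {
    out <- numeric(length(a))
    for (i in seq_len(nrow(rates))) {
      sel <- a >= rates$age_lower[i] & a < rates$age_upper[i]
      out[sel] <- rates$rate[i]
    }
    out
  }
  for (age in c(41.3, 44.9, 53.27, 60)) {
    lam <- -log(1 - taylor_absolute_risk(
      tibble::tibble(age = age, fh_category = "0"), spec, horizon = 7
    )$risk)
    quad <- stats::integrate(rate_fun, age, age + 7, subdivisions = 2000L,
                             rel.tol = 1e-12)$value
    expect_lt(abs(lam - quad), 1e-10)
  }
})

test_that("Taylor risk is monotone and close to the cumulative hazard when small", {
  spec <- taylor_model_spec(simple_rates(0.001), simple_rr())
  d <- tibble::tibble(age = 45, fh_category = "2")
  risks <- vapply(c(1, 3, 5, 10), function(h) {
    taylor_absolute_risk(d, spec, horizon = h)$risk
  }, numeric(1))
  expect_true(all(diff(risks) > 0))

  r_by_rr <- vapply(c("0", "1", "2"), function(fh) {
    taylor_absolute_risk(tibble::tibble(age = 45, fh_category = fh), spec, 5)$risk
  }, numeric(1))
  expect_true(all(diff(r_by_rr) > 0))

  # small-hazard expansion: |(1 - exp(-L)) - L| <= L^2 / 2
  lam <- 4 * 0.001 * 5
  expect_lt(abs(taylor_absolute_risk(d, spec, 5)$risk - lam), lam^2 / 2)
})

wells_like_spec <- function() {
  cox_model_spec(
    tibble::tibble(
      term = c("age", "diabetes", "bmi", "oestrogen"),
      type = c("linear", "linear", "linear", "linear"),
      coefficient = c(0.05, 0.3, 0.02, -0.1),
      reference = c(55, 0, 27, 0),
      sex = c("all", "all", "all", "female")
    ),
    baseline_survival = 0.99, horizon = 5
  )
}

test_that("Cox linear predictor handles references, units and sex masks", {
  spec <- wells_like_spec()
  ref <- tibble::tibble(age = 55, diabetes = 0, bmi = 27, oestrogen = 0,
                        sex = "female")
  expect_equal(cox_linear_predictor(ref, spec), 0)

  # single covariate 2 units above reference with beta 0.3
  one <- tibble::tibble(age = 55, diabetes = 2, bmi = 27, oestrogen = 0,
                        sex = "female")
  expect_equal(cox_linear_predictor(one, spec), 0.6)

  # mask semantics against an explicit per-covariate loop oracle
  d <- withr::with_seed(4, tibble::tibble(
    age = runif(30, 40, 69), diabetes = rbinom(30, 1, 0.2),
    bmi = rnorm(30, 27, 4), oestrogen = rbinom(30, 1, 0.5),
    sex = sample(c("female", "male"), 30, replace = TRUE)
  ))
  eta <- cox_linear_predictor(d, spec)
  oracle <- vapply(seq_len(30), function(i) {
    tot <- 0
    for (k in seq_len(nrow(spec$terms))) {
      tm <- spec$terms[k, ]
      if (tm$sex != "all" && d$sex[i] != tm$sex) next
      tot <- tot + tm$coefficient * (d[[tm$term]][i] - tm$reference)
    }
    tot
  }, numeric(1))
  expect_equal(eta, oracle)
  # any oestrogen value contributes 0 for men
  men <- d[d$sex == "male", ]
  men2 <- men
  men2$oestrogen <- men2$oestrogen + 5
  expect_equal(cox_linear_predictor(men, spec), cox_linear_predictor(men2, spec))

  d_na <- ref
  d_na$bmi <- NA
  expect_error(cox_linear_predictor(d_na, spec), "bmi")
  expect_error(cox_linear_predictor(ref[, -1], spec), "age")
})

test_that("Cox absolute risk follows 1 - S0^exp(eta)", {
  spec <- wells_like_spec()
  expect_equal(cox_absolute_risk(0, spec), 1 - 0.99)
  expect_equal(cox_absolute_risk(log(2), spec), 1 - 0.99^2, tolerance = 1e-12)
  spec1 <- cox_model_spec(spec$terms, baseline_survival = 1, horizon = 5)
  expect_equal(cox_absolute_risk(c(-2, 0, 3), spec1), rep(0, 3))
  # strictly increasing in eta when S0 < 1
  r <- cox_absolute_risk(c(-1, 0, 1, 2), spec)
  expect_true(all(diff(r) > 0))
  expect_error(cox_absolute_risk(0, spec, horizon = 10), "horizon")
})

test_that("remove_covariate_effect zeroes terms without touching the original", {
  spec <- wells_like_spec()
  expect_identical(remove_covariate_effect(spec, character()), spec)
  no_age <- remove_covariate_effect(spec, "age")
  expect_equal(no_age$terms$coefficient[no_age$terms$term == "age"], 0)
  expect_equal(spec$terms$coefficient[spec$terms$term == "age"], 0.05)
  a <- tibble::tibble(age = 45, diabetes = 1, bmi = 30, oestrogen = 0, sex = "male")
  b <- a
  b$age <- 65
  expect_equal(cox_linear_predictor(a, no_age), cox_linear_predictor(b, no_age))
  expect_error(remove_covariate_effect(spec, "nope"), "nope")

  # Taylor model with age removed scores by family history only
  tspec <- taylor_model_spec(simple_rates(0.002), simple_rr())
  tno <- remove_covariate_effect(tspec, "age")
  d <- tibble::tibble(age = c(42, 68), fh_category = c("1", "1"))
  out <- taylor_absolute_risk(d, tno, horizon = 5)
  expect_equal(out$risk[1], out$risk[2])
  expect_equal(out$log_rel_hazard, rep(log(2), 2))
  # original spec still age-dependent
  out_age <- taylor_absolute_risk(d, tspec, horizon = 5)
  expect_equal(out_age$risk[1], out_age$risk[2])  # constant rates here
})
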