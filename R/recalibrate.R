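#' Initial calibration of a published model to a target cohort
#'
#' Calibration-in-the-large: the published model's log relative hazard
#' enters a flexible parametric survival model as an offset (coefficient
#' fixed at 1) and only the baseline spline is re-estimated against the
#' target cohort. The relative ordering of participants is untouched; only
#' the baseline cumulative hazard adapts to the cohort's incidence.
#'
#' @param data Data frame with the follow-up columns and the base model's
#'   log relative hazard.
#' @param base_log_hr Column name of the base-model log relative hazard.
#' @param time,event Follow-up column names.
#' @param df Spline degrees of freedom (default 2).
#' @param horizon Horizon in years at which `risk` is predicted (default 5).
#' @param knots Optional `"rcs_knots"` object.
#'
#' @return A list of class `"initial_calibration"`: `fit` (the offset-mode
#'   `"fpsm"`) and `risks` (tibble `risk` at the horizon, one row per
#'   participant).
#' @export
initial_calibration <- function(data, base_log_hr = "base_log_hr",
                                time = "time", event = "event", df = 2L,
                                horizon = 5, knots = NULL) {
  lhr <- as.numeric(assert_column(data, base_log_hr))
  if (!all(is.finite(lhr))) abort("Base log hazard ratios must be finite.")
  fit <- fit_fpsm(data, time = time, event = event, covariates = character(),
                  df = df, knots = knots, offset = base_log_hr)
  pred <- predict_survival(fit, newdata = data, t = horizon, offset = base_log_hr)
  structure(list(fit = fit, risks = tibble::tibble(risk = pred$risk),
                 horizon = horizon),
            class = "initial_calibration")
}

#' Recalibrate a base model with and without the genetic risk score
#'
#' Fits two flexible parametric survival models sharing one knot
#' specification: the base model's predicted log hazard ratio alone, and
#' together with the (mean-centred) GRS as a separate covariate. The
#' estimated coefficients are calibration slopes: 1 means the predictor's
#' relative risks are correct in this cohort, below 1 that they are too
#' extreme — the signature of winner's-curse-inflated GRS weights, where
#' the slope shrinks towards 1/kappa for inflation factor kappa. Five-year
#' absolute risks are predicted from both fits.
#'
#' @param data Data frame with follow-up columns, the base-model log hazard
#'   ratio and the GRS.
#' @param base_log_hr,grs Column names.
#' @param time,event Follow-up column names.
#' @param df Spline degrees of freedom (default 2).
#' @param horizon Risk horizon in years (default 5).
#'
#' @return An object of class `"grs_recalibration"`: `fit_base`,
#'   `fit_augmented` (`"fpsm"` objects), `risks` (tibble `risk_base`,
#'   `risk_augmented`, `delta`), and `slopes` (tibble `model`, `term`,
#'   `estimate`, `std_error`, `conf_low`, `conf_high`).
#' @export
recalibrate_with_grs <- function(data, base_log_hr = "base_log_hr",
                                 grs = "grs", time = "time", event = "event",
                                 df = 2L, horizon = 5) {
  lhr <- as.numeric(assert_column(data, base_log_hr))
  g <- as.numeric(assert_column(data, grs))
  if (!all(is.finite(lhr)) || !all(is.finite(g))) {
    abort("Base log hazard ratios and GRS must be finite.")
  }
  grs_degenerate <- stats::sd(g) == 0
  if (!grs_degenerate && stats::sd(lhr) > 0 &&
      abs(cor(lhr, g)) > 0.999) {
    abort("Base log HR and GRS are collinear (|corr| > 0.999).")
  }

  t_obs <- assert_column(data, time)
  d <- assert_column(data, event)
  knots <- rcs_knots(log(t_obs[d == 1]), df = df)

  fit_base <- fit_fpsm(data, time = time, event = event,
                       covariates = base_log_hr, df = df, knots = knots)
  if (grs_degenerate) {
    inform("GRS has zero variance; augmented model equals the base model.")
    fit_aug <- fit_base
  } else {
    fit_aug <- fit_fpsm(data, time = time, event = event,
                        covariates = c(base_log_hr, grs), df = df,
                        knots = knots)
  }

  risk_base <- predict_survival(fit_base, newdata = data, t = horizon)$risk
  risk_aug <- predict_survival(fit_aug, newdata = data, t = horizon)$risk

  slope_row <- function(fit, model, term) {
    td <- tidy(fit)
    td <- td[td$term == term, ]
    tibble::tibble(model = model, term = term, estimate = td$estimate,
                   std_error = td$std_error, conf_low = td$conf_low,
                   conf_high = td$conf_high)
  }
  slopes <- dplyr::bind_rows(
    slope_row(fit_base, "base", base_log_hr),
    slope_row(fit_aug, "augmented", base_log_hr),
    if (grs_degenerate) {
      tibble::tibble(model = "augmented", term = grs, estimate = NA_real_,
                     std_error = NA_real_, conf_low = NA_real_,
                     conf_high = NA_real_)
    } else {
      slope_row(fit_aug, "augmented", grs)
    }
  )

  structure(
    list(
      fit_base = fit_base, fit_augmented = fit_aug,
      risks = tibble::tibble(risk_base = risk_base,
                             risk_augmented = risk_aug,
                             delta = risk_aug - risk_base),
      slopes = slopes, horizon = horizon
    ),
    class = "grs_recalibration"
  )
}

#' @export
print.grs_recalibration <- function(x, ...) {
  cat(sprintf("<grs_recalibration> n = %d, horizon = %g years\n",
              nrow(x$risks), x$horizon))
  print(x$slopes)
  invisible(x)
}

#' @rdname recalibrate_with_grs
#' @param x A `"grs_recalibration"` object.
#' @param ... Unused.
#' @method tidy grs_recalibration
#' @export
tidy.grs_recalibration <- function(x, ...) x$slopes

#' @rdname recalibrate_with_grs
#' @method glance grs_recalibration
#' @export
glance.grs_recalibration <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$risks), horizon = x$horizon,
    log_lik_base = x$fit_base$loglik,
    log_lik_augmented = x$fit_augmented$loglik,
    mean_abs_delta = mean(abs(x$risks$delta))
  )
}

#' Summarise per-participant change in predicted risk
#'
#' Computes `delta_i = risk_augmented_i - risk_base_i` and the proportion of
#' participants whose absolute change reaches a threshold (default 0.3
#' percentage points, i.e. 0.003), overall and among participants whose
#' initial (base) risk is at or above a high-risk cutoff (default 1%).
#' Ties count as exceeding (`>=`).
#'
#' @param data Data frame with the two risk columns.
#' @param risk_base,risk_augmented Column names.
#' @param threshold Absolute risk-difference threshold in probability
#'   points, in (0, 1) (0 is allowed and counts any nonzero change).
#' @param high_risk_cutoff Initial-risk cutoff defining the high-risk
#'   subgroup, in (0, 1).
#'
#' @return A one-row tibble of class `"delta_risk_summary"`: `n`,
#'   `threshold`, `prop_exceeding`, `n_high_risk`, `high_risk_cutoff`,
#'   `prop_exceeding_high_risk`, with the per-participant detail
#'   (`risk_base`, `delta`) in attribute `"detail"`.
#' @export
delta_risk_summary <- function(data, risk_base = "risk_base",
                               risk_augmented = "risk_augmented",
                               threshold = 0.003, high_risk_cutoff = 0.01) {
  rb <- as.numeric(assert_column(data, risk_base))
  ra <- as.numeric(assert_column(data, risk_augmented))
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  assert_scalar_number(high_risk_cutoff, "high_risk_cutoff",
                       lower = 0, upper = 1, strict = TRUE)
  if (length(rb) != length(ra)) abort("Risk vectors must align.")
  delta <- ra - rb
  exceeds <- if (threshold == 0) abs(delta) > 0 else abs(delta) >= threshold
  high <- rb >= high_risk_cutoff
  out <- tibble::tibble(
    n = length(delta),
    threshold = threshold,
    prop_exceeding = mean(exceeds),
    n_high_risk = sum(high),
    high_risk_cutoff = high_risk_cutoff,
    prop_exceeding_high_risk = if (any(high)) mean(exceeds[high]) else NA_real_
  )
  attr(out, "detail") <- tibble::tibble(risk_base = rb, delta = delta)
  class(out) <- c("delta_risk_summary", class(out))
  out
}
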