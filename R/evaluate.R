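#' Kaplan-Meier event probability at a time point
#'
#' Product-limit estimate of the event probability `1 - S_KM(t)`, with a
#' Greenwood-based confidence interval computed on the log(-log) scale
#' (via [survival::survfit()]).
#'
#' @param data Data frame with follow-up columns.
#' @param time,event Column names.
#' @param t Evaluation time (> 0, years).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A one-row tibble `t`, `n`, `n_events`, `survival`, `event_prob`,
#'   `conf_low`, `conf_high` (interval on the event-probability scale).
#' @export
km_estimator <- function(data, time = "time", event = "event", t,
                         conf_level = 0.95) {
  t_obs <- assert_positive_times(assert_column(data, time))
  d <- assert_event_vector(assert_column(data, event))
  assert_scalar_number(t, "t", lower = 0, strict = TRUE)
  if (length(t_obs) == 0) abort("No observations.")
  sf <- survival::survfit(survival::Surv(t_obs, d) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  sm <- summary(sf, times = t, extend = TRUE)
  surv <- sm$surv
  lo <- sm$lower
  hi <- sm$upper
  # before the first event the estimate is 1 with a degenerate interval
  if (is.na(lo)) lo <- surv
  if (is.na(hi)) hi <- surv
  tibble::tibble(
    t = t, n = length(t_obs), n_events = sum(d),
    survival = surv, event_prob = 1 - surv,
    conf_low = 1 - hi, conf_high = 1 - lo
  )
}

#' Harrell's C-statistic for censored survival data
#'
#' Concordance over comparable pairs (the participant with the earlier time
#' must have had the event); score ties are credited 0.5. Higher scores are
#' taken to mean higher risk (shorter survival). Computed via
#' [survival::concordance()]; the confidence interval uses the asymptotic
#' variance of the concordance estimator.
#'
#' @param data Data frame with follow-up columns and the risk score.
#' @param time,event,score Column names.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A one-row tibble `c_statistic`, `std_error`, `conf_low`,
#'   `conf_high`, `n_pairs`, `concordant`, `discordant`, `tied_score`.
#' @export
harrell_c <- function(data, time = "time", event = "event", score = "score",
                      conf_level = 0.95) {
  t_obs <- assert_positive_times(assert_column(data, time))
  d <- assert_event_vector(assert_column(data, event))
  s <- as.numeric(assert_column(data, score))
  if (anyNA(s)) abort("Missing scores.")
  cc <- survival::concordance(survival::Surv(t_obs, d) ~ s, reverse = TRUE)
  counts <- cc$count
  n_pairs <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) abort("No comparable pairs.")
  se <- sqrt(cc$var)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    c_statistic = unname(cc$concordance),
    std_error = unname(se),
    conf_low = unname(pmax(0, cc$concordance - zq * se)),
    conf_high = unname(pmin(1, cc$concordance + zq * se)),
    n_pairs = unname(n_pairs),
    concordant = unname(counts[["concordant"]]),
    discordant = unname(counts[["discordant"]]),
    tied_score = unname(counts[["tied.x"]])
  )
}

#' Decile calibration table: observed vs mean predicted risk
#'
#' Participants are ranked by predicted risk and split into ten equal-count
#' groups (ties broken by stable input order); each group gets its mean
#' predicted probability and the Kaplan-Meier observed event probability at
#' the horizon with confidence interval.
#'
#' @param data Data frame with predicted risks and follow-up columns.
#' @param predicted Column name of predicted risks in \[0, 1\].
#' @param time,event Follow-up column names.
#' @param horizon Horizon in years at which observed probability is taken.
#' @param groups Number of groups (default 10).
#'
#' @return A tibble of class `"calibration_table"`: `group`, `n`,
#'   `mean_predicted`, `observed`, `conf_low`, `conf_high`.
#' @export
calibration_by_tenths <- function(data, predicted = "predicted",
                                  time = "time", event = "event",
                                  horizon = 5, groups = 10L) {
  p <- as.numeric(assert_column(data, predicted))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("Predicted risks must lie in [0, 1] with no missing values.")
  }
  groups <- assert_count(groups, "groups", min = 2L)
  if (nrow(data) < groups) {
    abort(sprintf("Need at least %d participants for %d groups.", groups, groups))
  }
  # stable ranking: ties keep input order, then equal-count grouping
  ord <- order(p)                       # stable in R
  grp <- integer(length(p))
  grp[ord] <- ceiling(seq_along(p) * groups / length(p))
  t_obs <- assert_column(data, time)
  d <- assert_column(data, event)
  out <- purrr::map_dfr(seq_len(groups), function(gi) {
    idx <- grp == gi
    km <- km_estimator(tibble::tibble(time = t_obs[idx], event = d[idx]),
                       t = horizon)
    tibble::tibble(
      group = gi, n = sum(idx), mean_predicted = mean(p[idx]),
      observed = km$event_prob, conf_low = km$conf_low,
      conf_high = km$conf_high
    )
  })
  class(out) <- c("calibration_table", class(out))
  attr(out, "horizon") <- horizon
  out
}

#' Relative-risk calibration curve
#'
#' Plots the hazard ratio estimated from the cohort against the hazard
#' ratio predicted by a model. A flexible parametric survival model is
#' fitted with a restricted cubic spline (default 2 df) of the predicted
#' log hazard ratio as covariates; the fitted log hazard ratio is evaluated
#' over a grid relative to the cohort-mean predicted log hazard ratio (so
#' the estimated HR is 1 at the cohort average, by construction). A curve
#' on the identity means the model's relative risks are observed at face
#' value; a flatter curve means they are too extreme, the signature of
#' inflated GRS weights.
#'
#' @param data Data frame with the predicted log hazard ratio and follow-up
#'   columns.
#' @param pred_log_hr Column name.
#' @param time,event Follow-up column names.
#' @param df_curve Spline df for the predictor (default 2).
#' @param df_baseline Spline df for the baseline log cumulative hazard
#'   (default 2).
#' @param grid_size Number of grid points (default 50).
#' @param conf_level Confidence level for the pointwise interval.
#'
#' @return A tibble of class `"rr_calibration"`: `pred_log_hr`, `pred_hr`
#'   (both relative to the cohort mean), `est_log_hr`, `est_hr`,
#'   `conf_low`, `conf_high` (HR scale), with the reference value in
#'   attribute `"reference"` and the underlying `"fpsm"` fit in `"fit"`.
#' @export
rr_calibration <- function(data, pred_log_hr = "pred_log_hr",
                           time = "time", event = "event", df_curve = 2L,
                           df_baseline = 2L, grid_size = 50L,
                           conf_level = 0.95) {
  lhr <- as.numeric(assert_column(data, pred_log_hr))
  if (!all(is.finite(lhr))) abort("Predicted log hazard ratios must be finite.")
  if (stats::sd(lhr) == 0) {
    abort("Predicted log hazard ratio has no variation; cannot fit a calibration curve.")
  }
  df_curve <- assert_count(df_curve, "df_curve")
  ref <- mean(lhr)
  # spline basis of the predictor, knots at quantiles of the predictor
  pk <- if (df_curve > 1L) {
    new_rcs_knots(range(lhr),
                  as.numeric(quantile(lhr, probs = seq_len(df_curve - 1L) / df_curve)))
  } else {
    new_rcs_knots(range(lhr), numeric())
  }
  Xb <- rcs_basis(lhr, pk)
  cov_names <- paste0("phr_", seq_len(ncol(Xb)))
  dd <- tibble::tibble(
    time = assert_column(data, time),
    event = assert_column(data, event)
  )
  for (j in seq_along(cov_names)) dd[[cov_names[j]]] <- Xb[, j]
  fit <- fit_fpsm(dd, covariates = cov_names, df = df_baseline)

  grid <- seq(min(lhr), max(lhr), length.out = grid_size)
  Bg <- rcs_basis(grid, pk)
  Br <- rcs_basis(ref, pk)
  D <- sweep(Bg, 2, drop(Br))            # basis difference to the reference
  beta <- fit$beta
  v_beta <- fit$vcov[names(beta), names(beta), drop = FALSE]
  est <- drop(D %*% beta)
  se <- sqrt(pmax(rowSums((D %*% v_beta) * D), 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    pred_log_hr = grid - ref,
    pred_hr = exp(grid - ref),
    est_log_hr = est,
    est_hr = exp(est),
    conf_low = exp(est - zq * se),
    conf_high = exp(est + zq * se)
  )
  class(out) <- c("rr_calibration", class(out))
  attr(out, "reference") <- ref
  attr(out, "fit") <- fit
  out
}
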