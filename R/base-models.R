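#' Age-specific incidence rate table
#'
#' Validates a table of age-band incidence rates (events per person-year)
#' with contiguous, non-overlapping, half-open bands `[lower, upper)`.
#'
#' @param rates Data frame with columns `age_lower`, `age_upper`, `rate`.
#' @return The validated tibble, classed `"age_rate_table"`.
#' @export
age_rate_table <- function(rates) {
  req <- c("age_lower", "age_upper", "rate")
  if (!is.data.frame(rates) || !all(req %in% names(rates))) {
    abort("`rates` must have columns age_lower, age_upper, rate.")
  }
  rates <- dplyr::arrange(tibble::as_tibble(rates), .data$age_lower)
  if (any(rates$rate < 0)) abort("Incidence rates must be >= 0.")
  if (any(rates$age_upper <= rates$age_lower)) {
    abort("Each band needs age_upper > age_lower.")
  }
  if (nrow(rates) > 1 &&
      any(abs(rates$age_lower[-1] - rates$age_upper[-nrow(rates)]) > 1e-9)) {
    abort("Age bands must be contiguous and non-overlapping.")
  }
  structure(rates, class = c("age_rate_table", class(rates)))
}

#' Family-history relative-risk table
#'
#' @param rr Data frame with columns `fh_category`, `rr`; the reference
#'   category must have `rr = 1` and all relative risks must be positive.
#' @return The validated tibble, classed `"family_history_rr"`.
#' @export
family_history_rr <- function(rr) {
  if (!is.data.frame(rr) || !all(c("fh_category", "rr") %in% names(rr))) {
    abort("`rr` must have columns fh_category, rr.")
  }
  if (any(rr$rr <= 0)) abort("Relative risks must be > 0.")
  if (!any(abs(rr$rr - 1) < 1e-12)) {
    abort("One category must be the reference with rr = 1.")
  }
  structure(tibble::as_tibble(rr), class = c("family_history_rr", "tbl_df",
                                             "tbl", "data.frame"))
}

#' Taylor-style absolute-risk model specification
#'
#' Combines an age-specific incidence rate table with family-history
#' relative risks: the cumulative hazard over a horizon is the
#' family-history relative risk times the integral of the piecewise-constant
#' age-specific rate, and absolute risk is `1 - exp(-H)`. No competing
#' mortality adjustment is applied.
#'
#' @param rates An [age_rate_table()].
#' @param fh_rr A [family_history_rr()].
#' @return A list of class `"taylor_spec"`.
#' @export
taylor_model_spec <- function(rates, fh_rr) {
  structure(
    list(rates = age_rate_table(rates), fh_rr = family_history_rr(fh_rr),
         age_removed = FALSE),
    class = "taylor_spec"
  )
}

# Exact integral of the piecewise-constant rate over [a, a + h).
integrate_rates <- function(rates, age_start, horizon) {
  lo <- rates$age_lower
  hi <- rates$age_upper
  end <- age_start + horizon
  not_covered <- age_start < min(lo) - 1e-9 | end > max(hi) + 1e-9
  if (any(not_covered)) {
    abort(sprintf(
      "Rate table covers [%g, %g) but ages up to %g (+horizon) are needed.",
      min(lo), max(hi), max(end[not_covered])
    ))
  }
  vapply(seq_along(age_start), function(i) {
    overlap <- pmax(0, pmin(hi, end[i]) - pmax(lo, age_start[i]))
    sum(overlap * rates$rate)
  }, numeric(1))
}

#' Predict absolute risk from the Taylor-style model
#'
#' @param data Data frame with columns `age` and `fh_category`.
#' @param spec A [taylor_model_spec()].
#' @param horizon Prediction horizon in years (default 5).
#'
#' @return A tibble `log_rel_hazard` (= log of the family-history relative
#'   risk) and `risk` (absolute risk over the horizon), one row per input
#'   row.
#' @export
taylor_absolute_risk <- function(data, spec, horizon = 5) {
  if (!inherits(spec, "taylor_spec")) abort("`spec` must be a taylor_spec.")
  assert_scalar_number(horizon, "horizon", lower = 0, strict = TRUE)
  age <- assert_column(data, "age")
  fh <- as.character(assert_column(data, "fh_category"))
  rrmap <- stats::setNames(spec$fh_rr$rr, as.character(spec$fh_rr$fh_category))
  unknown <- setdiff(unique(fh), names(rrmap))
  if (length(unknown) > 0) {
    abort(sprintf("Family-history categories missing from the RR table: %s.",
                  paste(unknown, collapse = ", ")))
  }
  rr <- unname(rrmap[fh])
  base_age <- if (isTRUE(spec$age_removed)) {
    # age effect removed: evaluate the baseline hazard at a fixed reference
    # age so that the score depends on family history only
    rep(mean(range(spec$rates$age_lower)), length(age))
  } else {
    age
  }
  lambda0 <- integrate_rates(spec$rates, base_age, horizon)
  tibble::tibble(
    log_rel_hazard = log(rr),
    risk = 1 - exp(-rr * lambda0)
  )
}

#' Cox-model specification for a published risk model
#'
#' Describes a published proportional-hazards model as a term table plus the
#' baseline survival at the prediction horizon. Term types: `"linear"`
#' (contribution `coef * (x - reference)`) and `"indicator"` (contribution
#' `coef * I(x == level)`). A term's `sex` field (`"all"`, `"female"`,
#' `"male"`) masks it to zero for non-applicable participants, e.g.
#' oestrogen use for men.
#'
#' @param terms Data frame with columns `term` (covariate column name),
#'   `type`, `coefficient`, and optionally `reference` (linear terms,
#'   default 0), `level` (indicator terms) and `sex` (default "all").
#' @param baseline_survival Baseline survival S0 at `horizon` for the
#'   reference covariate profile, in (0, 1].
#' @param horizon Horizon in years to which `baseline_survival` refers.
#' @return A list of class `"cox_spec"`.
#' @export
cox_model_spec <- function(terms, baseline_survival, horizon = 5) {
  req <- c("term", "type", "coefficient")
  if (!is.data.frame(terms) || !all(req %in% names(terms))) {
    abort("`terms` must have columns term, type, coefficient.")
  }
  if (!all(terms$type %in% c("linear", "indicator"))) {
    abort("Term types must be \"linear\" or \"indicator\".")
  }
  if (!all(is.finite(terms$coefficient))) abort("Non-finite coefficient.")
  assert_scalar_number(baseline_survival, "baseline_survival",
                       lower = 0, upper = 1, strict = FALSE)
  if (baseline_survival <= 0) abort("`baseline_survival` must be in (0, 1].")
  terms <- tibble::as_tibble(terms)
  if (!"reference" %in% names(terms)) terms$reference <- 0
  terms$reference[is.na(terms$reference)] <- 0
  if (!"level" %in% names(terms)) terms$level <- NA_character_
  if (!"sex" %in% names(terms)) terms$sex <- "all"
  terms$sex[is.na(terms$sex)] <- "all"
  if (!all(terms$sex %in% c("all", "female", "male"))) {
    abort("Term sex mask must be one of all/female/male.")
  }
  structure(list(terms = terms, baseline_survival = baseline_survival,
                 horizon = horizon),
            class = "cox_spec")
}

#' Linear predictor of a published Cox model
#'
#' `eta_i = sum_k beta_k * transform_k(x_ik)`, with sex-masked terms
#' contributing 0 for non-applicable participants. Missing values in a
#' required covariate raise an error naming it: the pipeline excludes
#' incomplete participants upstream (complete-case analysis).
#'
#' @param data Cohort data frame; must contain every unmasked term's column
#'   (and a `sex` column if any term is sex-masked).
#' @param spec A [cox_model_spec()].
#' @return Numeric vector of log relative hazards.
#' @export
cox_linear_predictor <- function(data, spec) {
  if (!inherits(spec, "cox_spec")) abort("`spec` must be a cox_spec.")
  n <- nrow(data)
  eta <- numeric(n)
  any_masked <- any(spec$terms$sex != "all")
  sex <- if (any_masked) as.character(assert_column(data, "sex")) else NULL
  for (k in seq_len(nrow(spec$terms))) {
    tm <- spec$terms[k, ]
    if (!tm$term %in% names(data)) {
      abort(sprintf("Required covariate `%s` missing from `data`.", tm$term))
    }
    x <- data[[tm$term]]
    applicable <- if (tm$sex == "all") rep(TRUE, n) else sex == tm$sex
    if (anyNA(x[applicable])) {
      abort(sprintf(
        "Missing values in required covariate `%s`; exclude incomplete participants first.",
        tm$term
      ))
    }
    contrib <- if (tm$type == "linear") {
      tm$coefficient * (as.numeric(x) - tm$reference)
    } else {
      tm$coefficient * as.numeric(as.character(x) == tm$level)
    }
    contrib[!applicable] <- 0
    eta <- eta + contrib
  }
  eta
}

#' Absolute risk from a Cox linear predictor
#'
#' `risk = 1 - S0(horizon)^exp(eta)`.
#'
#' @param eta Numeric vector of log relative hazards.
#' @param spec A [cox_model_spec()] carrying `baseline_survival`.
#' @param horizon Horizon in years; must equal the spec's horizon.
#' @return Numeric vector of absolute risks in \[0, 1\].
#' @export
cox_absolute_risk <- function(eta, spec, horizon = spec$horizon) {
  if (!inherits(spec, "cox_spec")) abort("`spec` must be a cox_spec.")
  if (!isTRUE(all.equal(horizon, spec$horizon))) {
    abort("`horizon` must match the horizon of the spec's baseline survival.")
  }
  s0 <- spec$baseline_survival
  if (s0 <= 0 || s0 > 1) abort("Baseline survival outside (0, 1].")
  1 - s0^exp(eta)
}

#' Remove covariate effects from a model specification
#'
#' Returns a copy of the specification with the named coefficients set to
#' zero (Cox-style model) or, for the Taylor-style model, with the age
#' dependence of the baseline hazard switched off so that only the
#' family-history relative risk distinguishes participants. Used to assess
#' discrimination net of age. The original specification is not modified.
#'
#' @param spec A [cox_model_spec()] or [taylor_model_spec()].
#' @param names Character vector of term names to remove (may be empty).
#' @return A specification of the same class.
#' @export
remove_covariate_effect <- function(spec, names) {
  if (length(names) == 0) return(spec)
  if (inherits(spec, "cox_spec")) {
    unknown <- setdiff(names, spec$terms$term)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown term(s): %s.", paste(unknown, collapse = ", ")))
    }
    spec$terms$coefficient[spec$terms$term %in% names] <- 0
    return(spec)
  }
  if (inherits(spec, "taylor_spec")) {
    if (!identical(sort(names), "age")) {
      abort("For the Taylor-style model only \"age\" can be removed.")
    }
    spec$age_removed <- TRUE
    return(spec)
  }
  abort("`spec` must be a cox_spec or taylor_spec.")
}
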