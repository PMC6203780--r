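#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [simulation_config()]) or `files` (named
#' list of input paths) must be given. Defaults encode the analysis
#' constants: 5-year horizon, 2-df baseline splines, a 0.3-percentage-point
#' risk-change threshold, a 1% high-risk cutoff and a 0.08 kinship
#' threshold.
#'
#' @param simulate Optional [simulation_config()] block.
#' @param files Optional named list with paths `cohort`, `dosages`,
#'   `weights`, and `model` (a YAML model-spec file, see
#'   [read_base_model_spec()]).
#' @param horizon Risk horizon in years.
#' @param df Baseline spline degrees of freedom.
#' @param delta_threshold Risk-change threshold (probability points).
#' @param high_risk_cutoff High-risk initial-risk cutoff.
#' @param kinship_threshold Kinship threshold for the relatedness filter.
#' @param filter_relatedness Run the relatedness-filtered sensitivity
#'   analysis (simulate mode only; uses an auxiliary SNP panel).
#' @param aux_n_snps Size of the auxiliary kinship panel (simulate mode).
#' @param seed Integer seed for every random stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, files = NULL, horizon = 5,
                            df = 2L, delta_threshold = 0.003,
                            high_risk_cutoff = 0.01,
                            kinship_threshold = 0.08,
                            filter_relatedness = FALSE,
                            aux_n_snps = 2000L, seed = 1L) {
  if (is.null(simulate) == is.null(files)) {
    abort("Give exactly one of `simulate` or `files`.")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    abort("`simulate` must come from simulation_config().")
  }
  if (!is.null(files)) {
    req <- c("cohort", "dosages", "weights", "model")
    if (!all(req %in% names(files))) {
      abort(sprintf("`files` must name paths: %s.", paste(req, collapse = ", ")))
    }
    missing <- unlist(files[req])[!file.exists(unlist(files[req]))]
    if (length(missing) > 0) {
      abort(sprintf("Input file(s) not found: %s.", paste(missing, collapse = ", ")))
    }
  }
  assert_scalar_number(horizon, "horizon", lower = 0, strict = TRUE)
  assert_scalar_number(delta_threshold, "delta_threshold", lower = 0, upper = 1)
  assert_scalar_number(high_risk_cutoff, "high_risk_cutoff", lower = 0,
                       upper = 1, strict = TRUE)
  assert_scalar_number(kinship_threshold, "kinship_threshold", lower = 0,
                       upper = 0.5)
  structure(
    list(simulate = simulate, files = files, horizon = horizon,
         df = assert_count(df, "df"), delta_threshold = delta_threshold,
         high_risk_cutoff = high_risk_cutoff,
         kinship_threshold = kinship_threshold,
         filter_relatedness = isTRUE(filter_relatedness),
         aux_n_snps = assert_count(aux_n_snps, "aux_n_snps"),
         seed = assert_count(seed, "seed", min = 0L)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file carries the [pipeline_config()] fields; a `simulate:` mapping is
#' passed to [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s.", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    sim_args <- raw$simulate
    if (!is.null(sim_args$covariate_effects)) {
      sim_args$covariate_effects <- unlist(sim_args$covariate_effects)
    }
    for (nm in c("allele_freqs", "true_log_ors")) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- as.numeric(sim_args[[nm]])
    }
    raw$simulate <- do.call(simulation_config, sim_args)
  }
  do.call(pipeline_config, raw)
}

#' Read a base-model specification file
#'
#' YAML with `type: cox` (fields `baseline_survival`, `horizon`, `terms`: a
#' list of term mappings) or `type: taylor` (fields `rates`, `fh_rr`: inline
#' tables or paths to tab-separated files, resolved relative to the spec
#' file).
#'
#' @param path YAML file path.
#' @return A `"cox_spec"` or `"taylor_spec"` object.
#' @export
read_base_model_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model spec file not found: %s.", path))
  raw <- yaml::read_yaml(path)
  here <- dirname(path)
  load_table <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      readr::read_tsv(file.path(here, x), show_col_types = FALSE)
    } else {
      dplyr::bind_rows(lapply(x, tibble::as_tibble))
    }
  }
  if (identical(raw$type, "cox")) {
    terms <- dplyr::bind_rows(lapply(raw$terms, tibble::as_tibble))
    cox_model_spec(terms, raw$baseline_survival, raw$horizon %||% 5)
  } else if (identical(raw$type, "taylor")) {
    taylor_model_spec(load_table(raw$rates), load_table(raw$fh_rr))
  } else {
    abort("Model spec `type` must be \"cox\" or \"taylor\".")
  }
}

# Cox-style spec matching the synthetic data-generating model: same
# covariate effects and codings, baseline survival from the Weibull baseline.
synthetic_base_model <- function(sim_config, horizon) {
  eff <- sim_config$covariate_effects
  rows <- list()
  add <- function(term, type, coefficient, reference = 0, level = NA_character_) {
    tibble::tibble(term = term, type = type, coefficient = coefficient,
                   reference = reference, level = level)
  }
  for (nm in names(eff)) {
    rows[[nm]] <- switch(nm,
      age = add("age", "linear", eff[[nm]], reference = 55),
      bmi = add("bmi", "linear", eff[[nm]], reference = 27),
      sex_male = add("sex", "indicator", eff[[nm]], level = "male"),
      fh_1 = add("fh_category", "indicator", eff[[nm]], level = "1"),
      fh_2 = add("fh_category", "indicator", eff[[nm]], level = "2"),
      alcohol = add("alcohol_g_day", "linear", eff[[nm]]),
      add(nm, "linear", eff[[nm]])
    )
  }
  s0 <- exp(-(horizon / sim_config$baseline_scale)^sim_config$baseline_shape)
  cox_model_spec(dplyr::bind_rows(rows), baseline_survival = s0,
                 horizon = horizon)
}

#' Run the full GRS-augmentation analysis
#'
#' Executes the pipeline: load or simulate the cohort, exclude participants
#' with missing required covariates (complete-case analysis), compute the
#' mean-centred GRS from the published weights, apply the base risk model,
#' initially calibrate it to the cohort (offset mode), recalibrate with the
#' GRS as a separate covariate, and evaluate discrimination (base, GRS
#' alone, augmented, age-removed base), decile calibration, relative-risk
#' calibration of the GRS, and the change in individual predicted risk.
#' Optionally repeats concordance after greedy relatedness filtering.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"evaluation_report"` with elements `stage_log`,
#'   `grs_summary`, `grs_by_fh`, `concordance`, `slopes`, `calibration`
#'   (list: `base`, `augmented`), `rr_curve_grs`, `delta`, `recalibration`,
#'   and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  log_rows <- list()
  log_stage <- function(stage, n) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(stage = stage, n = n)
    inform(sprintf("[%s] n = %d", stage, n))
  }

  # -- load or simulate ------------------------------------------------------
  if (!is.null(config$simulate)) {
    syn <- generate_cohort(config$simulate)
    cohort <- syn$cohort
    dosages <- syn$dosages
    weights <- syn$published_weights
    base_spec <- synthetic_base_model(config$simulate, config$horizon)
  } else {
    cohort <- read_cohort_table(config$files$cohort)
    dosages <- read_dosage_matrix(config$files$dosages)
    weights <- read_weight_table(config$files$weights)
    base_spec <- read_base_model_spec(config$files$model)
    if (!"id" %in% names(cohort)) abort("Cohort table needs an `id` column.")
    cohort <- cohort[match(rownames(dosages), cohort$id), ]
    if (anyNA(cohort$id)) abort("Cohort and dosage ids do not match.")
  }
  log_stage("input", nrow(cohort))

  # -- complete-case exclusion ----------------------------------------------
  required <- if (inherits(base_spec, "cox_spec")) {
    unique(c(base_spec$terms$term, "time", "event",
             if (any(base_spec$terms$sex != "all")) "sex"))
  } else {
    c("age", "fh_category", "time", "event")
  }
  complete <- stats::complete.cases(cohort[, intersect(required, names(cohort))])
  cohort <- cohort[complete, ]
  dosages <- dosages[cohort$id, , drop = FALSE]
  log_stage("complete_case", nrow(cohort))

  # -- GRS -------------------------------------------------------------------
  grs <- compute_grs(dosages, weights, centre = TRUE)
  cohort$grs <- grs$grs
  grs_fh <- if ("fh_category" %in% names(cohort)) {
    grs_by_family_history(grs, cohort$fh_category)
  } else {
    NULL
  }
  log_stage("grs", nrow(cohort))

  # -- base-model predictions -----------------------------------------------
  if (inherits(base_spec, "cox_spec")) {
    eta <- cox_linear_predictor(cohort, base_spec)
    cohort$base_log_hr <- eta
    cohort$base_risk <- cox_absolute_risk(eta, base_spec, config$horizon)
    age_removed_spec <- if ("age" %in% base_spec$terms$term) {
      remove_covariate_effect(base_spec, "age")
    } else {
      NULL
    }
    cohort$base_log_hr_noage <- if (!is.null(age_removed_spec)) {
      cox_linear_predictor(cohort, age_removed_spec)
    } else {
      NA_real_
    }
  } else {
    pred <- taylor_absolute_risk(cohort, base_spec, config$horizon)
    cohort$base_log_hr <- pred$log_rel_hazard
    cohort$base_risk <- pred$risk
    noage <- taylor_absolute_risk(
      cohort, remove_covariate_effect(base_spec, "age"), config$horizon
    )
    cohort$base_log_hr_noage <- noage$log_rel_hazard
  }
  log_stage("base_model", nrow(cohort))

  # centre the base log HR so spline intercept and slope separate cleanly
  cohort$base_log_hr <- cohort$base_log_hr - mean(cohort$base_log_hr)

  # -- initial calibration and GRS recalibration ----------------------------
  init <- initial_calibration(cohort, df = config$df, horizon = config$horizon)
  recal <- recalibrate_with_grs(cohort, df = config$df,
                                horizon = config$horizon)
  log_stage("recalibration", nrow(cohort))

  # -- evaluation ------------------------------------------------------------
  aug_beta <- recal$fit_augmented$beta
  cohort$aug_score <- drop(cbind(cohort$base_log_hr, cohort$grs) %*%
                             if (length(aug_beta) == 2) aug_beta else c(aug_beta, 0))
  conc <- dplyr::bind_rows(
    dplyr::mutate(harrell_c(cohort, score = "base_log_hr"), model = "base"),
    dplyr::mutate(harrell_c(cohort, score = "grs"), model = "grs_alone"),
    dplyr::mutate(harrell_c(cohort, score = "aug_score"), model = "augmented"),
    if (!anyNA(cohort$base_log_hr_noage)) {
      dplyr::mutate(harrell_c(cohort, score = "base_log_hr_noage"),
                    model = "base_age_removed")
    }
  )
  conc <- dplyr::relocate(conc, "model")

  cohort$risk_recal_base <- recal$risks$risk_base
  cohort$risk_recal_aug <- recal$risks$risk_augmented
  calib_base <- calibration_by_tenths(cohort, predicted = "risk_recal_base",
                                      horizon = config$horizon)
  calib_aug <- calibration_by_tenths(cohort, predicted = "risk_recal_aug",
                                     horizon = config$horizon)
  rr_grs <- rr_calibration(cohort, pred_log_hr = "grs",
                           df_baseline = config$df)
  delta <- delta_risk_summary(
    recal$risks,
    threshold = config$delta_threshold,
    high_risk_cutoff = config$high_risk_cutoff
  )
  log_stage("evaluation", nrow(cohort))

  # -- optional relatedness-filtered sensitivity analysis -------------------
  related <- NULL
  if (config$filter_relatedness) {
    if (is.null(config$simulate)) {
      warn("Relatedness filtering is only wired for simulate mode; skipped.")
    } else {
      aux_freq <- with_seed(derive_seed(config$seed, 201L),
                            runif(config$aux_n_snps, 0.1, 0.9))
      aux <- simulate_genotypes(nrow(cohort), aux_freq,
                                derive_seed(config$seed, 202L),
                                ids = cohort$id)
      aux <- inject_sibling_pairs(aux, config$simulate$n_sibling_pairs,
                                  aux_freq, derive_seed(config$seed, 203L))$dosages
      pairs <- estimate_kinship(aux)
      kept <- filter_related(pairs, cohort$id,
                             threshold = config$kinship_threshold,
                             seed = derive_seed(config$seed, 204L))
      sub <- cohort[cohort$id %in% kept, ]
      log_stage("relatedness_filtered", nrow(sub))
      related <- list(
        kept_ids = kept,
        concordance = dplyr::relocate(dplyr::bind_rows(
          dplyr::mutate(harrell_c(sub, score = "base_log_hr"), model = "base"),
          dplyr::mutate(harrell_c(sub, score = "aug_score"), model = "augmented")
        ), "model")
      )
    }
  }

  structure(
    list(
      stage_log = dplyr::bind_rows(log_rows),
      grs_summary = grs_summary(grs),
      grs_by_fh = grs_fh,
      concordance = conc,
      slopes = recal$slopes,
      calibration = list(base = calib_base, augmented = calib_aug),
      rr_curve_grs = rr_grs,
      delta = delta,
      recalibration = recal,
      initial_calibration = init,
      related = related,
      cohort = cohort,
      provenance = list(
        seed = config$seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("grsrecal"))
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat("Stages:\n")
  print(x$stage_log)
  cat("\nConcordance:\n")
  print(x$concordance[, c("model", "c_statistic", "conf_low", "conf_high")])
  cat("\nCalibration slopes:\n")
  print(x$slopes)
  cat("\nChange in predicted risk:\n")
  print(tibble::as_tibble(x$delta))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary (`report.json`) plus tab-separated detail tables.
#'
#' @param report An `"evaluation_report"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "evaluation_report")) {
    abort("`report` must come from run_pipeline().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    stage_log = report$stage_log,
    grs_summary = report$grs_summary,
    concordance = report$concordance,
    slopes = report$slopes,
    delta = tibble::as_tibble(report$delta),
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 6, dataframe = "rows")
  readr::write_tsv(report$calibration$base, file.path(dir, "calibration_base.tsv"))
  readr::write_tsv(report$calibration$augmented,
                   file.path(dir, "calibration_augmented.tsv"))
  readr::write_tsv(tibble::as_tibble(report$rr_curve_grs),
                   file.path(dir, "rr_calibration_grs.tsv"))
  readr::write_tsv(attr(report$delta, "detail"),
                   file.path(dir, "delta_detail.tsv"))
  invisible(dir)
}
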