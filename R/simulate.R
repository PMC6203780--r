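#' Simulation configuration for a synthetic cohort
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults emulate a large prospective cohort of
#' middle-aged participants genotyped at 41 independent risk SNPs: allele
#' frequencies spread over (0.1, 0.9), per-SNP log hazard ratios scaled so the
#' theoretical standard deviation of the genetic risk score (GRS) is 0.495,
#' a Weibull baseline hazard giving roughly a 0.4% five-year event
#' probability at the average covariate profile, administrative censoring at
#' 7 years with light exponential dropout, and a weak positive ordinal-logit
#' link between the GRS and self-reported family history.
#'
#' @param n_participants Number of participants to simulate.
#' @param n_snps Number of GRS SNPs (default 41).
#' @param allele_freqs Effect-allele frequencies, strictly in (0, 1). If
#'   `NULL`, drawn reproducibly from the seed on (0.1, 0.9).
#' @param true_log_ors Per-SNP log hazard ratios used in data generation. If
#'   `NULL`, drawn from the seed and rescaled so the theoretical GRS standard
#'   deviation `sqrt(sum(w^2 * 2 p (1 - p)))` equals `grs_sd`.
#' @param grs_sd Target theoretical GRS standard deviation used when
#'   `true_log_ors` is `NULL` (default 0.495).
#' @param inflation_factor Multiplicative winner's-curse inflation kappa:
#'   published weight = kappa * true weight. 1 means no inflation.
#' @param grs_hazard_scale Coefficient on the true-weight GRS in the
#'   data-generating hazard (default 1; set 0 for a cohort where the GRS
#'   truly has no effect while published weights stay nonzero).
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (time in years): cumulative hazard `(t / scale)^shape`.
#' @param covariate_effects Named vector of log hazard ratios applied to the
#'   simulated covariates (see [simulate_covariates_and_fh()] for names and
#'   codings; effects apply to centred/indicator codings).
#' @param fh_grs_association Ordinal-logit coefficient linking the GRS to the
#'   family-history category (per GRS unit on the log-odds scale).
#' @param censor_horizon Administrative censoring horizon in years.
#' @param dropout_rate Exponential dropout rate per year (0 disables).
#' @param n_sibling_pairs Number of sibling pairs injected into the genotype
#'   matrix (expected kinship 0.25).
#' @param seed Integer seed; every random draw flows from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_participants,
                              n_snps = 41L,
                              allele_freqs = NULL,
                              true_log_ors = NULL,
                              grs_sd = 0.495,
                              inflation_factor = 1,
                              grs_hazard_scale = 1,
                              baseline_shape = 1.2,
                              baseline_scale = 500,
                              covariate_effects = default_covariate_effects(),
                              fh_grs_association = 0.3,
                              censor_horizon = 7,
                              dropout_rate = 0.005,
                              n_sibling_pairs = 0L,
                              seed = 1L) {
  n_participants <- assert_count(n_participants, "n_participants")
  n_snps <- assert_count(n_snps, "n_snps")
  assert_scalar_number(inflation_factor, "inflation_factor", lower = 0, strict = TRUE)
  assert_scalar_number(grs_hazard_scale, "grs_hazard_scale")
  assert_scalar_number(baseline_shape, "baseline_shape", lower = 0, strict = TRUE)
  assert_scalar_number(baseline_scale, "baseline_scale", lower = 0, strict = TRUE)
  assert_scalar_number(censor_horizon, "censor_horizon", lower = 0, strict = TRUE)
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0)
  n_sibling_pairs <- assert_count(n_sibling_pairs, "n_sibling_pairs", min = 0L)
  if (2L * n_sibling_pairs > n_participants) {
    abort("`n_sibling_pairs` must not exceed n_participants / 2.")
  }
  seed <- assert_count(seed, "seed", min = 0L)

  if (is.null(allele_freqs)) {
    allele_freqs <- with_seed(derive_seed(seed, 101L),
                              runif(n_snps, 0.1, 0.9))
  }
  if (length(allele_freqs) != n_snps) {
    abort("`allele_freqs` must have length `n_snps`.")
  }
  assert_probability_vector(allele_freqs, "allele_freqs")

  if (is.null(true_log_ors)) {
    raw <- with_seed(derive_seed(seed, 102L), abs(rnorm(n_snps, 0, 1)))
    het <- 2 * allele_freqs * (1 - allele_freqs)
    true_log_ors <- raw * grs_sd / sqrt(sum(raw^2 * het))
  }
  if (length(true_log_ors) != n_snps || !all(is.finite(true_log_ors))) {
    abort("`true_log_ors` must be a finite vector of length `n_snps`.")
  }
  if (!is.numeric(covariate_effects) || is.null(names(covariate_effects))) {
    abort("`covariate_effects` must be a named numeric vector.")
  }

  structure(
    list(
      n_participants = n_participants, n_snps = n_snps,
      allele_freqs = allele_freqs, true_log_ors = true_log_ors,
      inflation_factor = inflation_factor,
      grs_hazard_scale = grs_hazard_scale,
      baseline_shape = baseline_shape, baseline_scale = baseline_scale,
      covariate_effects = covariate_effects,
      fh_grs_association = fh_grs_association,
      censor_horizon = censor_horizon, dropout_rate = dropout_rate,
      n_sibling_pairs = n_sibling_pairs, seed = seed
    ),
    class = "sim_config"
  )
}

#' Default covariate log hazard ratios for the synthetic cohort
#'
#' Modest lifestyle and metabolic effects of the size reported for
#' colorectal cancer risk factors, plus a per-year age effect reflecting the
#' steep age gradient of incidence. Codings are those produced by
#' [simulate_covariates_and_fh()]: `age` is centred at 55 years, `bmi` at
#' 27 kg/m^2, binary factors are 0/1 indicators.
#'
#' @return Named numeric vector of log hazard ratios.
#' @export
default_covariate_effects <- function() {
  c(age = 0.06, sex_male = 0.25, diabetes = 0.2, fh_1 = 0.55, fh_2 = 0.9,
    bmi = 0.02, smoking = 0.15, alcohol = 0.004, nsaid = -0.2)
}

#' Simulate unlinked genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP column is drawn i.i.d. Binomial(2, p) across participants: no
#' linkage disequilibrium, no genotyping error.
#'
#' @param n Number of participants (rows).
#' @param freqs Effect-allele frequencies, strictly in (0, 1).
#' @param seed Integer seed.
#' @param ids Optional participant ids (row names); default `p1..pn`.
#' @param snp_ids Optional SNP ids (column names); default `rs_sim_1..m`.
#'
#' @return Integer matrix of allele dosages in \{0, 1, 2\}, participants in
#'   rows, SNPs in columns.
#' @export
simulate_genotypes <- function(n, freqs, seed, ids = NULL, snp_ids = NULL) {
  n <- assert_count(n, "n")
  assert_probability_vector(freqs, "freqs")
  m <- length(freqs)
  g <- with_seed(seed, {
    matrix(rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n, ncol = m)
  })
  rownames(g) <- ids %||% paste0("p", seq_len(n))
  colnames(g) <- snp_ids %||% paste0("rs_sim_", seq_len(m))
  g
}

#' Simulate covariates and a GRS-linked family-history category
#'
#' Generates baseline age (uniform on 40-69 years), sex, and the lifestyle
#' covariates used by the published colorectal-cancer risk models, plus a
#' family-history category in \{0, 1, 2\} ("2" meaning two or more affected
#' first-degree relatives). The family-history category follows a
#' proportional-odds (ordinal logit) model in the GRS with coefficient
#' `fh_grs_association`, so a positive coefficient makes higher categories
#' more likely at higher GRS — a weak positive link at the default value.
#'
#' @param n Number of participants.
#' @param grs_values Numeric GRS vector of length `n` (centred scale).
#' @param fh_grs_association Ordinal-logit coefficient (log odds per GRS
#'   unit); 0 makes family history independent of the GRS.
#' @param seed Integer seed.
#' @param fh_base_probs Marginal category probabilities at GRS = 0
#'   (default c(0.90, 0.09, 0.01)).
#'
#' @return A tibble with columns `age`, `sex` ("female"/"male"), `diabetes`,
#'   `multivitamin`, `fh_category` (factor 0/1/2), `education_years`, `bmi`,
#'   `alcohol_g_day`, `physical_activity`, `nsaid`, `red_meat`, `smoking`,
#'   `oestrogen` (women only; 0 for men).
#' @export
simulate_covariates_and_fh <- function(n, grs_values, fh_grs_association,
                                       seed, fh_base_probs = c(0.90, 0.09, 0.01)) {
  n <- assert_count(n, "n")
  if (length(grs_values) != n || anyNA(grs_values)) {
    abort("`grs_values` must be a complete numeric vector of length `n`.")
  }
  stopifnot(length(fh_base_probs) == 3L, all(fh_base_probs > 0),
            abs(sum(fh_base_probs) - 1) < 1e-8)

  # proportional-odds cutpoints on the logit scale at GRS = 0
  c1 <- stats::qlogis(fh_base_probs[1])
  c2 <- stats::qlogis(fh_base_probs[1] + fh_base_probs[2])

  with_seed(seed, {
    lp <- fh_grs_association * grs_values
    p_le0 <- stats::plogis(c1 - lp)
    p_le1 <- stats::plogis(c2 - lp)
    u <- runif(n)
    fh <- ifelse(u < p_le0, 0L, ifelse(u < p_le1, 1L, 2L))

    sex <- ifelse(runif(n) < 0.55, "female", "male")
    tibble::tibble(
      age = runif(n, 40, 69),
      sex = sex,
      diabetes = as.integer(runif(n) < 0.05),
      multivitamin = as.integer(runif(n) < 0.3),
      fh_category = factor(fh, levels = 0:2),
      education_years = pmax(7, pmin(20, round(rnorm(n, 13, 2.5)))),
      bmi = pmax(16, rnorm(n, 27, 4.5)),
      alcohol_g_day = pmax(0, rnorm(n, 12, 12)),
      physical_activity = pmax(0, rnorm(n, 30, 20)),
      nsaid = as.integer(runif(n) < 0.25),
      red_meat = pmax(0, rnorm(n, 60, 30)),
      smoking = as.integer(runif(n) < 0.45),
      oestrogen = as.integer(sex == "female" & runif(n) < 0.35)
    )
  })
}

#' Simulate event and censoring times under a Weibull proportional-hazards model
#'
#' Latent event times have cumulative hazard
#' `H(t | x) = (t / scale)^shape * exp(lp)`, inverted in closed form as
#' `T = scale * (E / exp(lp))^(1/shape)` with `E ~ Exp(1)`. Observed time is
#' the minimum of the event time, an exponential dropout time, and the
#' administrative horizon; the event indicator is 1 iff the event time is
#' smallest.
#'
#' @param linear_predictor Numeric vector of log relative hazards.
#' @param shape,scale Positive Weibull baseline parameters (years).
#' @param censor_horizon Administrative horizon in years.
#' @param dropout_rate Exponential dropout rate per year (0 disables).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `time` (> 0) and `event` (0/1).
#' @export
simulate_event_times <- function(linear_predictor, shape, scale,
                                 censor_horizon, dropout_rate, seed) {
  if (!is.numeric(linear_predictor) || anyNA(linear_predictor)) {
    abort("`linear_predictor` must be numeric with no missing values.")
  }
  assert_scalar_number(shape, "shape", lower = 0, strict = TRUE)
  assert_scalar_number(scale, "scale", lower = 0, strict = TRUE)
  assert_scalar_number(censor_horizon, "censor_horizon", lower = 0, strict = TRUE)
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0)
  n <- length(linear_predictor)

  with_seed(seed, {
    e <- rexp(n)
    t_event <- scale * (e / exp(linear_predictor))^(1 / shape)
    t_drop <- if (dropout_rate > 0) rexp(n, dropout_rate) else rep(Inf, n)
    time <- pmin(t_event, t_drop, censor_horizon)
    event <- as.integer(t_event <= pmin(t_drop, censor_horizon))
    # guard against numerically zero times for the log-time model
    time <- pmax(time, 1e-8)
    tibble::tibble(time = time, event = event)
  })
}

#' Inject sibling pairs into a genotype matrix by Mendelian transmission
#'
#' For each designated pair, two parental genotypes are drawn under
#' Hardy-Weinberg equilibrium and both siblings receive one transmitted
#' allele per parent per SNP, giving an expected kinship coefficient of
#' 0.25. All other rows are left untouched.
#'
#' @param dosages Dosage matrix in \{0, 1, 2\} with participant row names.
#' @param n_pairs Number of sibling pairs (uses rows 1..2*n_pairs).
#' @param freqs Effect-allele frequencies (length = number of SNP columns).
#' @param seed Integer seed.
#'
#' @return A list with `dosages` (modified matrix) and `pedigree` (tibble
#'   `id_a`, `id_b`, `relationship`).
#' @export
inject_sibling_pairs <- function(dosages, n_pairs, freqs, seed) {
  n_pairs <- assert_count(n_pairs, "n_pairs", min = 0L)
  if (2L * n_pairs > nrow(dosages)) {
    abort("`n_pairs` too large: need 2 * n_pairs <= nrow(dosages).")
  }
  if (length(freqs) != ncol(dosages)) {
    abort("`freqs` must have one entry per SNP column.")
  }
  if (n_pairs == 0L) {
    return(list(
      dosages = dosages,
      pedigree = tibble::tibble(id_a = character(), id_b = character(),
                                relationship = character())
    ))
  }
  m <- ncol(dosages)
  ids <- rownames(dosages)
  out <- with_seed(seed, {
    for (k in seq_len(n_pairs)) {
      i <- 2L * k - 1L
      j <- 2L * k
      pa <- rbinom(m, 2L, freqs)  # parent A dosage per SNP
      pb <- rbinom(m, 2L, freqs)  # parent B
      # transmitted allele ~ Bernoulli(dosage / 2) per meiosis
      sib1 <- rbinom(m, 1L, pa / 2) + rbinom(m, 1L, pb / 2)
      sib2 <- rbinom(m, 1L, pa / 2) + rbinom(m, 1L, pb / 2)
      dosages[i, ] <- sib1
      dosages[j, ] <- sib2
    }
    dosages
  })
  pedigree <- tibble::tibble(
    id_a = ids[seq(1L, 2L * n_pairs, by = 2L)],
    id_b = ids[seq(2L, 2L * n_pairs, by = 2L)],
    relationship = "sibling"
  )
  list(dosages = out, pedigree = pedigree)
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates the generator: genotypes (with optional sibling pairs), the
#' true-weight GRS, covariates with a GRS-linked family history, and
#' censored event times whose hazard combines the covariate effects with
#' `grs_hazard_scale` times the true-weight GRS. Published weights are
#' `inflation_factor` times the true weights (winner's-curse inflation).
#'
#' @param config A [simulation_config()] object.
#'
#' @return A list of class `"synthetic_cohort"` with elements `cohort`
#'   (tibble: `id`, covariates, `time`, `event`, `grs_true`), `dosages`
#'   (matrix), `published_weights` and `true_weights` (tibbles `snp_id`,
#'   `effect_allele`, `log_or`), and `pedigree`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must come from simulation_config().")
  }
  cf <- config
  alleles <- with_seed(derive_seed(cf$seed, 103L), {
    eff <- sample(c("A", "C", "G", "T"), cf$n_snps, replace = TRUE)
    oth <- vapply(eff, function(a) {
      sample(setdiff(c("A", "C", "G", "T"), a), 1L)
    }, character(1))
    list(effect = unname(eff), other = unname(oth))
  })

  dosages <- simulate_genotypes(cf$n_participants, cf$allele_freqs,
                                derive_seed(cf$seed, 1L))
  sib <- inject_sibling_pairs(dosages, cf$n_sibling_pairs, cf$allele_freqs,
                              derive_seed(cf$seed, 2L))
  dosages <- sib$dosages

  true_weights <- tibble::tibble(
    snp_id = colnames(dosages),
    effect_allele = alleles$effect,
    other_allele = alleles$other,
    log_or = cf$true_log_ors
  )
  published_weights <- true_weights
  published_weights$log_or <- cf$inflation_factor * true_weights$log_or

  grs_true <- as.numeric(dosages %*% cf$true_log_ors)
  grs_true_c <- grs_true - mean(grs_true)

  covs <- simulate_covariates_and_fh(cf$n_participants, grs_true_c,
                                     cf$fh_grs_association,
                                     derive_seed(cf$seed, 3L))

  lp_cov <- covariate_linear_predictor(covs, cf$covariate_effects)
  lp <- lp_cov + cf$grs_hazard_scale * grs_true_c
  surv <- simulate_event_times(lp, cf$baseline_shape, cf$baseline_scale,
                               cf$censor_horizon, cf$dropout_rate,
                               derive_seed(cf$seed, 4L))

  cohort <- dplyr::bind_cols(
    tibble::tibble(id = rownames(dosages)), covs, surv,
    tibble::tibble(grs_true = grs_true_c, lp_true = lp)
  )
  structure(
    list(cohort = cohort, dosages = dosages,
         published_weights = published_weights, true_weights = true_weights,
         pedigree = sib$pedigree, config = cf),
    class = "synthetic_cohort"
  )
}

# Linear predictor of the data-generating hazard from named covariate effects.
# Codings: age centred at 55, bmi at 27; fh_1/fh_2 are category indicators;
# sex_male indicator; other names match cohort columns used as-is.
covariate_linear_predictor <- function(covs, effects) {
  lp <- numeric(nrow(covs))
  for (nm in names(effects)) {
    b <- effects[[nm]]
    x <- switch(nm,
      age = covs$age - 55,
      bmi = covs$bmi - 27,
      sex_male = as.numeric(covs$sex == "male"),
      fh_1 = as.numeric(covs$fh_category == "1"),
      fh_2 = as.numeric(covs$fh_category == "2"),
      alcohol = covs$alcohol_g_day,
      {
        if (!nm %in% names(covs)) {
          abort(sprintf("Unknown covariate `%s` in covariate_effects.", nm))
        }
        as.numeric(covs[[nm]])
      }
    )
    lp <- lp + b * x
  }
  lp
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participants, %d SNPs, %d events, %d sibling pairs\n",
    nrow(x$cohort), ncol(x$dosages), sum(x$cohort$event), nrow(x$pedigree)
  ))
  invisible(x)
}
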