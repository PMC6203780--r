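#' Compute a weighted genetic risk score
#'
#' The GRS is the linear combination of allele dosages and published log
#' odds ratios, `GRS_i = sum_j w_j g_ij`, optionally mean-centred. The score
#' is kept on the natural log-odds-ratio scale (no standardisation) so that
#' it can enter survival models as a log relative hazard; standardisation,
#' if wanted, is an explicit downstream choice.
#'
#' @param dosages Numeric matrix of allele dosages in \[0, 2\], participants
#'   in rows (row names = ids), SNPs in columns (column names = SNP ids).
#' @param weights Weight table: data frame with columns `snp_id`,
#'   `effect_allele`, `log_or`. Every `snp_id` must be a dosage column.
#' @param centre Subtract the sample mean (default `TRUE`, the scale on
#'   which the score is reported and modelled).
#' @param na_action `"error"` (default) fails on missing dosages;
#'   `"impute_mean"` replaces missing dosages with twice the effect-allele
#'   frequency estimated from the non-missing calls of that SNP, and records
#'   the imputed SNPs in the result's `imputed_snps` attribute.
#'
#' @return A tibble `id`, `grs` of class `"grs_result"`, with attribute
#'   `grs_summary` (tibble `n`, `mean`, `sd`, `min`, `max`, `centred`).
#' @export
compute_grs <- function(dosages, weights, centre = TRUE,
                        na_action = c("error", "impute_mean")) {
  na_action <- match.arg(na_action)
  check_weight_table(weights)
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    abort("`dosages` must be a numeric matrix (participants x SNPs).")
  }
  missing_snps <- setdiff(weights$snp_id, colnames(dosages))
  if (length(missing_snps) > 0) {
    abort(sprintf(
      "SNPs in the weight table are missing from the dosage matrix: %s.",
      paste(missing_snps, collapse = ", ")
    ))
  }
  g <- dosages[, weights$snp_id, drop = FALSE]
  imputed <- character()
  if (anyNA(g)) {
    if (na_action == "error") {
      abort("Missing dosages found; set na_action = \"impute_mean\" to impute 2*freq.")
    }
    for (j in which(colSums(is.na(g)) > 0)) {
      fill <- mean(g[, j], na.rm = TRUE)  # = 2 * effect-allele frequency
      g[is.na(g[, j]), j] <- fill
      imputed <- c(imputed, colnames(g)[j])
    }
  }
  if (any(g < 0 | g > 2)) {
    abort("Dosage values outside [0, 2] found.")
  }
  grs <- as.numeric(g %*% weights$log_or)
  if (isTRUE(centre)) grs <- grs - mean(grs)

  out <- tibble::tibble(
    id = rownames(dosages) %||% as.character(seq_len(nrow(dosages))),
    grs = grs
  )
  attr(out, "grs_summary") <- tibble::tibble(
    n = length(grs), mean = mean(grs), sd = stats::sd(grs),
    min = min(grs), max = max(grs), centred = isTRUE(centre)
  )
  attr(out, "imputed_snps") <- imputed
  class(out) <- c("grs_result", class(out))
  out
}

check_weight_table <- function(weights) {
  req <- c("snp_id", "effect_allele", "log_or")
  if (!is.data.frame(weights) || !all(req %in% names(weights))) {
    abort("`weights` must have columns snp_id, effect_allele, log_or.")
  }
  if (anyDuplicated(weights$snp_id)) {
    abort("Duplicate snp_id entries in the weight table.")
  }
  if (!all(is.finite(weights$log_or))) {
    abort("Non-finite log_or in the weight table.")
  }
  invisible(weights)
}

#' Summary block of a GRS result
#'
#' @param grs A [compute_grs()] result.
#' @return The tibble stored in the `grs_summary` attribute.
#' @export
grs_summary <- function(grs) {
  s <- attr(grs, "grs_summary")
  if (is.null(s)) abort("`grs` must come from compute_grs().")
  s
}

#' Align dosage orientation to a weight table's effect alleles
#'
#' Dosages must count the weight table's effect allele. Where the cohort's
#' counted allele is the weight table's *other* allele, dosages are flipped
#' to `2 - g`. Strand-ambiguous SNPs (A/T or C/G pairs) are flagged for user
#' review, never silently resolved, because a strand error flips the sign of
#' the SNP's contribution to the score.
#'
#' @param dosages Dosage matrix; columns named by SNP id.
#' @param weights Weight table (`snp_id`, `effect_allele`, optionally
#'   `other_allele`, `log_or`).
#' @param cohort_alleles Data frame `snp_id`, `counted_allele`,
#'   `other_allele` describing what the dosage columns count.
#'
#' @return A list with `dosages` (aligned matrix) and `alignment` (tibble
#'   `snp_id`, `flipped`, `ambiguous`).
#' @export
align_alleles <- function(dosages, weights, cohort_alleles) {
  check_weight_table(weights)
  req <- c("snp_id", "counted_allele", "other_allele")
  if (!is.data.frame(cohort_alleles) || !all(req %in% names(cohort_alleles))) {
    abort("`cohort_alleles` must have columns snp_id, counted_allele, other_allele.")
  }
  ca <- cohort_alleles[match(weights$snp_id, cohort_alleles$snp_id), ]
  if (anyNA(ca$snp_id)) {
    abort(sprintf(
      "No cohort allele annotation for SNP(s): %s.",
      paste(setdiff(weights$snp_id, cohort_alleles$snp_id), collapse = ", ")
    ))
  }
  ambiguous_pair <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  flipped <- logical(nrow(ca))
  for (k in seq_len(nrow(ca))) {
    eff <- weights$effect_allele[k]
    if (ca$counted_allele[k] == eff) {
      flipped[k] <- FALSE
    } else if (ca$other_allele[k] == eff) {
      flipped[k] <- TRUE
    } else {
      abort(sprintf(
        "Allele pair %s/%s at SNP %s is incompatible with effect allele %s.",
        ca$counted_allele[k], ca$other_allele[k], ca$snp_id[k], eff
      ))
    }
  }
  amb <- ambiguous_pair(ca$counted_allele, ca$other_allele)
  out <- dosages
  if (any(flipped)) {
    cols <- ca$snp_id[flipped]
    out[, cols] <- 2 - out[, cols, drop = FALSE]
  }
  list(
    dosages = out,
    alignment = tibble::tibble(snp_id = ca$snp_id, flipped = flipped,
                               ambiguous = amb)
  )
}

#' Summarise the GRS by family-history category
#'
#' @param grs A [compute_grs()] result (or tibble with a `grs` column).
#' @param fh_category Vector of family-history categories, same length.
#'
#' @return A tibble `fh_category`, `n`, `mean_grs`, `sd_grs`, one row per
#'   category.
#' @export
grs_by_family_history <- function(grs, fh_category) {
  values <- if (is.data.frame(grs)) grs$grs else grs
  if (length(values) != length(fh_category)) {
    abort("`grs` and `fh_category` must have equal length.")
  }
  if (anyNA(fh_category) || any(as.character(fh_category) == "")) {
    abort("Empty or missing family-history category labels.")
  }
  tibble::tibble(fh_category = fh_category, grs = values) |>
    dplyr::group_by(.data$fh_category) |>
    dplyr::summarise(n = dplyr::n(), mean_grs = mean(.data$grs),
                     sd_grs = stats::sd(.data$grs), .groups = "drop") |>
    dplyr::arrange(.data$fh_category)
}
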