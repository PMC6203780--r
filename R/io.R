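#' Read and write the package's tab-separated tables
#'
#' Weight tables have columns `snp_id`, `effect_allele`, `log_or` (and
#' optionally `other_allele`); dosage matrices are written with an `id`
#' column followed by one column per SNP; cohort tables carry the covariate,
#' follow-up and event columns. All files are tab-separated UTF-8 with a
#' header row.
#'
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_weight_table <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  check_weight_table(w)
  w
}

#' @rdname table_io
#' @param weights Weight table to write.
#' @export
write_weight_table <- function(weights, path) {
  check_weight_table(weights)
  readr::write_tsv(weights, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_dosage_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(d)[1] != "id") abort("Dosage file must start with an `id` column.")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d$id)
  storage.mode(m) <- "numeric"
  if (any(m < 0 | m > 2, na.rm = TRUE)) abort("Dosages outside [0, 2].")
  m
}

#' @rdname table_io
#' @param dosages Dosage matrix to write.
#' @export
write_dosage_matrix <- function(dosages, path) {
  d <- tibble::as_tibble(dosages, rownames = "id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_cohort_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname table_io
#' @param cohort Cohort tibble to write.
#' @export
write_cohort_table <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' Write dosages as a minimal VCF with a DS FORMAT field
#'
#' Emits a minimal VCFv4.2 file (one line per SNP, one sample column per
#' participant) whose DS field carries the dosage of the ALT allele; REF is
#' the weight table's other allele and ALT its effect allele, so a
#' round-trip through [read_dosages_vcf()] reproduces the matrix and the
#' counted-allele annotation. Intended for round-trip testing and
#' interchange, not as a general VCF writer.
#'
#' @param dosages Dosage matrix (participants x SNPs).
#' @param alleles Data frame `snp_id`, `effect_allele`, `other_allele`.
#' @param path Output path (plain text).
#' @export
write_dosages_vcf <- function(dosages, alleles, path) {
  req <- c("snp_id", "effect_allele", "other_allele")
  if (!is.data.frame(alleles) || !all(req %in% names(alleles))) {
    abort("`alleles` must have columns snp_id, effect_allele, other_allele.")
  }
  snps <- colnames(dosages)
  al <- alleles[match(snps, alleles$snp_id), ]
  if (anyNA(al$snp_id)) abort("Allele annotation missing for some SNPs.")
  ids <- rownames(dosages) %||% paste0("p", seq_len(nrow(dosages)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_along(snps), function(j) {
    paste(c("1", as.character(j * 1000L), snps[j], al$other_allele[j],
            al$effect_allele[j], ".", "PASS", ".", "DS",
            format(dosages[, j], trim = TRUE, digits = 10)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read allele dosages from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise counts ALT alleles from
#' GT. The counted allele is the ALT allele; the returned annotation feeds
#' [align_alleles()]. Multi-allelic records are rejected.
#'
#' @param path VCF file path.
#' @param snp_ids Optional ids to extract; an error lists any that are
#'   absent.
#'
#' @return A list with `dosages` (participants x SNPs matrix) and
#'   `alleles` (tibble `snp_id`, `counted_allele`, `other_allele`).
#' @export
read_dosages_vcf <- function(path, snp_ids = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Package vcfR is required to read VCF files.")
  }
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s.", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    abort(sprintf(
      "Multi-allelic record(s) at position(s) %s; split them first.",
      paste(fix[multi, "POS"], collapse = ", ")
    ))
  }
  ids <- fix[, "ID"]
  if (!is.null(snp_ids)) {
    missing <- setdiff(snp_ids, ids)
    if (length(missing) > 0) {
      abort(sprintf("Requested SNP(s) absent from VCF: %s.",
                    paste(missing, collapse = ", ")))
    }
  }
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(s) {
      if (is.na(s)) return(NA_real_)
      sum(strsplit(s, "[/|]")[[1]] == "1")
    }
    ds <- apply(gt, c(1, 2), count_alt)
  }
  rownames(ds) <- ids
  m <- t(ds)
  if (!is.null(snp_ids)) m <- m[, snp_ids, drop = FALSE]
  keep <- colnames(m)
  sel <- match(keep, ids)
  list(
    dosages = m,
    alleles = tibble::tibble(
      snp_id = keep,
      counted_allele = unname(fix[sel, "ALT"]),
      other_allele = unname(fix[sel, "REF"])
    )
  )
}

#' Export a fitted flexible parametric model as JSON
#'
#' @param fit An `"fpsm"` object.
#' @param path Output path.
#' @export
write_fpsm_json <- function(fit, path) {
  if (!inherits(fit, "fpsm")) abort("`fit` must be an fpsm object.")
  obj <- list(
    gamma = as.list(fit$gamma), beta = as.list(fit$beta),
    knots = list(boundary = fit$knots$boundary,
                 interior = fit$knots$interior),
    std_errors = as.list(stats::setNames(sqrt(pmax(diag(fit$vcov), 0)),
                                         rownames(fit$vcov))),
    log_lik = fit$loglik, n = fit$n, n_events = fit$n_events
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
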