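#' Estimate pairwise kinship coefficients from genotypes
#'
#' Robust between-family kinship estimator based on heterozygote
#' concordance and opposite-homozygote counts (the KING-robust form):
#' for a pair (i, j),
#' `phi_hat = (N_AaAa - 2 * N_AAaa) / (N_Aa(i) + N_Aa(j))`,
#' where `N_AaAa` counts SNPs at which both are heterozygous, `N_AAaa`
#' counts opposite homozygotes, and `N_Aa(.)` counts heterozygous SNPs per
#' individual over the shared non-missing SNPs. Expected values: 0.5 for
#' duplicates/MZ twins, 0.25 for full siblings, 0.125 for second-degree
#' relatives, 0 for unrelated pairs under Hardy-Weinberg equilibrium. The
#' GRS panel (41 SNPs) is far too small for this; use a dedicated auxiliary
#' panel of several thousand SNPs.
#'
#' @param dosages Hard-call dosage matrix in \{0, 1, 2\} (NA = missing),
#'   participants in rows.
#' @param min_snps Minimum shared non-missing SNPs for a pair to be
#'   estimated (default 100); pairs below it are flagged with `NA` kinship.
#' @param pairs Optional two-column matrix/data frame of row indices or ids
#'   restricting which pairs to estimate (default: all pairs).
#'
#' @return A tibble of class `"kinship_pairs"`: `id_a`, `id_b`, `kinship`,
#'   `n_snps`, `flagged`, one row per unordered pair.
#' @export
estimate_kinship <- function(dosages, min_snps = 100L, pairs = NULL) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix.")
  vals <- dosages[!is.na(dosages)]
  if (!all(vals %in% c(0, 1, 2))) {
    abort("Kinship estimation needs hard-call dosages in {0, 1, 2}.")
  }
  min_snps <- assert_count(min_snps, "min_snps")
  ids <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  n <- nrow(dosages)
  if (n < 2) abort("Need at least two participants.")

  obs <- !is.na(dosages)
  g <- dosages
  g[!obs] <- 0
  het <- (g == 1) & obs
  hom0 <- (g == 0) & obs
  hom2 <- (g == 2) & obs
  mode(het) <- "numeric"; mode(hom0) <- "numeric"; mode(hom2) <- "numeric"
  obs_n <- matrix(as.numeric(obs), nrow = n)

  n_shared <- tcrossprod(obs_n)
  n_hh <- tcrossprod(het)                       # both heterozygous
  n_opp <- tcrossprod(hom0, hom2)               # 0 vs 2
  n_opp <- n_opp + t(n_opp)
  # per-individual heterozygote counts restricted to shared SNPs
  het_i <- tcrossprod(het, obs_n)               # het in i, observed in j
  denom <- het_i + t(het_i)

  phi <- (n_hh - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_

  if (is.null(pairs)) {
    idx <- which(upper.tri(phi), arr.ind = TRUE)
  } else {
    pairs <- as.matrix(pairs)
    to_idx <- function(v) if (is.numeric(v)) as.integer(v) else match(v, ids)
    idx <- cbind(to_idx(pairs[, 1]), to_idx(pairs[, 2]))
    if (anyNA(idx) || any(idx[, 1] == idx[, 2])) {
      abort("`pairs` must name distinct, existing participants.")
    }
  }
  out <- tibble::tibble(
    id_a = ids[idx[, 1]],
    id_b = ids[idx[, 2]],
    kinship = phi[idx],
    n_snps = n_shared[idx],
    flagged = n_shared[idx] < min_snps
  )
  out$kinship[out$flagged] <- NA_real_
  class(out) <- c("kinship_pairs", class(out))
  out
}

#' Drop one member of each related pair
#'
#' Greedy randomized filtering: pairs with kinship above the threshold are
#' visited in random order and, whenever both members are still present,
#' one member is dropped at random. The result contains no pair above the
#' threshold, and is reproducible from the seed. Matching the sensitivity
#' analysis it supports, no attempt is made to maximise the retained set.
#'
#' @param pairs A [estimate_kinship()] result (or tibble `id_a`, `id_b`,
#'   `kinship`).
#' @param ids Character vector of all participant ids (the universe from
#'   which members are dropped).
#' @param threshold Kinship threshold (default 0.08, capturing first- and
#'   second-degree relatives).
#' @param seed Integer seed.
#'
#' @return Character vector of kept ids, in the order of `ids`.
#' @export
filter_related <- function(pairs, ids, threshold = 0.08, seed = 1L) {
  if (!is.data.frame(pairs) ||
      !all(c("id_a", "id_b", "kinship") %in% names(pairs))) {
    abort("`pairs` must have columns id_a, id_b, kinship.")
  }
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 0.5)
  if (threshold <= 0) abort("`threshold` must be in (0, 0.5].")
  rel <- pairs[!is.na(pairs$kinship) & pairs$kinship > threshold, ]
  if (nrow(rel) == 0) return(ids)
  dropped <- character()
  with_seed(seed, {
    for (k in sample.int(nrow(rel))) {
      a <- rel$id_a[k]
      b <- rel$id_b[k]
      if (a %in% dropped || b %in% dropped) next
      dropped <- c(dropped, if (runif(1) < 0.5) a else b)
    }
  })
  setdiff(ids, dropped)
}
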