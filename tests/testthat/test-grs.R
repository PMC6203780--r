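test_that("compute_grs matches hand arithmetic and the centring identity", {
  dos <- matrix(c(1, 2), nrow = 1, dimnames = list("p1", c("s1", "s2")))
  w <- tibble::tibble(snp_id = c("s1", "s2"), effect_allele = c("A", "G"),
                      log_or = c(0.1, -0.2))
  expect_equal(compute_grs(dos, w, centre = FALSE)$grs, -0.3)

  zero <- matrix(0, nrow = 3, ncol = 2,
                 dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  expect_equal(compute_grs(zero, w, centre = FALSE)$grs, rep(0, 3))

  fx <- make_dosage_fixture(n = 50)
  g <- compute_grs(fx$dosages, fx$weights, centre = TRUE)
  expect_lt(abs(mean(g$grs)), 1e-12)
  expect_true(isTRUE(grs_summary(g)$centred))
})

test_that("compute_grs is linear, scales, and matches a per-participant loop oracle", {
  fx <- make_dosage_fixture(n = 50, m = 5)
  w1 <- fx$weights
  w2 <- fx$weights
  w2$log_or <- rev(w2$log_or) + 0.05
  g1 <- compute_grs(fx$dosages, w1, centre = FALSE)$grs
  g2 <- compute_grs(fx$dosages, w2, centre = FALSE)$grs
  w12 <- w1
  w12$log_or <- w1$log_or + w2$log_or
  expect_equal(compute_grs(fx$dosages, w12, centre = FALSE)$grs, g1 + g2)
  wd <- w1
  wd$log_or <- 2 * w1$log_or
  expect_equal(compute_grs(fx$dosages, wd, centre = FALSE)$grs, 2 * g1)

  # naive loop oracle on a random 50 x 41 matrix
  dos41 <- simulate_genotypes(50, rep(0.3, 41), seed = 2)
  w41 <- tibble::tibble(snp_id = colnames(dos41),
                        effect_allele = "A",
                        log_or = withr::with_seed(3, rnorm(41, 0, 0.1)))
  oracle <- vapply(seq_len(50), function(i) {
    tot <- 0
    for (j in seq_len(41)) {
      tot <- tot + w41$log_or[j] * dos41[i, w41$snp_id[j]]
    }
    tot
  }, numeric(1))
  expect_equal(compute_grs(dos41, w41, centre = FALSE)$grs, unname(oracle))
})

test_that("compute_grs validates inputs and handles missingness by policy", {
  fx <- make_dosage_fixture()
  w_missing <- fx$weights
  w_missing$snp_id[1] <- "rs_absent"
  expect_error(compute_grs(fx$dosages, w_missing), "rs_absent")

  bad <- fx$dosages
  bad[1, 1] <- 3
  expect_error(compute_grs(bad, fx$weights), "\\[0, 2\\]")

  na_dos <- fx$dosages
  na_dos[1:3, 2] <- NA
  expect_error(compute_grs(na_dos, fx$weights), "impute")
  g <- compute_grs(na_dos, fx$weights, centre = FALSE,
                   na_action = "impute_mean")
  expect_equal(attr(g, "imputed_snps"), colnames(fx$dosages)[2])
  # imputed value is 2 * estimated allele frequency of the non-missing calls
  fill <- mean(na_dos[-(1:3), 2])
  manual <- fx$dosages
  manual[1:3, 2] <- fill
  expect_equal(g$grs, compute_grs(manual, fx$weights, centre = FALSE)$grs)
})

test_that("align_alleles flips, flags ambiguity, and is an involution", {
  fx <- make_dosage_fixture(n = 15, m = 4)
  w <- fx$weights[1:4, ]
  # counted allele equals the effect allele everywhere: identity
  same <- tibble::tibble(snp_id = w$snp_id, counted_allele = w$effect_allele,
                         other_allele = w$other_allele)
  out <- align_alleles(fx$dosages[, 1:4], w, same)
  expect_identical(out$dosages, fx$dosages[, 1:4])
  expect_true(!any(out$alignment$flipped))

  # counted allele is the other allele: dosage 2 becomes 0
  swapped <- tibble::tibble(snp_id = w$snp_id, counted_allele = w$other_allele,
                            other_allele = w$effect_allele)
  d2 <- fx$dosages[, 1:4]
  d2[1, 1] <- 2
  fl <- align_alleles(d2, w, swapped)
  expect_true(all(fl$alignment$flipped))
  expect_equal(fl$dosages[1, 1], 0)
  # flipping twice restores the input (involution), on random matrices
  for (seed in 1:3) {
    dr <- simulate_genotypes(10, rep(0.4, 4), seed = seed,
                             snp_ids = w$snp_id)
    once <- align_alleles(dr, w, swapped)$dosages
    twice <- align_alleles(once, w, same)$dosages  # flips back
    expect_equal(2 - once, dr)
    expect_equal(twice, once)
  }

  # strand-ambiguous SNP flagged
  w_amb <- w
  w_amb$effect_allele[1] <- "A"
  w_amb$other_allele[1] <- "T"
  amb <- tibble::tibble(snp_id = w$snp_id,
                        counted_allele = w_amb$effect_allele,
                        other_allele = w_amb$other_allele)
  expect_true(align_alleles(fx$dosages[, 1:4], w_amb, amb)$alignment$ambiguous[1])

  # incompatible allele pair names the SNP
  bad <- same
  bad$counted_allele[2] <- setdiff(c("A", "C", "G", "T"),
                                   c(w$effect_allele[2], w$other_allele[2]))[1]
  bad$other_allele[2] <- setdiff(c("A", "C", "G", "T"),
                                 c(w$effect_allele[2], bad$counted_allele[2]))[1]
  expect_error(align_alleles(fx$dosages[, 1:4], w, bad), w$snp_id[2])
})

test_that("grs_by_family_history summarises and respects the simulator contract", {
  g <- tibble::tibble(id = as.character(1:6), grs = c(1, 2, 3, 4, 5, 6))
  one <- grs_by_family_history(g, rep("0", 6))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_grs, 3.5)
  expect_error(grs_by_family_history(g, c(rep("0", 5), "")), "Empty")

  grs_vals <- withr::with_seed(8, rnorm(50000, 0, 0.5))
  cv <- simulate_covariates_and_fh(50000, grs_vals, 1.5, seed = 8)
  tab <- grs_by_family_history(tibble::tibble(grs = grs_vals), cv$fh_category)
  expect_true(all(diff(tab$mean_grs) > 0))

  # permuted labels: category means equal within sampling error
  perm <- withr::with_seed(9, sample(cv$fh_category))
  tabp <- grs_by_family_history(tibble::tibble(grs = grs_vals), perm)
  expect_true(max(abs(tabp$mean_grs - mean(grs_vals))) < 0.06)
})
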