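# Shared fixtures and independent oracles, all built in code at test time.

# Censored survival data from an exponential hazard.
make_exp_data <- function(n, rate = 0.2, cens_max = 15, seed = 1) {
  withr::with_seed(seed, {
    t <- rexp(n, rate)
    cens <- runif(n, 0, cens_max)
    tibble::tibble(time = pmin(t, cens), event = as.integer(t <= cens))
  })
}

# O(n^2) brute-force Harrell concordance: comparable pairs are those where
# the participant with the earlier (distinct) time had the event; score
# ties score 0.5. Independent of survival::concordance.
bf_concordance <- function(time, event, score) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next
      den <- den + 1
      if (score[a] > score[b]) {
        num <- num + 1
      } else if (score[a] == score[b]) {
        num <- num + 0.5
      }
    }
  }
  num / den
}

# Small deterministic dosage fixture with allele annotations.
make_dosage_fixture <- function(n = 20, m = 5, seed = 7) {
  freqs <- seq(0.2, 0.8, length.out = m)
  dos <- simulate_genotypes(n, freqs, seed = seed)
  weights <- tibble::tibble(
    snp_id = colnames(dos),
    effect_allele = rep(c("A", "G", "C", "T", "A"), length.out = m),
    other_allele = rep(c("C", "T", "A", "G", "G"), length.out = m),
    log_or = seq(-0.2, 0.2, length.out = m)
  )
  list(dosages = dos, weights = weights, freqs = freqs)
}
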