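# Independent brute-force oracle: hypergeometric upper tail P(X >= k) by
# exhaustive enumeration of the mass with choose() products. Kept separate
# from the package's lgamma-based summation so the two routes stay
# independent.
oracle_hyper_tail <- function(k, n, K, N) {
  xs <- 0:min(n, K)
  mass <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(mass[xs >= k])
}

# A small well-formed competition data set: three replicates, identical
# deterministic dynamics with a 10x bearing and 100x free expansion.
toy_competition <- function(n_reps = 3) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    tibble::tibble(
      replicate_id = sprintf("r%d", r),
      time_h = c(0, 24),
      cfu_total_per_ml = c(2e6, 1.1e8),
      n_screened = 200,
      n_positive = c(100, 200 * (1e7 / 1.1e8))
    )
  })
}
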