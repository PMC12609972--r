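suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# A small noise-free configuration used across tests
quiet_config <- function(...) {
  sim_config(
    n_genes = 200, n_arrays = 1, background_level = 0,
    dye_bias_coeffs = 0,
    noise_sd_at_low_A = 1e-9, noise_sd_at_high_A = 1e-9,
    ...
  )
}

# Brute-force sliding-window oracle: explicit rank-window enumeration
naive_window_stats <- function(records, window_size) {
  n <- nrow(records)
  w <- min(window_size, n)
  ord <- order(records$A, records$gene)
  sorted <- records[ord, , drop = FALSE]
  mu <- sigma <- numeric(n)
  for (i in seq_len(n)) {
    s <- min(max(i - (w - 1L) %/% 2L, 1L), n - w + 1L)
    win <- sorted$R[s:(s + w - 1)]
    mu[i] <- mean(win)
    sigma[i] <- sd(win)
  }
  out <- sorted
  out$mu_local <- mu
  out$sigma_local <- sigma
  out[order(ord), , drop = FALSE]
}

# Exact hypergeometric upper-tail by combinatorial summation
naive_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Naive BH step-up
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
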