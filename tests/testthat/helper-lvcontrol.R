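# Independent oracles and small fixtures used across the suite.

# Direct textbook evaluation of the discrete Laguerre function with plain
# binomial coefficients (small lags only) — independent of the package's
# log-space and recurrence implementations.
laguerre_oracle <- function(alpha, l, m) {
  k <- 0:l
  alpha^((m - l) / 2) * sqrt(1 - alpha) *
    sum((-1)^k * choose(m, k) * choose(l, k) * alpha^(l - k) * (1 - alpha)^k)
}

# Brute-force double loop over all event pairs for v_l(t_i).
convolve_oracle <- function(basis, train, i) {
  v <- numeric(basis$n_basis)
  if (i == 1L) return(v)
  for (j in seq_len(i - 1L)) {
    d <- train$times[i] - train$times[j]
    if (d < basis$memory_s) {
      bin <- min(max(round(d / basis$dt), 0), basis$n_lags - 1L)
      for (l in seq_len(basis$n_basis)) {
        v[l] <- v[l] + train$amplitudes[j] * laguerre_oracle(basis$alpha, l - 1L, bin)
      }
    }
  }
  v
}

# A small, fast basis for unit tests (memory 2 s at 10 ms bins).
small_basis <- function(alpha = 0.9, n_basis = 3, n_lags = 200, dt = 0.01) {
  laguerre_basis(alpha, n_basis, n_lags, dt)
}

# A modest ground-truth plant on the small basis.
small_plant <- function(preset = "mixed") {
  make_ground_truth_model(preset, basis = small_basis(), noise_sd = 0)
}

random_coeffs <- function(L) {
  c2 <- matrix(stats::rnorm(L * L, sd = 1e-4), L, L)
  lv_coefficients(stats::rnorm(1, 0.1, 0.05), stats::rnorm(1, 0.01, 0.003),
                  stats::rnorm(1, -1e-5, 3e-6), stats::rnorm(L, 0, 0.01),
                  (c2 + t(c2)) / 2, stats::rnorm(L, 0, 1e-5))
}

random_train <- function(n = 50, id = "T1", amp_mean = 150, amp_sd = 40) {
  event_train(generate_intervals(n, mean_rate = 2),
              abs(stats::rnorm(n, amp_mean, amp_sd)), train_id = id)
}
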