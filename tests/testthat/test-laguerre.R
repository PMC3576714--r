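test_that("direct Laguerre evaluation matches the closed form", {
  # only the k = 0 term survives at order 0
  expect_equal(laguerre_function(0.5, 0, 0), sqrt(0.5), tolerance = 1e-12)
  for (a in c(0.3, 0.5, 0.8)) {
    m <- c(0, 1, 7, 20)
    expect_equal(laguerre_function(a, 0, m), a^(m / 2) * sqrt(1 - a),
                 tolerance = 1e-12)
  }
  # against an independent plain-binomial implementation on a grid
  for (a in c(0.4, 0.7, 0.95)) {
    for (l in 0:4) {
      got <- laguerre_function(a, l, 0:40)
      want <- vapply(0:40, function(m) laguerre_oracle(a, l, m), numeric(1))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("recurrence-tabulated basis agrees with the direct formula", {
  for (a in c(0.5, 0.7, 0.99)) {
    b <- laguerre_basis(a, 4, 120, 0.001)
    for (l in 0:3) {
      expect_equal(b$values[l + 1, ], laguerre_function(a, l, 0:119),
                   tolerance = 1e-10)
    }
  }
})

test_that("basis is orthonormal once the tail is negligible", {
  # order-3 function at alpha = 0.5 has unit sum of squares within 1e-6 by M = 64
  v <- laguerre_function(0.5, 3, 0:63)
  expect_lt(abs(sum(v^2) - 1), 1e-6)
  b <- laguerre_basis(0.7, 3, 200, 0.001)
  expect_lt(max(abs(b$values[, 200])), 1e-8)
  expect_lt(max(abs(tcrossprod(b$values) - diag(3))), 1e-6)
})

test_that("larger alpha stretches the basis over more lags", {
  half_energy_lag <- function(alpha) {
    v <- laguerre_basis(alpha, 2, 500, 0.001)$values[2, ]
    which(cumsum(v^2) >= 0.5 * sum(v^2))[1]
  }
  expect_gt(half_energy_lag(0.95), half_energy_lag(0.7))
})

test_that("basis construction validates its parameters", {
  expect_error(laguerre_basis(1.2, 3, 100, 0.001), "alpha")
  expect_error(laguerre_basis(0.5, 0, 100, 0.001), "n_basis")
  expect_error(laguerre_basis(0.5, 3, 3, 0.001), "n_lags")
  expect_error(laguerre_basis(0.5, 3, 100, -1), "dt")
  expect_error(laguerre_function(0.5, -1, 0), "order")
  expect_error(laguerre_function(0.5, 0, -2), "lag")
})

test_that("event convolutions match a brute-force double loop", {
  b <- small_basis()
  expect_equal(convolve_events(b, random_train(10), 1), numeric(3))

  # two events closer than the memory window: single-term sum
  tr <- event_train(c(0, 0.05), c(120, 80))
  v2 <- convolve_events(b, tr, 2)
  want <- 120 * vapply(0:2, function(l) {
    laguerre_function(b$alpha, l, round(0.05 / b$dt))
  }, numeric(1))
  expect_equal(v2, want, tolerance = 1e-12)

  set.seed(42)
  tr <- random_train(50)
  V <- convolve_events(b, tr)
  for (i in c(1, 2, 17, 50)) {
    expect_equal(unname(V[i, ]), convolve_oracle(b, tr, i), tolerance = 1e-9)
  }
})

test_that("convolution is linear in amplitudes and blind beyond the memory window", {
  b <- small_basis()
  set.seed(7)
  tr <- random_train(30)
  sc <- event_train(tr$times, 3.5 * tr$amplitudes)
  expect_equal(convolve_events(b, sc), 3.5 * convolve_events(b, tr),
               tolerance = 1e-12)

  # an event exactly memory_s old (half-open window) or older contributes zero
  tr2 <- event_train(c(0, b$memory_s, b$memory_s + 5), c(100, 100, 100))
  expect_equal(convolve_events(b, tr2, 2), numeric(3))
  expect_equal(convolve_events(b, tr2, 3), numeric(3))
})

test_that("unsorted or duplicate event times are rejected", {
  expect_error(event_train(c(0, 0.5, 0.4), c(1, 1, 1)), "strictly increasing")
  expect_error(event_train(c(0, 0.5, 0.5), c(1, 1, 1)), "strictly increasing")
})
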