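test_that("design matrix has the documented column structure", {
  b <- small_basis()   # L = 3
  set.seed(5)
  trains <- list(random_train(20, "A"), random_train(25, "B"))
  trains <- lapply(trains, function(tr) { tr$outputs <- rnorm(length(tr)); tr })
  dm <- lv_design_matrix(b, trains)
  expect_equal(ncol(dm$X), 15)   # 3 + 3 + 6 + 3 for L = 3
  expect_equal(nrow(dm$X), 45)
  # intercept column of ones appears exactly once
  ones <- apply(dm$X, 2, function(col) all(col == 1))
  expect_equal(sum(ones), 1)
  # first event of each train has empty history: only static terms non-zero
  for (r in c(1, 21)) {
    A <- unname(dm$X[r, 2])
    expect_equal(unname(dm$X[r, ]), c(1, A, A^2, rep(0, 12)))
  }
  expect_error(lv_design_matrix(b, list(random_train(10))), "without outputs")
})

test_that("noiseless parameter recovery is exact to numerical precision", {
  set.seed(6)
  truth <- small_plant()
  trains <- generate_rarit(n_trains = 2, n_pulses = 150)
  trains <- lapply(trains, function(tr) simulate_plant(truth, tr, noise_sd = 0))
  fit <- lv_fit(trains, basis = truth$basis)
  expect_lt(max(abs(coef(fit) - coef(truth)) / abs(coef(truth))), 1e-6)
  # residuals orthogonal to the design columns (normal equations)
  dm <- lv_design_matrix(truth$basis, trains)
  g <- crossprod(dm$X, residuals(fit))
  expect_lt(max(abs(g) / (colSums(dm$X^2) + 1)), 1e-8)
})

test_that("constant outputs are absorbed by the intercept", {
  b <- small_basis()
  set.seed(8)
  tr <- random_train(120)
  tr$outputs <- rep(0.37, 120)
  fit <- lv_fit(list(tr), basis = b)
  expect_equal(coef(fit)[["c0"]], 0.37, tolerance = 1e-8)
  expect_lt(max(abs(coef(fit)[-1])), 1e-8)
})

test_that("estimation is unbiased under output noise", {
  set.seed(9)
  truth <- small_plant()
  bt <- coef(truth)
  est <- replicate(40, {
    trains <- generate_rarit(n_trains = 2, n_pulses = 150)
    trains <- lapply(trains, function(tr) simulate_plant(truth, tr, noise_sd = 0.05))
    coef(lv_fit(trains, basis = truth$basis))
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  # mean estimate within 4 standard errors of truth, coefficient-wise
  expect_true(all(abs(m - bt) < 4 * se + 1e-12))
})

test_that("rank deficiency without ridge is a named error, ridge resolves it", {
  set.seed(10)
  b <- small_basis()
  tr <- random_train(100)
  tr$outputs <- rnorm(100)
  dm <- lv_design_matrix(b, list(tr))
  X <- cbind(dm$X, dup = dm$X[, 4])   # duplicate the first v_l column
  expect_error(fit_least_squares(X, dm$y), "rank deficient")
  # with ridge the same system is solvable
  expect_silent(fit_least_squares(dm$X, dm$y, ridge = 1e-6))
  # more parameters than events
  expect_error(fit_least_squares(dm$X[1:10, ], dm$y[1:10]), "fewer events")
})

test_that("leave-one-train-out cross-validation scores held-out trains", {
  set.seed(12)
  truth <- small_plant()
  trains <- generate_rarit(n_trains = 4, n_pulses = 120)
  trains <- lapply(trains, function(tr) simulate_plant(truth, tr, noise_sd = 0))
  cfg <- data.frame(alpha = truth$basis$alpha, n_basis = truth$basis$n_basis,
                    memory = truth$basis$memory_s)
  cv <- lv_cross_validate(trains, grid = cfg, dt = truth$basis$dt)
  # folds = number of trains; noiseless with the true basis: VAF ~ 100%
  expect_equal(nrow(cv$folds), 4)
  expect_gt(cv$results$mean_vaf, 1 - 1e-8)
  expect_error(lv_cross_validate(trains[1], grid = cfg), "at least 2")
})

test_that("cross-validation prefers the true model order over a starved one", {
  set.seed(13)
  truth <- small_plant("facilitating")
  trains <- generate_rarit(n_trains = 4, n_pulses = 120)
  trains <- lapply(trains, function(tr) simulate_plant(truth, tr, noise_sd = 0.02))
  grid <- data.frame(alpha = c(truth$basis$alpha, 0.2),
                     n_basis = c(truth$basis$n_basis, 1),
                     memory = c(truth$basis$memory_s, 0.05))
  cv <- lv_cross_validate(trains, grid = grid, dt = truth$basis$dt)
  expect_equal(cv$best, 1)
  expect_gt(cv$results$mean_vaf[1], cv$results$mean_vaf[2])
})
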