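test_that("default protocol produces 4 x 300 events with bounded intervals", {
  set.seed(41)
  trains <- generate_farit()
  expect_length(trains, 4)
  expect_equal(sum(vapply(trains, length, integer(1))), 1200)
  for (tr in trains) {
    iv <- diff(tr$times)
    expect_true(all(iv >= 0.002 & iv <= 5))
    expect_true(all(tr$amplitudes == tr$amplitudes[1]))  # fixed intensity
  }
})

test_that("truncated-exponential intervals keep the target mean rate", {
  set.seed(42)
  means <- replicate(10, mean(diff(generate_intervals(500))))
  expect_lt(abs(mean(means) - 0.5) / 0.5, 0.05)
  expect_error(generate_intervals(100, mean_rate = 0.1,
                                  interval_bounds = c(0.002, 5)),
               "mean interval")
})

test_that("RARIT amplitudes are Gaussian around the protocol mean", {
  set.seed(43)
  trains <- generate_rarit()
  amps <- unlist(lapply(trains, `[[`, "amplitudes"))
  expect_length(amps, 1200)
  expect_true(all(amps > 0))
  expect_lt(abs(mean(amps) - 150), 3 * 45 / sqrt(1200))
})

test_that("generation is reproducible under a fixed seed", {
  set.seed(7); a <- generate_rarit(n_trains = 1, n_pulses = 50)[[1]]
  set.seed(7); b <- generate_rarit(n_trains = 1, n_pulses = 50)[[1]]
  expect_identical(a, b)
})

test_that("ground-truth presets have the advertised paired-pulse signature", {
  paired <- function(preset, gap = 0.05) {
    plant <- small_plant(preset)
    predict(plant, event_train(c(0, gap), c(150, 150)))
  }
  y <- paired("facilitating")
  expect_gt(y[2], y[1])
  y <- paired("depressing")
  expect_lt(y[2], y[1])
  # mixed: facilitation at short lags, depression at long lags
  plant <- small_plant("mixed")
  K <- volterra_kernels(plant)
  expect_gt(K$k1[round(0.05 / plant$basis$dt)], 0)
  expect_lt(min(K$k1), 0)
})

test_that("the static input-output curve is monotone over the operating range", {
  for (preset in c("facilitating", "depressing", "mixed")) {
    co <- make_ground_truth_model(preset, basis = small_basis())$coefficients
    A <- seq(0, 300, by = 1)
    y <- co$c0 + A * co$c1_present + A^2 * co$c2_present
    expect_true(all(diff(y) > 0))
  }
})

test_that("plant simulation adds seeded Gaussian noise around predictions", {
  plant <- make_ground_truth_model("mixed", basis = small_basis(),
                                   noise_sd = 0.1)
  set.seed(44)
  tr <- random_train(600)
  exact <- simulate_plant(plant, tr, noise_sd = 0)
  expect_equal(exact$outputs, predict(plant, tr), tolerance = 1e-12)
  n1 <- simulate(plant, seed = 1, train = tr)
  n2 <- simulate(plant, seed = 2, train = tr)
  expect_false(identical(n1$outputs, n2$outputs))
  expect_identical(simulate(plant, seed = 1, train = tr)$outputs, n1$outputs)
  # VAF of the noiseless prediction against noisy outputs ~ analytic limit
  expect_equal(vaf(n1$outputs, exact$outputs),
               1 - plant$noise_sd^2 / var(n1$outputs), tolerance = 0.03)
})

test_that("end-to-end control error vanishes in the noiseless limit", {
  res <- run_endtoend_scenario(seed = 101, noise_sd = 0, n_trains = 2,
                               n_pulses = 120)
  expect_lt(res$controlled_nmse, 1e-10)
  expect_gt(res$trajectory_vaf, 1 - 1e-8)
  expect_gt(res$plant_vaf, 1 - 1e-8)
  # and degrades gracefully, staying below the non-optimal benchmark
  resn <- run_endtoend_scenario(seed = 101, noise_sd = 0.1, n_trains = 2,
                                n_pulses = 120)
  expect_gt(resn$controlled_nmse, res$controlled_nmse)
  expect_lt(resn$controlled_nmse, resn$nonoptimal_nmse)
})
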