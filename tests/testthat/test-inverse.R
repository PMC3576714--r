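test_that("quadratic terms reduce to the static equation at the first event", {
  plant <- small_plant()
  co <- plant$coefficients
  q <- quadratic_terms(co, numeric(3), y_desired = 0.8)
  expect_equal(q$a, co$c2_present)
  expect_equal(q$b, co$c1_present)
  expect_equal(q$c, co$c0 - 0.8)
})

test_that("a forward-predicted output is a root of the inverse quadratic", {
  set.seed(21)
  plant <- small_plant("facilitating")
  tr <- random_train(30)
  y <- predict(plant, tr)
  V <- convolve_events(plant$basis, tr)
  for (i in c(1, 5, 30)) {
    q <- quadratic_terms(plant, V[i, ], y[i])
    A <- tr$amplitudes[i]
    expect_equal(q$a * A^2 + q$b * A + q$c, 0, tolerance = 1e-10)
  }
})

test_that("root solving follows the printed branch with flagged fallbacks", {
  quad <- function(a, b, c) quadratic_terms(
    lv_coefficients(c, b, a, numeric(0), matrix(0, 0, 0), numeric(0)),
    numeric(0), y_desired = 0)
  s <- solve_amplitude(quad(1, 0, -4))
  expect_equal(s$amplitude, 2)
  expect_equal(s$flag, "ok")
  # negative discriminant: vertex amplitude
  s <- solve_amplitude(quad(1, 0, 4))
  expect_equal(s$amplitude, 0)
  expect_equal(s$flag, "no_real_root_vertex")
  # vanishing quadratic term: linear fallback
  s <- solve_amplitude(quad(0, 2, -3))
  expect_equal(s$amplitude, 1.5)
  expect_equal(s$flag, "linear_fallback")
  # "+" branch root below zero: clamped
  s <- solve_amplitude(quad(1, 5, 4))
  expect_equal(s$amplitude, 0)
  expect_equal(s$flag, "clamped_negative")
  expect_error(solve_amplitude(quad(0, 0, 1)), "degenerate")
})

test_that("forward-inverse identity recovers a simulated train exactly", {
  set.seed(22)
  plant <- small_plant()
  tr <- random_train(200)
  desired <- predict(plant, tr)
  res <- invert_sequence(plant, tr$times, desired)
  expect_true(all(res$flags == "ok"))
  expect_lt(max(abs(res$amplitudes - tr$amplitudes) / tr$amplitudes), 1e-8)
  expect_equal(res$achieved_outputs, desired, tolerance = 1e-8)
})

test_that("solved amplitudes are causal in the desired trajectory", {
  set.seed(23)
  plant <- small_plant()
  tr <- random_train(40)
  desired <- predict(plant, tr)
  res1 <- invert_sequence(plant, tr$times, desired)
  bumped <- desired
  bumped[31:40] <- bumped[31:40] + 0.2
  res2 <- invert_sequence(plant, tr$times, bumped)
  expect_equal(res2$amplitudes[1:30], res1$amplitudes[1:30], tolerance = 1e-12)
})

test_that("constant desired output at baseline yields zero stimulation", {
  plant <- small_plant()
  times <- cumsum(rep(0.5, 20))
  res <- invert_sequence(plant, times, rep(plant$coefficients$c0, 20))
  expect_equal(res$amplitudes, rep(0, 20))
})

test_that("unreachable targets saturate at the vertex with a flag", {
  plant <- small_plant()
  res <- invert_sequence(plant, c(0, 1), c(0.8, 50))   # 50 mV is unreachable
  expect_equal(res$flags[2], "no_real_root_vertex")
  expect_lt(res$achieved_outputs[2], 50)
  expect_equal(res$amplitudes[2],
               -res$quadratics$b[2] / (2 * res$quadratics$a[2]))
})

test_that("raising one desired output never lowers its solved amplitude", {
  set.seed(24)
  plant <- small_plant("facilitating")
  tr <- random_train(15)
  desired <- predict(plant, tr)
  base <- invert_sequence(plant, tr$times, desired)
  for (d in c(0.02, 0.1, 0.2)) {
    up <- desired
    up[10] <- up[10] + d
    res <- invert_sequence(plant, tr$times, up)
    expect_gte(res$amplitudes[10], base$amplitudes[10] - 1e-12)
  }
})

test_that("the control pipeline composes trajectory prediction and inversion", {
  set.seed(25)
  traj <- make_ground_truth_model("mixed", basis = small_basis(),
                                  input_scale = 1, output_gain = 0.7,
                                  noise_sd = 0)
  plant <- small_plant()
  up <- event_train(generate_intervals(100), abs(rnorm(100, 1, 0.25)),
                    train_id = "UP1", units = c(amplitude = "mV", output = "mV"))
  res <- run_control_pipeline(traj, plant, up)
  expect_equal(res$desired_outputs, predict(traj, up), tolerance = 1e-12)
  # noiseless composition: achieved outputs reproduce the desired trajectory
  feasible <- res$flags == "ok"
  expect_gte(mean(feasible), 0.99)
  expect_equal(res$achieved_outputs[feasible],
               res$desired_outputs[feasible], tolerance = 1e-6)
})
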