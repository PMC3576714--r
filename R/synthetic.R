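#' Poisson event times with truncated inter-impulse intervals
#'
#' Draws exponential inter-impulse intervals with mean `1 / mean_rate`,
#' resampling (not clipping) any draw outside `interval_bounds` so no
#' probability mass piles up at the bounds, and accumulates them into event
#' times starting at 0.  Defaults reproduce the standard random-interval
#' protocol: mean frequency 2 Hz, intervals between 2 ms and 5 s.
#'
#' @param n_pulses Number of events.
#' @param mean_rate Mean event rate in Hz.
#' @param interval_bounds Length-2 vector `[min_s, max_s]` of admissible
#'   intervals, in seconds.
#' @return Numeric vector of `n_pulses` strictly increasing times (seconds),
#'   first event at 0.
#' @export
generate_intervals <- function(n_pulses, mean_rate = 2,
                               interval_bounds = c(0.002, 5)) {
  if (n_pulses < 1 || n_pulses != round(n_pulses)) {
    stop("`n_pulses` must be a positive integer", call. = FALSE)
  }
  if (mean_rate <= 0) stop("`mean_rate` must be positive", call. = FALSE)
  if (length(interval_bounds) != 2L || interval_bounds[1L] < 0 ||
      diff(interval_bounds) <= 0) {
    stop("`interval_bounds` must be an increasing non-negative pair",
         call. = FALSE)
  }
  if (1 / mean_rate <= interval_bounds[1L] || 1 / mean_rate >= interval_bounds[2L]) {
    stop("target mean interval 1/mean_rate must lie inside `interval_bounds`",
         call. = FALSE)
  }
  n_iv <- n_pulses - 1L
  iv <- numeric(n_iv)
  todo <- seq_len(n_iv)
  while (length(todo)) {
    draw <- stats::rexp(length(todo), rate = mean_rate)
    ok <- draw >= interval_bounds[1L] & draw <= interval_bounds[2L]
    iv[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  cumsum(c(0, iv))
}

#' Fixed-amplitude random-interval trains (FARITs)
#'
#' Generates the fixed-intensity Poisson stimulation protocol: `n_trains`
#' independent trains of `n_pulses` events each, all at the same amplitude.
#' Defaults give 4 trains x 300 pulses = 1200 events at 2 Hz with every
#' interval in \[2 ms, 5 s\]; the fixed intensity defaults to 200 (within the
#' 150-300 uA range typically used, and exposed as a parameter since it is
#' picked per preparation).
#'
#' @param n_trains Number of independent trains.
#' @param n_pulses Events per train.
#' @param amplitude Fixed amplitude for every event.
#' @param mean_rate,interval_bounds Passed to [generate_intervals()].
#' @param units Unit tags for the trains.
#' @return List of [event_train()]s (no outputs).
#' @export
generate_farit <- function(n_trains = 4, n_pulses = 300, amplitude = 200,
                           mean_rate = 2, interval_bounds = c(0.002, 5),
                           units = c(amplitude = "uA", output = "mV")) {
  if (amplitude < 0) stop("`amplitude` must be non-negative", call. = FALSE)
  lapply(seq_len(n_trains), function(k) {
    event_train(generate_intervals(n_pulses, mean_rate, interval_bounds),
                rep(amplitude, n_pulses),
                train_id = sprintf("FARIT%d", k), units = units)
  })
}

#' Random-amplitude random-interval trains (RARITs)
#'
#' Poisson-interval trains with Gaussian-distributed amplitudes (default mean
#' 150 uA, sd 45 uA, i.e. 30% coefficient of variation), truncated to
#' positive values by resampling.
#'
#' @inheritParams generate_farit
#' @param amp_mean Mean amplitude.
#' @param amp_sd Amplitude standard deviation.
#' @return List of [event_train()]s (no outputs).
#' @export
generate_rarit <- function(n_trains = 4, n_pulses = 300, amp_mean = 150,
                           amp_sd = 45, mean_rate = 2,
                           interval_bounds = c(0.002, 5),
                           units = c(amplitude = "uA", output = "mV")) {
  if (amp_mean <= 0 || amp_sd < 0) {
    stop("`amp_mean` must be positive and `amp_sd` non-negative", call. = FALSE)
  }
  lapply(seq_len(n_trains), function(k) {
    amps <- numeric(n_pulses)
    todo <- seq_len(n_pulses)
    while (length(todo)) {
      draw <- stats::rnorm(length(todo), amp_mean, amp_sd)
      ok <- draw > 0
      amps[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }
    event_train(generate_intervals(n_pulses, mean_rate, interval_bounds),
                amps, train_id = sprintf("RARIT%d", k), units = units)
  })
}

# preset coefficient templates (L = 3), in units of the input scale s:
# static curve y = c0 + g1 (A/s) + g2 (A/s)^2 is positive, increasing and
# saturating over A in [0, 2s]; history terms give ~25-30% paired-pulse
# modulation at 50 ms for A ~ s.
preset_templates <- list(
  facilitating = list(c1 = c(3, 0.5, 0.2), cross = c(0.5, 0.2, 0.1)),
  depressing   = list(c1 = -c(3, 0.5, 0.2), cross = -c(0.5, 0.2, 0.1)),
  mixed        = list(c1 = c(2, 3, -0.5), cross = c(0.3, 0.3, 0.1))
)

#' Ground-truth Laguerre-Volterra plant presets
#'
#' Builds a fully known second-order model to stand in for a biological
#' preparation in simulations (a synthetic plant; no recorded data are
#' involved).  All presets share a positive, saturating static curve
#' (`c1(0) > 0`, `c2(0,0) < 0`, monotone increasing over
#' `[0, 2 * input_scale]`); they differ in the sign structure of the history
#' terms:
#' * `"facilitating"` — past impulses boost the next response (paired-pulse
#'   facilitation), zero-lag and early first-order kernel share polarity;
#' * `"depressing"` — past impulses suppress it, so the early first-order
#'   kernel has polarity opposite to the zero-lag term;
#' * `"mixed"` — facilitation at short lags turning into depression at longer
#'   lags.
#'
#' @param preset One of `"mixed"`, `"facilitating"`, `"depressing"`.
#' @param basis A [laguerre_basis()] with `n_basis <= 3`; the default
#'   (`alpha = 0.99`, `L = 3`, `M = 3000`, `dt` 1 ms) places the history
#'   dynamics on the tens-to-hundreds-of-milliseconds timescale of
#'   paired-pulse modulation.
#' @param input_scale Characteristic input amplitude `s` (e.g. 150 for
#'   stimulation in uA, 1 for upstream response amplitudes in mV); the
#'   static curve saturates around `2.4 * s`.
#' @param output_gain Multiplies all coefficients, scaling the output range.
#' @param noise_sd Default Gaussian output noise (response units) used by
#'   [simulate_plant()].
#' @param units Unit tags for the model's input/output amplitudes.
#' @return An `lv_model` with extra fields `noise_sd` and `preset`.
#' @export
make_ground_truth_model <- function(preset = c("mixed", "facilitating",
                                               "depressing"),
                                    basis = NULL, input_scale = 150,
                                    output_gain = 1, noise_sd = 0.1,
                                    units = c(amplitude = "uA", output = "mV")) {
  preset <- match.arg(preset)
  basis <- basis %||% laguerre_basis(alpha = 0.99, n_basis = 3,
                                     n_lags = 3000, dt = 0.001)
  if (basis$n_basis > 3L) {
    stop("presets are defined for up to 3 basis functions", call. = FALSE)
  }
  if (input_scale <= 0 || noise_sd < 0) {
    stop("`input_scale` must be positive and `noise_sd` non-negative",
         call. = FALSE)
  }
  s <- input_scale
  g <- output_gain
  L <- basis$n_basis
  tpl <- preset_templates[[preset]]
  c2_tpl <- matrix(c(-5, -1, 0.3,
                     -1, -2, -0.2,
                     0.3, -0.2, -0.5), 3, 3)
  coeffs <- lv_coefficients(
    c0 = 0.05 * g,
    c1_present = 1.2 / s * g,
    c2_present = -0.25 / s^2 * g,
    c1 = tpl$c1[seq_len(L)] / s * g,
    c2 = c2_tpl[seq_len(L), seq_len(L), drop = FALSE] / s^2 * g,
    c2_cross = tpl$cross[seq_len(L)] / s^2 * g
  )
  m <- lv_model(coeffs, basis, units = units)
  m$noise_sd <- noise_sd
  m$preset <- preset
  m
}

#' Simulate plant responses to a stimulation train
#'
#' Convenience wrapper: forward-predicts the model on the train and adds
#' Gaussian output noise, returning the train with `outputs` filled in.
#' Equivalent to `simulate(plant, train = train, noise_sd = noise_sd)`.
#'
#' @param plant An `lv_model` (typically from [make_ground_truth_model()]).
#' @param train An [event_train()].
#' @param noise_sd Output noise sd; defaults to the plant's own `noise_sd`.
#' @return The train with simulated `outputs`.
#' @export
simulate_plant <- function(plant, train, noise_sd = NULL) {
  simulate(plant, nsim = 1, train = train, noise_sd = noise_sd)
}

#' End-to-end synthetic modeling-control scenario
#'
#' Runs the full control protocol on synthetic data from known ground-truth
#' models, standing in for a slice experiment:
#' 1. generate upstream ("reference-pathway") event trains with Gaussian
#'    amplitude variability, and simulate their downstream responses through
#'    a ground-truth trajectory model — the reference responses to be
#'    reproduced;
#' 2. fit the trajectory model to those train pairs (leave-one-train-out
#'    cross-validation reports held-out VAF);
#' 3. generate RARIT stimulation trains, simulate the ground-truth plant's
#'    responses, and fit the plant model likewise;
#' 4. run the trajectory-to-inverse-plant pipeline on the upstream trains to
#'    derive DARIT stimulation amplitudes, and "deliver" them to the
#'    ground-truth plant (with fresh output noise) to obtain controlled
#'    responses;
#' 5. as a non-optimal benchmark, deliver fixed-amplitude stimulation at the
#'    same mean intensity as the DARITs;
#' 6. score controlled and non-optimal responses against the reference
#'    responses with NMSE.
#'
#' @param seed Optional integer seed for all randomness in the scenario.
#' @param preset Ground-truth dynamics preset, see [make_ground_truth_model()].
#' @param noise_sd Output noise sd for both simulated preparations (response
#'   units).
#' @param n_trains,n_pulses Protocol size (default 4 x 300).
#' @param upstream_mean,upstream_sd Gaussian amplitude parameters of the
#'   upstream trains (response units of the upstream region).
#' @param rarit_mean,rarit_sd RARIT amplitude parameters.
#' @param trajectory_gain Output gain of the ground-truth trajectory model;
#'   the default keeps desired outputs inside the plant's reachable range.
#' @param policy Root policy for the inverse solve.
#' @return Object of class `"lv_endtoend"`: list with the ground-truth and
#'   fitted models, cross-validation objects, per-train control results,
#'   `trajectory_vaf`, `plant_vaf` (mean held-out fractions),
#'   `controlled_nmse`, `nonoptimal_nmse` (pooled fractions),
#'   `fixed_amplitude`, and `flags` (table).
#' @export
run_endtoend_scenario <- function(seed = NULL, preset = "mixed",
                                  noise_sd = 0.1, n_trains = 4,
                                  n_pulses = 300, upstream_mean = 1,
                                  upstream_sd = 0.25, rarit_mean = 150,
                                  rarit_sd = 45, trajectory_gain = 0.7,
                                  policy = "plus") {
  if (!is.null(seed)) set.seed(seed)
  traj_truth <- make_ground_truth_model(preset, input_scale = upstream_mean,
                                        output_gain = trajectory_gain,
                                        noise_sd = noise_sd,
                                        units = c(amplitude = "mV", output = "mV"))
  plant_truth <- make_ground_truth_model(preset, input_scale = rarit_mean,
                                         noise_sd = noise_sd)
  basis <- plant_truth$basis
  cfg <- data.frame(alpha = basis$alpha, n_basis = basis$n_basis,
                    memory = basis$memory_s)

  # reference pathway: upstream trains -> simulated downstream responses
  upstream <- generate_rarit(n_trains, n_pulses, amp_mean = upstream_mean,
                             amp_sd = upstream_sd,
                             units = c(amplitude = "mV", output = "mV"))
  upstream <- lapply(upstream, function(tr) {
    tr$train_id <- sub("RARIT", "UP", tr$train_id)
    tr
  })
  reference <- lapply(upstream, function(tr) simulate_plant(traj_truth, tr))
  traj_cv <- lv_cross_validate(reference, grid = cfg, dt = basis$dt)
  traj_fit <- traj_cv$best_model

  # stimulated pathway: RARITs -> simulated plant responses
  rarit <- generate_rarit(n_trains, n_pulses, amp_mean = rarit_mean,
                          amp_sd = rarit_sd)
  mono <- lapply(rarit, function(tr) simulate_plant(plant_truth, tr))
  plant_cv <- lv_cross_validate(mono, grid = cfg, dt = basis$dt)
  plant_fit <- plant_cv$best_model

  # derive DARITs and deliver them (and the fixed-amplitude benchmark)
  control <- lapply(upstream, function(tr) {
    run_control_pipeline(traj_fit, plant_fit, tr, policy = policy)
  })
  fixed_amp <- mean(unlist(lapply(control, `[[`, "amplitudes")))
  y_ref <- y_ctrl <- y_fix <- list()
  for (k in seq_along(upstream)) {
    darit <- event_train(control[[k]]$times, control[[k]]$amplitudes,
                         train_id = sprintf("DARIT%d", k))
    fixed <- event_train(control[[k]]$times,
                         rep(fixed_amp, length(control[[k]]$times)),
                         train_id = sprintf("FIXED%d", k))
    y_ref[[k]] <- reference[[k]]$outputs
    y_ctrl[[k]] <- simulate_plant(plant_truth, darit)$outputs
    y_fix[[k]] <- simulate_plant(plant_truth, fixed)$outputs
  }
  y_ref <- unlist(y_ref); y_ctrl <- unlist(y_ctrl); y_fix <- unlist(y_fix)
  structure(
    list(preset = preset, noise_sd = noise_sd, seed = seed,
         trajectory_truth = traj_truth, plant_truth = plant_truth,
         trajectory_cv = traj_cv, plant_cv = plant_cv,
         trajectory_fit = traj_fit, plant_fit = plant_fit,
         upstream = upstream, reference = reference, control = control,
         fixed_amplitude = fixed_amp,
         trajectory_vaf = traj_cv$results$mean_vaf[traj_cv$best],
         plant_vaf = plant_cv$results$mean_vaf[plant_cv$best],
         controlled_nmse = nmse(y_ref, y_ctrl),
         nonoptimal_nmse = nmse(y_ref, y_fix),
         n_events = length(y_ref),
         flags = table(unlist(lapply(control, `[[`, "flags")))),
    class = "lv_endtoend"
  )
}

#' @export
print.lv_endtoend <- function(x, ...) {
  cat(sprintf("End-to-end synthetic control scenario (preset '%s', noise sd %g)\n",
              x$preset, x$noise_sd))
  cat(sprintf("  trajectory model held-out VAF: %.2f%%\n",
              100 * x$trajectory_vaf))
  cat(sprintf("  plant model held-out VAF:      %.2f%%\n", 100 * x$plant_vaf))
  cat(sprintf("  controlled NMSE:   %.2f%%  (%d events)\n",
              100 * x$controlled_nmse, x$n_events))
  cat(sprintf("  non-optimal NMSE:  %.2f%%  (fixed amplitude %.1f)\n",
              100 * x$nonoptimal_nmse, x$fixed_amplitude))
  cat("  inverse-solver flags:",
      paste(sprintf("%s=%d", names(x$flags), x$flags), collapse = ", "), "\n")
  invisible(x)
}
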