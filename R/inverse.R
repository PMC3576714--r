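#' Quadratic terms of the inverse model at one event
#'
#' Because the present impulse's terms are isolated from the history terms,
#' the second-order model is a quadratic in the current amplitude `A`:
#' rearranging the forward prediction against a desired output gives
#' `a A^2 + b A + c = 0` with
#' \deqn{a = c_2(0,0),\qquad b = c_1(0) + 2\sum_l c_2(l) v_l,}
#' \deqn{c = c_0 + \sum_l c_1(l) v_l + \sum_{l_1,l_2} c_2(l_1,l_2)
#'   v_{l_1} v_{l_2} - y_{desired}.}
#' The convolutions `v` must be computed from already-determined past
#' amplitudes only.
#'
#' @param coeffs An [lv_coefficients()] set (or an `lv_model`).
#' @param v Numeric vector of Laguerre convolutions \eqn{v_l(t_i)} at the
#'   event, length `n_basis`.
#' @param y_desired Desired output amplitude at the event.
#' @return Object of class `"lv_quadratic"`: list `a`, `b`, `c`,
#'   `discriminant`.
#' @seealso [solve_amplitude()], [invert_sequence()]
#' @export
quadratic_terms <- function(coeffs, v, y_desired) {
  if (inherits(coeffs, "lv_model")) coeffs <- coeffs$coefficients
  stopifnot(inherits(coeffs, "lv_coefficients"),
            length(v) == coeffs$n_basis, is.finite(y_desired))
  a <- coeffs$c2_present
  b <- coeffs$c1_present + 2 * sum(coeffs$c2_cross * v)
  cc <- coeffs$c0 + sum(coeffs$c1 * v) + drop(v %*% coeffs$c2 %*% v) - y_desired
  structure(list(a = a, b = b, c = cc, discriminant = b^2 - 4 * a * cc),
            class = "lv_quadratic")
}

#' Solve one inverse-model quadratic for the stimulation amplitude
#'
#' Default policy takes the root `A = (-b + sqrt(b^2 - 4ac)) / (2a)`.  For a
#' saturating plant (`a < 0`) operated below the vertex of its static curve
#' this branch selects the physically operating root.  Degenerate and
#' infeasible cases are handled by flagged fallbacks rather than errors, since
#' a stimulation device must emit something at every event:
#' * `|a| < tol`: linear solve `A = -c/b`, flag `"linear_fallback"`;
#' * negative discriminant (desired output unreachable): vertex amplitude
#'   `A = -b/(2a)`, flag `"no_real_root_vertex"`;
#' * negative solution: clamped to 0, flag `"clamped_negative"`;
#' * otherwise flag `"ok"`.
#'
#' @param q An `"lv_quadratic"` from [quadratic_terms()].
#' @param policy Root branch: `"plus"` (default), `"minus"`, or
#'   `"nearest"` (root nearest `prev`).
#' @param prev Previous amplitude, used by `policy = "nearest"` (default 0).
#' @param tol Threshold below which `|a|` is treated as zero.
#' @return List with `amplitude` and `flag`.
#' @export
solve_amplitude <- function(q, policy = c("plus", "minus", "nearest"),
                            prev = 0, tol = 1e-12) {
  policy <- match.arg(policy)
  stopifnot(inherits(q, "lv_quadratic"))
  if (abs(q$a) < tol) {
    if (abs(q$b) < tol) {
      stop("degenerate inverse: both quadratic and linear terms vanish",
           call. = FALSE)
    }
    A <- -q$c / q$b
    flag <- "linear_fallback"
  } else if (q$discriminant < 0) {
    A <- -q$b / (2 * q$a)
    flag <- "no_real_root_vertex"
  } else {
    r <- sqrt(q$discriminant)
    A <- switch(policy,
                plus = (-q$b + r) / (2 * q$a),
                minus = (-q$b - r) / (2 * q$a),
                nearest = {
                  roots <- c(-q$b + r, -q$b - r) / (2 * q$a)
                  roots[which.min(abs(roots - prev))]
                })
    flag <- "ok"
  }
  if (A < 0) {
    A <- 0
    flag <- "clamped_negative"
  }
  list(amplitude = A, flag = flag)
}

#' Recursively invert a plant model over a desired output trajectory
#'
#' Walks the events in time order; at each event the Laguerre convolutions are
#' formed from the amplitudes *solved at earlier events* (true recursion — no
#' reference input is consulted), the inverse quadratic is assembled and
#' solved, and the amplitude is appended to the history.  Before the first
#' event no stimulation exists, so the history terms are zero and the first
#' amplitude comes from the static quadratic alone.  The solved train is then
#' forward-simulated (noiselessly) through the same plant to report achieved
#' outputs.
#'
#' @param plant An `lv_model` (the plant: stimulation amplitude to response).
#' @param times Strictly increasing event times (seconds).
#' @param desired_outputs Desired response amplitude at each event.
#' @param policy Root policy, see [solve_amplitude()].
#' @return Object of class `"control_result"`: list with `times`,
#'   `desired_outputs`, `amplitudes`, `flags`, `achieved_outputs`, and
#'   `quadratics` (per-event `a`, `b`, `c`, `discriminant` data frame).
#' @export
invert_sequence <- function(plant, times, desired_outputs, policy = "plus") {
  stopifnot(inherits(plant, "lv_model"))
  times <- as.numeric(times)
  desired_outputs <- as.numeric(desired_outputs)
  n <- length(times)
  if (length(desired_outputs) != n) {
    stop("`times` and `desired_outputs` must have equal length", call. = FALSE)
  }
  if (n && (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(desired_outputs))) {
    stop("`desired_outputs` must be finite", call. = FALSE)
  }
  basis <- plant$basis
  amps <- numeric(n)
  flags <- character(n)
  quads <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("a", "b", "c", "discriminant")))
  for (i in seq_len(n)) {
    v <- event_history(basis, times, amps, i)   # solved amplitudes only
    q <- quadratic_terms(plant$coefficients, v, desired_outputs[i])
    sol <- tryCatch(
      solve_amplitude(q, policy = policy, prev = if (i > 1L) amps[i - 1L] else 0),
      error = function(e) {
        stop(sprintf("event %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
    amps[i] <- sol$amplitude
    flags[i] <- sol$flag
    quads[i, ] <- c(q$a, q$b, q$c, q$discriminant)
  }
  solved <- event_train(times, amps, train_id = "DARIT",
                        units = plant$units)
  structure(
    list(times = times, desired_outputs = desired_outputs,
         amplitudes = amps, flags = flags,
         achieved_outputs = predict(plant, solved),
         quadratics = as.data.frame(quads), policy = policy),
    class = "control_result"
  )
}

#' Run the trajectory-to-stimulation control pipeline
#'
#' Full open-loop derivation of a desired-amplitude stimulation train
#' (a DARIT): the trajectory model predicts the desired downstream responses
#' from the upstream event train, and the inverse plant model converts that
#' desired trajectory into per-event stimulation amplitudes.
#'
#' @param trajectory An `lv_model` mapping upstream response amplitudes to
#'   desired downstream output amplitudes.
#' @param plant An `lv_model` mapping stimulation amplitude to downstream
#'   output amplitude.
#' @param upstream_train [event_train()] of upstream events (e.g.
#'   population-spike amplitudes).
#' @param policy Root policy for the inverse solve.
#' @return A `"control_result"` (see [invert_sequence()]); its `amplitudes`
#'   are the DARIT stimulation intensities.
#' @export
#' @seealso [run_endtoend_scenario()] for a fully synthetic closed loop.
run_control_pipeline <- function(trajectory, plant, upstream_train,
                                 policy = "plus") {
  stopifnot(inherits(trajectory, "lv_model"), inherits(plant, "lv_model"))
  upstream_train <- as_event_train(upstream_train)
  desired <- predict(trajectory, upstream_train)
  invert_sequence(plant, upstream_train$times, desired, policy = policy)
}

#' @export
print.control_result <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Inverse-model control result: %d events (root policy '%s')\n",
              n, x$policy))
  tab <- table(factor(x$flags, levels = c("ok", "clamped_negative",
                                          "no_real_root_vertex",
                                          "linear_fallback")))
  cat("  solver flags:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  cat(sprintf("  amplitudes: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$amplitudes), min(x$amplitudes), max(x$amplitudes)))
  err <- x$achieved_outputs - x$desired_outputs
  cat(sprintf("  achieved vs desired: max |error| %.3g, NMSE %.3g%%\n",
              max(abs(err)), 100 * nmse(x$desired_outputs, x$achieved_outputs)))
  invisible(x)
}

#' @export
as.data.frame.control_result <- function(x, ..., train_id = "DARIT") {
  data.frame(train_id = train_id, time_s = x$times,
             amplitude = x$amplitudes, desired_output = x$desired_outputs,
             achieved_output = x$achieved_outputs, flag = x$flags,
             stringsAsFactors = FALSE)
}

#' @export
plot.control_result <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  idx <- seq_along(x$times)
  graphics::plot(idx, x$desired_outputs, type = "p", pch = 5, col = "blue",
                 xlab = "input event", ylab = "output amplitude",
                 main = "Desired vs achieved outputs", ...)
  graphics::points(idx, x$achieved_outputs, pch = 15, col = "red")
  graphics::legend("topright", c("desired", "achieved"), pch = c(5, 15),
                   col = c("blue", "red"), bty = "n")
  graphics::plot(idx, x$amplitudes, type = "h",
                 xlab = "input event", ylab = "stimulation amplitude",
                 main = "Derived stimulation (DARIT)", ...)
  invisible(x)
}
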