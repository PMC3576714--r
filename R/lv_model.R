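#' Laguerre-Volterra coefficient set
#'
#' Container for the second-order Laguerre-Volterra expansion coefficients
#' with isolated zero-lag (present-impulse) terms.  With `L` basis functions
#' the predicted response at event \eqn{t_i} is
#' \deqn{y(t_i) = c_0 + A_i c_1(0) + A_i^2 c_2(0,0)
#'   + \sum_l c_1(l) v_l + \sum_{l_1,l_2} c_2(l_1,l_2) v_{l_1} v_{l_2}
#'   + 2 A_i \sum_l c_2(l) v_l,}
#' where \eqn{v_l} are the past-impulse Laguerre convolutions
#' ([convolve_events()]).  The parameter count is
#' `3 + 2L + L(L+1)/2`.
#'
#' @param c0 Constant (response when input is absent).
#' @param c1_present Coefficient of the present amplitude `A_i`.
#' @param c2_present Coefficient of `A_i^2` (negative for a saturating
#'   static curve).
#' @param c1 Numeric vector, length `L`: first-order history coefficients.
#' @param c2 Symmetric `L x L` matrix: second-order history coefficients.
#' @param c2_cross Numeric vector, length `L`: present-by-past cross terms.
#' @return Object of class `"lv_coefficients"`.
#' @export
lv_coefficients <- function(c0, c1_present, c2_present, c1, c2, c2_cross) {
  L <- length(c1)
  c2 <- as.matrix(c2)
  if (!identical(dim(c2), c(L, L))) {
    stop("`c2` must be an L x L matrix matching length(c1)", call. = FALSE)
  }
  if (length(c2_cross) != L) {
    stop("`c2_cross` must have length L", call. = FALSE)
  }
  if (L > 0L && max(abs(c2 - t(c2))) > 1e-12 * max(1, max(abs(c2)))) {
    stop("`c2` must be symmetric", call. = FALSE)
  }
  vals <- c(c0, c1_present, c2_present, c1, c2, c2_cross)
  if (any(!is.finite(vals))) stop("coefficients must be finite", call. = FALSE)
  structure(
    list(c0 = as.numeric(c0), c1_present = as.numeric(c1_present),
         c2_present = as.numeric(c2_present), c1 = as.numeric(c1),
         c2 = (c2 + t(c2)) / 2, c2_cross = as.numeric(c2_cross),
         n_basis = L),
    class = "lv_coefficients"
  )
}

#' @export
print.lv_coefficients <- function(x, ...) {
  cat(sprintf("Laguerre-Volterra coefficients (L = %d, %d parameters)\n",
              x$n_basis, n_lv_params(x$n_basis)))
  cat(sprintf("  static: c0 = %.4g, c1(0) = %.4g, c2(0,0) = %.4g\n",
              x$c0, x$c1_present, x$c2_present))
  cat("  c1(l):      ", paste(signif(x$c1, 4), collapse = " "), "\n")
  cat("  c2(l):      ", paste(signif(x$c2_cross, 4), collapse = " "), "\n")
  cat("  c2(l1,l2) diagonal:", paste(signif(diag(x$c2), 4), collapse = " "), "\n")
  invisible(x)
}

n_lv_params <- function(L) 3L + 2L * L + (L * (L + 1L)) %/% 2L

# flatten to the design-matrix parameter order and back
coef_vector <- function(coeffs) {
  L <- coeffs$n_basis
  ut <- which(upper.tri(coeffs$c2, diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  c(coeffs$c0, coeffs$c1_present, coeffs$c2_present, coeffs$c1,
    coeffs$c2[ut], coeffs$c2_cross)
}

coef_from_vector <- function(beta, L) {
  stopifnot(length(beta) == n_lv_params(L))
  c1 <- beta[3L + seq_len(L)]
  c2 <- matrix(0, L, L)
  idx <- 3L + L
  for (l1 in seq_len(L)) {
    for (l2 in l1:L) {
      idx <- idx + 1L
      c2[l1, l2] <- beta[idx]
      c2[l2, l1] <- beta[idx]
    }
  }
  c2_cross <- beta[idx + seq_len(L)]
  lv_coefficients(beta[1L], beta[2L], beta[3L], c1, c2, c2_cross)
}

#' Construct a Laguerre-Volterra model from known coefficients
#'
#' Assembles an `lv_model` object directly from an [lv_coefficients()] set and
#' a [laguerre_basis()], e.g. for a ground-truth simulation plant.  Fitted
#' models are normally produced by [lv_fit()].
#'
#' @param coefficients An [lv_coefficients()] object.
#' @param basis A [laguerre_basis()] with `n_basis` matching the coefficients.
#' @param units Named character vector of unit tags.
#' @return Object of class `"lv_model"`.
#' @seealso [lv_fit()], [predict.lv_model()], [volterra_kernels()]
#' @export
lv_model <- function(coefficients, basis,
                     units = c(amplitude = "uA", output = "mV")) {
  stopifnot(inherits(coefficients, "lv_coefficients"),
            inherits(basis, "laguerre_basis"))
  if (coefficients$n_basis != basis$n_basis) {
    stop("coefficient order and basis size disagree", call. = FALSE)
  }
  structure(list(coefficients = coefficients, basis = basis, units = units,
                 fit = NULL, call = sys.call()),
            class = "lv_model")
}

#' @export
print.lv_model <- function(x, ...) {
  cat("Laguerre-Volterra model")
  if (!is.null(x$preset)) cat(sprintf(" (preset '%s')", x$preset))
  cat("\n")
  cat(sprintf("  basis: alpha = %g, L = %d, memory = %g s, dt = %g s\n",
              x$basis$alpha, x$basis$n_basis, x$basis$memory_s, x$basis$dt))
  print(x$coefficients)
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted to %d events (%d parameters), condition number %.3g\n",
                x$fit$n_events, x$fit$n_params, x$fit$condition_number))
    cat(sprintf("  in-sample VAF %.2f%%, NMSE %.2f%%\n",
                100 * mean(x$fit$per_train_vaf),
                100 * mean(x$fit$per_train_nmse)))
  }
  invisible(x)
}

#' @export
coef.lv_model <- function(object, ...) {
  beta <- coef_vector(object$coefficients)
  names(beta) <- lv_param_names(object$coefficients$n_basis)
  beta
}

lv_param_names <- function(L) {
  ut <- expand.grid(l2 = seq_len(L), l1 = seq_len(L))
  ut <- ut[ut$l1 <= ut$l2, c("l1", "l2")]
  ut <- ut[order(ut$l1, ut$l2), ]
  c("c0", "c1(0)", "c2(0,0)",
    paste0("c1(", seq_len(L), ")"),
    paste0("c2(", ut$l1, ",", ut$l2, ")"),
    paste0("c2x(", seq_len(L), ")"))
}

#' Predict response amplitudes from a Laguerre-Volterra model
#'
#' Forward-runs the model over the events of one or more trains: for each
#' event the past-impulse convolutions \eqn{v_l(t_i)} are computed from the
#' train itself (history never crosses train boundaries) and combined with the
#' present amplitude through the second-order expansion.
#'
#' @param object An `lv_model`.
#' @param newdata An [event_train()] or list of them.  If omitted, the
#'   training data fitted values are returned (fitted models only).
#' @param ... Unused.
#' @return Numeric vector of predictions (single train) or a named list of
#'   vectors (list of trains).
#' @export
predict.lv_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fit)) {
      stop("`newdata` is required for a model that was not fitted to data",
           call. = FALSE)
    }
    return(object$fit$fitted)
  }
  single <- inherits(newdata, "event_train")
  trains <- as_train_list(newdata)
  beta <- coef_vector(object$coefficients)
  preds <- lapply(trains, function(tr) {
    X <- design_rows(object$basis, tr)
    drop(X %*% beta)
  })
  if (single) preds[[1L]] else preds
}

#' @export
residuals.lv_model <- function(object, ...) {
  if (is.null(object$fit)) stop("model has no fit", call. = FALSE)
  object$fit$residuals
}

#' @export
fitted.lv_model <- function(object, ...) {
  if (is.null(object$fit)) stop("model has no fit", call. = FALSE)
  object$fit$fitted
}

#' Reconstruct Volterra kernels from a fitted Laguerre expansion
#'
#' Materialises the zeroth-, first- and second-order Volterra kernels on the
#' basis lag grid:
#' \deqn{k_0 = c_0,\quad k_1(m) = \sum_l c_1(l) L_l(m),\quad
#'   k_2(m_1,m_2) = \sum_{l_1,l_2} c_2(l_1,l_2) L_{l_1}(m_1) L_{l_2}(m_2),}
#' together with the isolated present-impulse entries `k1_present = c1(0)`,
#' `k2_present = c2(0,0)` and the present-by-past cross kernel
#' \eqn{k_2(m,0) = \sum_l c_2(l) L_l(m)}.  History kernels are tabulated at
#' lag bins `0..M-1` (bin `b` corresponds to lag `b * dt` seconds); the
#' present-impulse entries are separate scalars, so their polarity can differ
#' from the adjacent history lags — the signature of zero-lag isolation.
#'
#' @param object An `lv_model` (or an [lv_coefficients()] plus `basis`).
#' @param basis Basis to expand on; defaults to the model's own.
#' @return Object of class `"volterra_kernels"`: list with `k0`,
#'   `k1_present`, `k2_present`, `k1` (length `M`), `k2_cross` (length `M`),
#'   `k2` (`M x M` symmetric matrix), `lags_s`, and `dt`.
#' @export
volterra_kernels <- function(object, basis = NULL) {
  if (inherits(object, "lv_model")) {
    coeffs <- object$coefficients
    basis <- basis %||% object$basis
  } else {
    coeffs <- object
    stopifnot(inherits(coeffs, "lv_coefficients"))
    if (is.null(basis)) stop("`basis` required", call. = FALSE)
  }
  Lmat <- basis$values                      # L x M
  k1 <- drop(crossprod(Lmat, coeffs$c1))
  k2_cross <- drop(crossprod(Lmat, coeffs$c2_cross))
  k2 <- crossprod(Lmat, coeffs$c2 %*% Lmat) # M x M
  structure(
    list(k0 = coeffs$c0, k1_present = coeffs$c1_present,
         k2_present = coeffs$c2_present, k1 = k1, k2_cross = k2_cross,
         k2 = (k2 + t(k2)) / 2,
         lags_s = (seq_len(basis$n_lags) - 1L) * basis$dt, dt = basis$dt),
    class = "volterra_kernels"
  )
}

#' @export
print.volterra_kernels <- function(x, ...) {
  cat("Volterra kernels (second order, zero-lag terms isolated)\n")
  cat(sprintf("  k0 = %.4g; k1(0) = %.4g; k2(0,0) = %.4g\n",
              x$k0, x$k1_present, x$k2_present))
  cat(sprintf("  history grid: %d lags at dt = %g s (memory %g s)\n",
              length(x$k1), x$dt, length(x$k1) * x$dt))
  cat(sprintf("  k1 range [%.4g, %.4g]; k2 range [%.4g, %.4g]\n",
              min(x$k1), max(x$k1), min(x$k2), max(x$k2)))
  invisible(x)
}

#' Plot reconstructed Volterra kernels
#'
#' Draws the first-order kernel (with the isolated zero-lag point) and an
#' image of the second-order kernel.
#'
#' @param x A `"volterra_kernels"` object.
#' @param which `1`, `2`, or both.
#' @param max_lag_s Truncate the displayed lag axis (seconds); default shows
#'   the lag range holding 99.9% of first-order kernel energy.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.volterra_kernels <- function(x, which = 1:2, max_lag_s = NULL, ...) {
  if (is.null(max_lag_s)) {
    e <- cumsum(x$k1^2)
    m <- if (e[length(e)] > 0) which(e >= 0.999 * e[length(e)])[1L] else length(x$k1)
    max_lag_s <- max(x$lags_s[m], 10 * x$dt)
  }
  keep <- x$lags_s <= max_lag_s
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::plot(x$lags_s[keep], x$k1[keep], type = "l",
                   xlab = "lag (s)", ylab = "k1", main = "First-order kernel", ...)
    graphics::points(0, x$k1_present, pch = 19, col = 2)
    graphics::legend("topright", legend = "k1(0), present impulse",
                     pch = 19, col = 2, bty = "n")
  }
  if (2 %in% which) {
    graphics::image(x$lags_s[keep], x$lags_s[keep], x$k2[keep, keep],
                    xlab = "lag m1 (s)", ylab = "lag m2 (s)",
                    main = "Second-order kernel", ...)
  }
  invisible(x)
}

#' Brute-force prediction from materialised Volterra kernels
#'
#' Direct evaluation of the second-order Volterra series with isolated
#' zero-lag terms over binned past events:
#' \deqn{y(t_i) = k_0 + A_i k_1(0) + A_i^2 k_2(0,0) + \sum_j A_j k_1(b_j)
#'   + \sum_{j_1} \sum_{j_2} A_{j_1} A_{j_2} k_2(b_{j_1}, b_{j_2})
#'   + 2 A_i \sum_j A_j k_2(b_j, 0),}
#' with the sums running over past events inside the memory window and
#' \eqn{b_j} the lag bin of event `j`.  This route is independent of the
#' coefficient-space predictor and serves as its oracle: for kernels
#' reconstructed with [volterra_kernels()] the two agree to machine precision.
#'
#' @param kernels A `"volterra_kernels"` object.
#' @param train An [event_train()].
#' @param dt Lag-bin width in seconds (defaults to the kernels' grid).
#' @return Numeric vector of predictions, one per event.
#' @export
predict_from_kernels <- function(kernels, train, dt = kernels$dt) {
  stopifnot(inherits(kernels, "volterra_kernels"))
  train <- as_event_train(train)
  M <- length(kernels$k1)
  memory_s <- M * dt
  n <- length(train$times)
  out <- numeric(n)
  for (i in seq_len(n)) {
    A <- train$amplitudes[i]
    y <- kernels$k0 + A * kernels$k1_present + A^2 * kernels$k2_present
    if (i > 1L) {
      j <- seq_len(i - 1L)
      dts <- train$times[i] - train$times[j]
      keep <- dts < memory_s
      if (any(keep)) {
        bins <- pmin(pmax(round(dts[keep] / dt), 0), M - 1L) + 1L
        aj <- train$amplitudes[j][keep]
        y <- y + sum(aj * kernels$k1[bins]) +
          drop(aj %*% kernels$k2[bins, bins, drop = FALSE] %*% aj) +
          2 * A * sum(aj * kernels$k2_cross[bins])
      }
    }
    out[i] <- y
  }
  out
}

#' Simulate noisy responses from a Laguerre-Volterra model
#'
#' Forward-predicts the model on a stimulation train and adds independent
#' Gaussian observation noise to each event's response, emulating
#' trial-to-trial variability of evoked-response amplitude measurements.
#'
#' @param object An `lv_model`.
#' @param nsim Number of response realisations.
#' @param seed Optional RNG seed, handled as in [stats::simulate()].
#' @param train The input [event_train()].
#' @param noise_sd Output noise standard deviation (response units); defaults
#'   to the model's `noise_sd` if set (ground-truth plants), else 0.
#' @param ... Unused.
#' @return An [event_train()] with `outputs` filled in (`nsim = 1`), or a
#'   list of them.
#' @export
simulate.lv_model <- function(object, nsim = 1, seed = NULL, train,
                              noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  noise_sd <- noise_sd %||% object$noise_sd %||% 0
  train <- as_event_train(train)
  mu <- predict(object, train)
  sims <- lapply(seq_len(nsim), function(k) {
    tr <- train
    tr$outputs <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
    tr$units["output"] <- object$units[["output"]] %||% "mV"
    tr
  })
  if (nsim == 1L) sims[[1L]] else sims
}
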