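#' Discrete orthonormal Laguerre function
#'
#' Evaluates the discrete-time orthonormal Laguerre function of order `l` at
#' integer lag `m`,
#' \deqn{L_l(m) = \alpha^{(m-l)/2} (1-\alpha)^{1/2}
#'   \sum_{k=0}^{l} (-1)^k \binom{m}{k} \binom{l}{k} \alpha^{l-k} (1-\alpha)^k,}
#' with \eqn{\binom{m}{k} = 0} for \eqn{k > m}.  The decay parameter
#' \eqn{\alpha \in (0,1)} sets the time extent of the basis: larger values
#' stretch the functions over more lags.
#'
#' This is the direct (closed-form) evaluation; binomial coefficients are
#' computed in log space via [lchoose()] so large lags (thousands of bins) do
#' not overflow.  [laguerre_basis()] tabulates the same functions through the
#' standard two-term recurrence, which is cheaper on a full lag grid; the two
#' routes agree to machine precision and are cross-checked in the test suite.
#'
#' @param alpha Decay parameter, in (0, 1).
#' @param order Basis order \eqn{l \ge 0} (0-based; the lowest order is the
#'   pure geometric decay \eqn{\alpha^{m/2}\sqrt{1-\alpha}}).
#' @param lag Integer lag(s) \eqn{m \ge 0}; may be a vector.
#' @return Numeric vector of `L_l(m)`, same length as `lag`.
#' @seealso [laguerre_basis()], [convolve_events()]
#' @export
#' @examples
#' laguerre_function(0.5, 0, 0)  # sqrt(1 - 0.5)
#' laguerre_function(0.7, 2, 0:10)
laguerre_function <- function(alpha, order, lag) {
  check_alpha(alpha)
  if (length(order) != 1L || order < 0 || order != round(order)) {
    stop("`order` must be a single non-negative integer", call. = FALSE)
  }
  if (any(lag < 0) || any(lag != round(lag))) {
    stop("`lag` must contain non-negative integers", call. = FALSE)
  }
  l <- as.integer(order)
  vapply(as.integer(lag), function(m) {
    k <- 0:min(l, m)
    # log-magnitude of each alternating term; signs tracked separately
    lt <- lchoose(m, k) + lchoose(l, k) + (l - k) * log(alpha) +
      k * log1p(-alpha)
    pref <- (m - l) / 2 * log(alpha) + 0.5 * log1p(-alpha)
    sum((-1)^k * exp(pref + lt))
  }, numeric(1))
}

#' Construct a discrete Laguerre basis on a lag grid
#'
#' Tabulates `n_basis` orthonormal Laguerre functions over `n_lags` discrete
#' lag bins of width `dt` seconds, giving a memory window of
#' `memory_s = n_lags * dt`.  Tabulation uses the standard stable recurrence
#' \deqn{L_0(m) = \sqrt{\alpha}\, L_0(m-1), \qquad
#'   L_l(m) = \sqrt{\alpha}\, L_l(m-1) + \sqrt{\alpha}\, L_{l-1}(m)
#'            - L_{l-1}(m-1),}
#' initialised with \eqn{L_l(0) = \alpha^{l/2}\sqrt{1-\alpha}}.
#'
#' The functions are orthonormal on the infinite lag axis; on a finite grid
#' their Gram matrix approaches the identity as soon as `n_lags` is large
#' enough that the tail \eqn{|L_l(M-1)|} is negligible.
#'
#' @param alpha Decay parameter in (0, 1).  Default 0.7.
#' @param n_basis Number of basis functions `L >= 1`.  Default 3.
#' @param n_lags Number of lag bins `M` (must exceed `n_basis`).  Default 3000.
#' @param dt Lag-bin width in seconds.  Default 0.001 (1 ms).
#' @return An object of class `"laguerre_basis"`: a list with elements
#'   `alpha`, `n_basis`, `n_lags`, `dt`, `memory_s`, and `values`, an
#'   `n_basis x n_lags` matrix with `values[l + 1, m + 1] = L_l(m)`.
#' @export
#' @examples
#' b <- laguerre_basis(0.7, 3, 200, 0.001)
#' tcrossprod(b$values)  # ~ identity for a long enough grid
laguerre_basis <- function(alpha = 0.7, n_basis = 3, n_lags = 3000,
                           dt = 0.001) {
  check_alpha(alpha)
  if (n_basis < 1 || n_basis != round(n_basis)) {
    stop("`n_basis` must be a positive integer", call. = FALSE)
  }
  if (n_lags <= n_basis || n_lags != round(n_lags)) {
    stop("`n_lags` must be an integer greater than `n_basis`", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a positive scalar (seconds)", call. = FALSE)
  }
  L <- as.integer(n_basis)
  M <- as.integer(n_lags)
  sa <- sqrt(alpha)
  vals <- matrix(0, L, M)
  vals[1L, ] <- sqrt(1 - alpha) * sa^(0:(M - 1L))
  if (L > 1L) {
    for (l in 2:L) {
      row <- numeric(M)
      row[1L] <- sa * vals[l - 1L, 1L]
      for (m in 2:M) {
        row[m] <- sa * row[m - 1L] + sa * vals[l - 1L, m] - vals[l - 1L, m - 1L]
      }
      vals[l, ] <- row
    }
  }
  structure(
    list(alpha = alpha, n_basis = L, n_lags = M, dt = dt,
         memory_s = M * dt, values = vals),
    class = "laguerre_basis"
  )
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat("Discrete orthonormal Laguerre basis\n")
  cat(sprintf("  alpha = %g, n_basis = %d, n_lags = %d, dt = %g s (memory %g s)\n",
              x$alpha, x$n_basis, x$n_lags, x$dt, x$memory_s))
  invisible(x)
}

#' Event-driven Laguerre convolutions
#'
#' Computes, for each event \eqn{t_i} of a train, the convolution of the
#' Laguerre basis with all *past* impulses inside the memory window:
#' \deqn{v_l(t_i) = \sum_{t_i - \mu < t_j < t_i} A_j\, L_l(\mathrm{bin}(t_i - t_j)),}
#' where \eqn{\mathrm{bin}(\Delta) = \mathrm{round}(\Delta / dt)} clipped to
#' the lag grid.  The present impulse (\eqn{t_j = t_i}) is excluded: its
#' contribution enters the model through the isolated zero-lag terms, which is
#' what makes the model a quadratic in the current amplitude and hence
#' analytically invertible.  The window is half-open — an event exactly
#' `memory_s` old contributes nothing.
#'
#' @param basis A [laguerre_basis()].
#' @param train An [event_train()] (times strictly increasing).
#' @param index Optional single event index (1-based).  If supplied, returns
#'   the length-`n_basis` vector \eqn{v_l(t_i)} for that event; otherwise a
#'   matrix with one row per event.
#' @return Numeric vector (length `n_basis`) or matrix
#'   (`n_events x n_basis`).
#' @export
convolve_events <- function(basis, train, index = NULL) {
  stopifnot(inherits(basis, "laguerre_basis"))
  train <- as_event_train(train)
  n <- length(train$times)
  if (!is.null(index)) {
    if (length(index) != 1L || index < 1 || index > n) {
      stop("`index` out of range", call. = FALSE)
    }
    return(drop(event_history(basis, train$times, train$amplitudes,
                              as.integer(index))))
  }
  out <- matrix(0, n, basis$n_basis,
                dimnames = list(NULL, paste0("v", seq_len(basis$n_basis))))
  for (i in seq_len(n)) {
    out[i, ] <- event_history(basis, train$times, train$amplitudes, i)
  }
  out
}

# v_l(t_i) for event i given full time/amplitude vectors; past events only,
# half-open memory window.
event_history <- function(basis, times, amps, i) {
  if (i == 1L) return(numeric(basis$n_basis))
  t_i <- times[i]
  j <- seq_len(i - 1L)
  dts <- t_i - times[j]
  keep <- dts < basis$memory_s
  if (!any(keep)) return(numeric(basis$n_basis))
  bins <- pmin(pmax(round(dts[keep] / basis$dt), 0), basis$n_lags - 1L)
  drop(basis$values[, bins + 1L, drop = FALSE] %*% amps[j][keep])
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  invisible(alpha)
}
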